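## Library roles recognised throughout the pipeline. Early embryos are
## unfractionated (total RNA); late blastoderm embryos are fractionated into
## cytoplasmic and nuclear extracts; wt/mutant whole-embryo pairs feed the
## depletion screen.
.fracscore_roles <- c("early_total", "late_cytoplasmic", "late_nuclear",
                      "wt_whole", "mutant_whole")

#' Known library roles
#'
#' The five library roles the pipeline understands: `early_total` (total RNA
#' from early syncytial embryos), `late_cytoplasmic` and `late_nuclear`
#' (compartment extracts of late blastoderm embryos), and `wt_whole` /
#' `mutant_whole` (whole-embryo libraries for the mutant depletion screen).
#'
#' @return Character vector of role names.
#' @export
library_roles <- function() .fracscore_roles

#' Construct a validated count matrix
#'
#' Bundles a genes-by-libraries matrix of raw read counts with a role
#' assignment for every library. All downstream steps (normalization,
#' enrichment scoring, mutant screening) start from this container.
#'
#' @param counts Numeric matrix of non-negative integer read counts with
#'   gene identifiers as rownames and library identifiers as colnames.
#' @param roles Named character vector mapping every library identifier to a
#'   role in [library_roles()].
#'
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer-valued matrix) and `roles`.
#' @export
#' @examples
#' m <- matrix(c(10L, 0L, 5L, 20L, 1L, 6L), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("E", "N", "C")))
#' cm <- count_matrix(m, c(E = "early_total", N = "late_nuclear",
#'                         C = "late_cytoplasmic"))
count_matrix <- function(counts, roles) {
  if (!is.matrix(counts))
    stop("`counts` must be a matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have gene rownames and library colnames",
         call. = FALSE)
  gene_ids <- rownames(counts)
  lib_ids <- colnames(counts)
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g))
    stop("duplicate gene identifier(s): ", paste(dup_g, collapse = ", "),
         call. = FALSE)
  dup_l <- unique(lib_ids[duplicated(lib_ids)])
  if (length(dup_l))
    stop("duplicate library identifier(s): ", paste(dup_l, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "count at gene '%s', library '%s' is not a non-negative integer",
      gene_ids[bad[1, 1]], lib_ids[bad[1, 2]]), call. = FALSE)
  roles <- validate_roles(roles, lib_ids)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, roles = roles[lib_ids]),
            class = "count_matrix")
}

validate_roles <- function(roles, lib_ids) {
  if (is.null(names(roles)) || any(names(roles) == ""))
    stop("`roles` must be a named vector (library id -> role)", call. = FALSE)
  missing_libs <- setdiff(lib_ids, names(roles))
  if (length(missing_libs))
    stop("no role assigned to library: ",
         paste(missing_libs, collapse = ", "), call. = FALSE)
  bad_roles <- setdiff(unique(roles), .fracscore_roles)
  if (length(bad_roles))
    stop("unknown role(s): ", paste(bad_roles, collapse = ", "),
         "; valid roles are: ", paste(.fracscore_roles, collapse = ", "),
         call. = FALSE)
  roles
}

#' Read a count matrix from a tab-separated file
#'
#' The expected layout is a header row of library identifiers and a first
#' column of gene identifiers, as exported from standard count pipelines.
#' Input ordering of genes and libraries is preserved.
#'
#' @param path Path to a tab-separated text file.
#' @param role_map Named character vector mapping each library column to a
#'   role (see [library_roles()]).
#'
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, role_map) {
  if (!file.exists(path))
    stop("count file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("count file needs a gene-id column plus at least one library",
         call. = FALSE)
  gene_ids <- df[[1]]
  lib_ids <- colnames(df)[-1]
  mat <- matrix(NA_real_, nrow = nrow(df), ncol = length(lib_ids),
                dimnames = list(gene_ids, lib_ids))
  for (j in seq_along(lib_ids)) {
    raw <- df[[j + 1]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) | val < 0 | val != round(val))
    if (length(bad))
      stop(sprintf(
        "invalid count '%s' at gene '%s' (row %d), library '%s'",
        raw[bad[1]], gene_ids[bad[1]], bad[1], lib_ids[j]), call. = FALSE)
    mat[, j] <- val
  }
  count_matrix(mat, role_map)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d libraries\n",
              nrow(x$counts), ncol(x$counts)))
  cat("roles:", paste(sprintf("%s=%s", names(x$roles), x$roles),
                      collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

## Columns of a count/normalized matrix carrying a given role.
libs_with_role <- function(x, role) names(x$roles)[x$roles == role]
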