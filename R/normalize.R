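#' Median-of-ratios size factors
#'
#' Estimates one scaling factor per library so that counts become
#' comparable across sequencing depths. For each gene with no zero count
#' (the reference set), the ratio of its count in a library to its
#' geometric mean across libraries is formed; a library's size factor is
#' the median of those ratios.
#'
#' @param m A [count_matrix()] with at least two libraries.
#'
#' @return Named numeric vector of positive size factors, one per library.
#' @export
#' @examples
#' m <- matrix(c(10L, 20L, 4L, 8L, 30L, 60L), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("g", 1:3), c("A", "B")))
#' cm <- count_matrix(m, c(A = "wt_whole", B = "mutant_whole"))
#' compute_size_factors(cm)  # (1/sqrt(2), sqrt(2))
compute_size_factors <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  counts <- m$counts
  if (ncol(counts) < 2)
    stop("size factors need at least two libraries", call. = FALSE)
  ref <- rowSums(counts == 0) == 0
  if (!any(ref))
    stop("no gene has positive counts in every library; ",
         "pre-filter all-zero-containing genes before normalization",
         call. = FALSE)
  lc <- log(counts[ref, , drop = FALSE])
  log_geo <- rowMeans(lc)
  apply(lc, 2, function(col) exp(stats::median(col - log_geo)))
}

#' Normalize counts by per-library size factors
#'
#' Divides every library's counts by its size factor, producing
#' normalized counts on a common scale.
#'
#' @param m A [count_matrix()].
#' @param factors Named (or positionally matched) positive numeric vector,
#'   one factor per library; defaults to [compute_size_factors()] of `m`.
#'
#' @return An object of class `normalized_matrix`: list with `values`
#'   (numeric matrix), `roles`, `size_factors` and `min_count_threshold`
#'   (NA until [filter_low_counts()] is applied).
#' @export
normalize_counts <- function(m, factors = compute_size_factors(m)) {
  stopifnot(inherits(m, "count_matrix"))
  if (length(factors) != ncol(m$counts))
    stop("need one size factor per library", call. = FALSE)
  if (any(!is.finite(factors) | factors <= 0))
    stop("size factors must be positive and finite", call. = FALSE)
  if (!is.null(names(factors))) {
    if (!setequal(names(factors), colnames(m$counts)))
      stop("size factor names do not match library identifiers",
           call. = FALSE)
    factors <- factors[colnames(m$counts)]
  } else {
    names(factors) <- colnames(m$counts)
  }
  values <- sweep(m$counts, 2, factors, "/")
  structure(list(values = values, roles = m$roles, size_factors = factors,
                 min_count_threshold = NA_real_),
            class = "normalized_matrix")
}

#' Remove weakly detected genes
#'
#' Retains genes whose normalized counts, summed over the libraries with
#' the given roles, reach `min_count`. Downstream enrichment scores
#' divide by the summed signal across the base libraries, so this filter
#' also guarantees positive denominators when applied over the three
#' base roles.
#'
#' @param m A `normalized_matrix`.
#' @param min_count Minimum summed normalized count (reads); default 5.
#' @param roles Roles whose libraries enter the sum; default all roles
#'   present in `m`.
#'
#' @return A `normalized_matrix` restricted to the retained genes, with
#'   `min_count_threshold` recorded.
#' @export
filter_low_counts <- function(m, min_count = 5, roles = unique(m$roles)) {
  stopifnot(inherits(m, "normalized_matrix"))
  if (!is.numeric(min_count) || length(min_count) != 1 || min_count < 0)
    stop("`min_count` must be a single non-negative number", call. = FALSE)
  use <- names(m$roles)[m$roles %in% roles]
  if (!length(use))
    stop("no library carries any of the requested roles", call. = FALSE)
  keep <- rowSums(m$values[, use, drop = FALSE]) >= min_count
  if (!any(keep))
    warning("low-count filter removed every gene", call. = FALSE)
  structure(list(values = m$values[keep, , drop = FALSE], roles = m$roles,
                 size_factors = m$size_factors,
                 min_count_threshold = min_count),
            class = "normalized_matrix")
}

#' Average replicate libraries by role
#'
#' Collapses a normalized matrix to one column per role by averaging the
#' normalized values of libraries sharing a role. With a single library
#' per role this is a relabelling. The collapse is reported via a
#' message when any role has replicates.
#'
#' @param m A `normalized_matrix`.
#' @param roles Roles to retain (default: all present).
#'
#' @return A `normalized_matrix` whose columns are roles; its
#'   `size_factors` are the per-role means of the input factors (kept for
#'   provenance only).
#' @export
average_roles <- function(m, roles = unique(m$roles)) {
  stopifnot(inherits(m, "normalized_matrix"))
  roles <- intersect(roles, unique(m$roles))
  if (!length(roles))
    stop("none of the requested roles are present", call. = FALSE)
  out <- vapply(roles, function(r) {
    cols <- libs_with_role(m, r)
    if (length(cols) > 1)
      message(sprintf("averaging %d replicate libraries for role '%s'",
                      length(cols), r))
    rowMeans(m$values[, cols, drop = FALSE])
  }, numeric(nrow(m$values)))
  if (nrow(m$values) == 1)  # vapply drops to vector shape edge case guard
    out <- matrix(out, nrow = 1, dimnames = list(rownames(m$values), roles))
  sf <- vapply(roles, function(r) mean(m$size_factors[libs_with_role(m, r)]),
               numeric(1))
  role_ids <- stats::setNames(roles, roles)
  structure(list(values = out, roles = role_ids, size_factors = sf,
                 min_count_threshold = m$min_count_threshold),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d libraries\n",
              nrow(x$values), ncol(x$values)))
  cat("size factors:",
      paste(sprintf("%s=%.4g", names(x$size_factors), x$size_factors),
            collapse = ", "), "\n")
  if (!is.na(x$min_count_threshold))
    cat("low-count filter: >=", x$min_count_threshold,
        "summed normalized reads\n")
  invisible(x)
}

#' @export
dim.normalized_matrix <- function(x) dim(x$values)

#' Write a normalized matrix and its metadata sidecar
#'
#' @param m A `normalized_matrix`.
#' @param path Output path for the tab-separated value matrix; a sidecar
#'   `<path>.meta.tsv` records size factors, roles and the filter
#'   threshold.
#' @return Invisibly, `path`.
#' @export
write_normalized_matrix <- function(m, path) {
  stopifnot(inherits(m, "normalized_matrix"))
  df <- data.frame(gene_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(
    library_id = names(m$size_factors),
    role = unname(m$roles[names(m$size_factors)]),
    size_factor = unname(m$size_factors),
    min_count_threshold = m$min_count_threshold,
    stringsAsFactors = FALSE)
  utils::write.table(meta, paste0(path, ".meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a normalized matrix written by [write_normalized_matrix()]
#'
#' @param path Path to the value matrix; `<path>.meta.tsv` must exist.
#' @return A `normalized_matrix`.
#' @export
read_normalized_matrix <- function(path) {
  meta_path <- paste0(path, ".meta.tsv")
  if (!file.exists(path) || !file.exists(meta_path))
    stop("missing matrix or metadata sidecar for: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  structure(list(
    values = values,
    roles = stats::setNames(meta$role, meta$library_id)[colnames(values)],
    size_factors = stats::setNames(meta$size_factor,
                                   meta$library_id)[colnames(values)],
    min_count_threshold = meta$min_count_threshold[1]),
    class = "normalized_matrix")
}
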