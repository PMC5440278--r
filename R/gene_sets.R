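#' Construct a gene set
#'
#' @param label Set label.
#' @param members Character vector of gene identifiers; duplicates are
#'   removed.
#' @param provenance Optional free-text provenance note.
#' @return A `gene_set` list with `label`, `members`, `provenance`.
#' @export
gene_set <- function(label, members, provenance = NULL) {
  members <- as.character(members)
  dup <- unique(members[duplicated(members)])
  if (length(dup))
    message(sprintf("gene_set '%s': %d duplicate id(s) removed",
                    label, length(dup)))
  structure(list(label = label, members = unique(members),
                 provenance = provenance),
            class = "gene_set")
}

#' Read a gene list file
#'
#' One identifier per line; blank lines and lines starting with `#` are
#' skipped; duplicates removed with a message.
#'
#' @param path Path to the list file.
#' @param label Set label; defaults to the file name without extension.
#' @return A [gene_set()].
#' @export
read_gene_list <- function(path, label = NULL) {
  if (!file.exists(path))
    stop("gene list not found: ", path, call. = FALSE)
  if (is.null(label))
    label <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    stop("gene list is empty: ", path, call. = FALSE)
  gene_set(label, lines, provenance = path)
}

#' Write a gene set as a plain list file
#'
#' @param s A [gene_set()].
#' @param path Output path (one id per line, label as a `#` header).
#' @return Invisibly, `path`.
#' @export
write_gene_list <- function(s, path) {
  stopifnot(inherits(s, "gene_set"))
  writeLines(c(paste0("# ", s$label), s$members), path)
  invisible(path)
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d members\n", x$label, length(x$members)))
  invisible(x)
}

#' Overlap between two gene sets within a universe
#'
#' Quantifies |A∩B|, the Jaccard index |A∩B|/|A∪B|, and a hypergeometric
#' upper-tail p-value: the probability of drawing at least |A∩B| members
#' of B when |A| genes are drawn without replacement from the universe.
#' The statistic is symmetric in A and B (it equals the one-tailed
#' Fisher exact test on the 2x2 membership table). Members outside the
#' universe are dropped with a warning.
#'
#' @param a,b [gene_set()] objects (or character vectors).
#' @param universe A [gene_set()] or character vector of the genes
#'   against which the overlap is judged, typically all genes passing
#'   the low-count filter.
#'
#' @return An `overlap_result` list with `label_a`, `label_b`, `n_a`,
#'   `n_b`, `n_intersect`, `n_union`, `universe_size`, `jaccard`,
#'   `p_value`.
#' @export
overlap <- function(a, b, universe) {
  as_set <- function(x, default_label) {
    if (inherits(x, "gene_set")) x
    else gene_set(default_label, x)
  }
  a <- as_set(a, "A")
  b <- as_set(b, "B")
  u <- if (inherits(universe, "gene_set")) universe$members
       else unique(as.character(universe))
  if (!length(u))
    stop("empty universe", call. = FALSE)
  clip <- function(s) {
    outside <- setdiff(s$members, u)
    if (length(outside))
      warning(sprintf("%d member(s) of '%s' outside the universe dropped",
                      length(outside), s$label), call. = FALSE)
    intersect(s$members, u)
  }
  am <- clip(a)
  bm <- clip(b)
  k <- length(intersect(am, bm))
  n_union <- length(union(am, bm))
  ## P(X >= k), X ~ Hypergeometric(|B| successes, |U|-|B| failures, |A| draws)
  p <- stats::phyper(k - 1, length(bm), length(u) - length(bm),
                     length(am), lower.tail = FALSE)
  structure(list(label_a = a$label, label_b = b$label,
                 n_a = length(am), n_b = length(bm),
                 n_intersect = k, n_union = n_union,
                 universe_size = length(u),
                 jaccard = if (n_union) k / n_union else 0,
                 p_value = p),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap %s ~ %s: |A|=%d |B|=%d |A&B|=%d (universe %d), Jaccard %.3f, p = %.3g\n",
    x$label_a, x$label_b, x$n_a, x$n_b, x$n_intersect, x$universe_size,
    x$jaccard, x$p_value))
  invisible(x)
}

#' Pairwise overlap table for several gene sets
#'
#' @param sets Named list of [gene_set()]s or character vectors.
#' @param universe As in [overlap()].
#' @return A data.frame with one row per unordered pair.
#' @export
overlap_table <- function(sets, universe) {
  labels <- names(sets)
  if (is.null(labels))
    stop("`sets` must be a named list", call. = FALSE)
  pairs <- utils::combn(labels, 2, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    o <- overlap(as_gene_set(sets[[p[1]]], p[1]),
                 as_gene_set(sets[[p[2]]], p[2]), universe)
    data.frame(set_a = o$label_a, set_b = o$label_b, n_a = o$n_a,
               n_b = o$n_b, n_intersect = o$n_intersect,
               universe_size = o$universe_size, jaccard = o$jaccard,
               p_value = o$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

as_gene_set <- function(x, label) {
  if (inherits(x, "gene_set")) x else gene_set(label, x)
}
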