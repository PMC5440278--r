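#' Wild-type vs mutant fold-change table
#'
#' Computes the per-gene decrease factor wt/mutant from jointly
#' normalized whole-embryo libraries. Genes are restricted to those
#' passing the wild-type-side low-count filter so that ratios are not
#' driven by undetectable wild-type signal. A mutant value of zero gives
#' an infinite decrease factor unless a pseudocount is used.
#'
#' @param wt,mut `normalized_matrix` objects carrying roles `wt_whole`
#'   and `mutant_whole` respectively (replicates averaged internally).
#'   Both may be the same object holding both roles; normalize wt and
#'   mutant libraries jointly so the ratio scale is comparable.
#' @param genotype Label for the mutant genotype (e.g. "grp_fs1").
#' @param min_count Wild-type-side detection threshold (normalized
#'   reads); default 5.
#' @param pseudocount Value added to both sides of the ratio; default 0
#'   (zero mutant counts map to +Inf).
#'
#' @return A `fold_change_table` data.frame with columns `gene_id`, `wt`,
#'   `mutant` and `decrease_factor`, plus attributes `genotype` and
#'   `pseudocount`.
#' @export
fold_change <- function(wt, mut, genotype, min_count = 5, pseudocount = 0) {
  stopifnot(inherits(wt, "normalized_matrix"),
            inherits(mut, "normalized_matrix"))
  if (pseudocount < 0)
    stop("`pseudocount` must be >= 0", call. = FALSE)
  wt_avg <- average_roles(wt, "wt_whole")
  mut_avg <- average_roles(mut, "mutant_whole")
  shared <- intersect(rownames(wt_avg$values), rownames(mut_avg$values))
  if (!length(shared))
    stop("wild-type and mutant matrices share no genes", call. = FALSE)
  w <- wt_avg$values[shared, "wt_whole"]
  keep <- w >= min_count
  if (!any(keep))
    stop("no gene passes the wild-type low-count filter", call. = FALSE)
  w <- w[keep]
  m <- mut_avg$values[shared, "mutant_whole"][keep]
  factor <- (w + pseudocount) / (m + pseudocount)
  out <- data.frame(gene_id = names(w), wt = unname(w), mutant = unname(m),
                    decrease_factor = unname(factor),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("fold_change_table", "data.frame")
  attr(out, "genotype") <- genotype
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Select transcripts depleted in the mutant
#'
#' Selects genes whose decrease factor (wt/mutant) is at least
#' `threshold`; the default 4 matches a "4-fold or greater decrease" and
#' the comparison is inclusive.
#'
#' @param t A `fold_change_table` from [fold_change()].
#' @param threshold Fold threshold (> 1); default 4.
#'
#' @return A `downregulated_set`: list with `genotype`, `threshold` and
#'   `genes`.
#' @export
select_downregulated <- function(t, threshold = 4) {
  stopifnot(inherits(t, "fold_change_table"))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 1)
    stop("`threshold` must be a single fold value > 1", call. = FALSE)
  structure(list(genotype = attr(t, "genotype"), threshold = threshold,
                 genes = t$gene_id[t$decrease_factor >= threshold]),
            class = "downregulated_set")
}

#' @export
print.downregulated_set <- function(x, ...) {
  cat(sprintf("downregulated_set '%s': %d genes at >= %g-fold decrease\n",
              x$genotype, length(x$genes), x$threshold))
  invisible(x)
}

## log2(x+1) stabilises the Pearson correlation against the handful of
## very highly expressed genes; Spearman is unaffected by the transform.
log_transform <- function(x) log2(x + 1)

#' Wild-type vs mutant correlation within transcript groups
#'
#' For each named gene group, computes the Pearson r (on log2(x+1)
#' normalized counts) and Spearman rho between wild-type and mutant
#' expression, restricted to the genes shared by both matrices after the
#' wild-type low-count filter. Groups with fewer than 3 usable genes are
#' skipped with a warning; a constant vector yields NA correlations.
#'
#' @param wt,mut As in [fold_change()].
#' @param groups Named list of character vectors (or of [gene_set()]
#'   objects) giving group membership.
#' @param genotype Label recorded in the output.
#' @inheritParams fold_change
#'
#' @return A data.frame with columns `group`, `genotype`, `n`,
#'   `spearman_rho`, `pearson_r`.
#' @export
group_correlations <- function(wt, mut, groups, genotype = "mutant",
                               min_count = 5) {
  fc <- fold_change(wt, mut, genotype, min_count = min_count)
  members <- lapply(groups, function(g) {
    if (inherits(g, "gene_set")) g$members else as.character(g)
  })
  rows <- lapply(names(members), function(label) {
    idx <- fc$gene_id %in% members[[label]]
    n <- sum(idx)
    if (n < 3) {
      warning(sprintf("group '%s' has %d usable gene(s) (< 3); skipped",
                      label, n), call. = FALSE)
      return(NULL)
    }
    w <- log_transform(fc$wt[idx])
    m <- log_transform(fc$mutant[idx])
    rho <- if (stats::sd(w) == 0 || stats::sd(m) == 0) NA_real_ else
      suppressWarnings(stats::cor(w, m, method = "spearman"))
    r <- if (stats::sd(w) == 0 || stats::sd(m) == 0) NA_real_ else
      stats::cor(w, m, method = "pearson")
    data.frame(group = label, genotype = genotype, n = n,
               spearman_rho = rho, pearson_r = r,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-group fold-change summaries
#'
#' Summarizes the depletion of each transcript group: median decrease
#' factor, fraction of genes at or above the fold threshold, and group
#' size within the filtered gene universe.
#'
#' @param t A `fold_change_table`.
#' @param groups Named list of character vectors or [gene_set()] objects.
#' @param threshold Fold threshold used for the depleted fraction;
#'   default 4.
#'
#' @return A data.frame with columns `group`, `genotype`, `n`,
#'   `median_factor`, `frac_ge_threshold`.
#' @export
group_foldchange_summary <- function(t, groups, threshold = 4) {
  stopifnot(inherits(t, "fold_change_table"))
  members <- lapply(groups, function(g) {
    if (inherits(g, "gene_set")) g$members else as.character(g)
  })
  rows <- lapply(names(members), function(label) {
    f <- t$decrease_factor[t$gene_id %in% members[[label]]]
    data.frame(group = label, genotype = attr(t, "genotype"),
               n = length(f),
               median_factor = if (length(f)) stats::median(f) else NA_real_,
               frac_ge_threshold = if (length(f)) mean(f >= threshold)
                                   else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
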