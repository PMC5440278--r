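## Spatiotemporal contexts and the base-library role backing each one.
.contexts <- c(early = "early_total", cytoplasmic = "late_cytoplasmic",
               nuclear = "late_nuclear", late = NA_character_)

#' Spatiotemporal context labels
#' @return Character vector: early, cytoplasmic, nuclear, late.
#' @export
context_labels <- function() names(.contexts)

#' Per-gene compartment enrichment scores
#'
#' For each gene with base-library normalized counts E (early total),
#' C (late cytoplasmic) and N (late nuclear), the enrichment scores are
#' \deqn{N_y = 2N/(E+C+N), \quad C_y = 2C/(E+C+N), \quad E_y = 2E/(E+C+N)}
#' so that a uniformly distributed transcript scores 2/3 in every context
#' and the three scores always sum to 2. The late-blastoderm score uses
#' the mean of the two late-embryo fractions as its signal:
#' \eqn{L_y = (C+N)/(E+C+N) = (C_y+N_y)/2}, which preserves the uniform
#' value 2/3 (there is no unfractionated late library to use directly).
#'
#' @param m A `normalized_matrix` containing the roles `early_total`,
#'   `late_cytoplasmic` and `late_nuclear` (replicates averaged
#'   internally via [average_roles()]). Apply [filter_low_counts()] over
#'   those roles first so every denominator is positive.
#'
#' @return An `enrichment_table` data.frame with columns `gene_id`,
#'   `E_x`, `C_x`, `N_x` (normalized counts) and the scores `E_y`, `C_y`,
#'   `N_y`, `L_y`.
#' @export
context_score <- function(m) {
  stopifnot(inherits(m, "normalized_matrix"))
  need <- c("early_total", "late_cytoplasmic", "late_nuclear")
  missing_roles <- setdiff(need, unique(m$roles))
  if (length(missing_roles))
    stop("missing base-library role(s): ",
         paste(missing_roles, collapse = ", "), call. = FALSE)
  avg <- average_roles(m, need)
  E <- avg$values[, "early_total"]
  C <- avg$values[, "late_cytoplasmic"]
  N <- avg$values[, "late_nuclear"]
  total <- E + C + N
  if (any(total <= 0))
    stop("gene(s) with zero total signal across base libraries: ",
         paste(utils::head(rownames(avg$values)[total <= 0], 5),
               collapse = ", "),
         "; apply filter_low_counts() first", call. = FALSE)
  out <- data.frame(
    gene_id = rownames(avg$values),
    E_x = E, C_x = C, N_x = N,
    E_y = 2 * E / total,
    C_y = 2 * C / total,
    N_y = 2 * N / total,
    L_y = (C + N) / total,
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Parameters for the adaptive score cutoff
#'
#' @param exponent Position of the cutoff along the log-range of the
#'   score distribution, strictly between 0 and 1 (default 0.6, leaving
#'   the top 40 percent of the log-range above the cutoff).
#' @param strict If `TRUE` (default) selection requires score strictly
#'   greater than the cutoff.
#' @return A `cutoff_params` list.
#' @export
cutoff_params <- function(exponent = 0.6, strict = TRUE) {
  if (!is.numeric(exponent) || length(exponent) != 1 ||
      exponent <= 0 || exponent >= 1)
    stop("`exponent` must be a single number in (0, 1)", call. = FALSE)
  structure(list(exponent = exponent, strict = isTRUE(strict)),
            class = "cutoff_params")
}

#' Adaptive cutoff on an exponential-shaped score distribution
#'
#' Sorted enrichment-score distributions are approximately exponential,
#' i.e. linear on a log scale. The cutoff
#' \deqn{y_{min} \times (y_{max}/y_{min})^{a}}
#' sits at fraction `a` of the distribution's log-range, so with the
#' default exponent 0.6 the scores above it occupy the top 40 percent of
#' the log-range, independent of scale and of log base.
#'
#' @param scores Positive numeric scores (order irrelevant).
#' @param params A [cutoff_params()].
#' @return The cutoff value.
#' @export
#' @examples
#' adaptive_cutoff(c(1, 10, 100, 1000, 1e5))  # 1 * (1e5)^0.6 = 1000
adaptive_cutoff <- function(scores, params = cutoff_params()) {
  stopifnot(inherits(params, "cutoff_params"))
  if (!length(scores))
    stop("empty score distribution", call. = FALSE)
  if (any(!is.finite(scores) | scores <= 0))
    stop("all scores must be positive and finite ",
         "(the cutoff is defined on the log scale)", call. = FALSE)
  y_min <- min(scores)
  y_max <- max(scores)
  y_min * (y_max / y_min)^params$exponent
}

#' Select context-enriched genes with the adaptive cutoff
#'
#' Sorts one context's scores (descending, ties broken by gene id),
#' computes the adaptive cutoff from the distribution's min and max, and
#' selects the genes whose score exceeds it. Genes with a zero score in
#' the requested context cannot be placed on the log scale and can never
#' be selected; they are dropped from the distribution with a warning.
#'
#' @param t An `enrichment_table` from [context_score()].
#' @param context One of [context_labels()].
#' @param params A [cutoff_params()].
#'
#' @return A `context_selection`: list with `context`, `scores` (named,
#'   sorted descending), `y_min`, `y_max`, `exponent`, `strict`,
#'   `cutoff`, `selected` (gene ids) and `n_zero_dropped`.
#' @export
select_enriched <- function(t, context, params = cutoff_params()) {
  stopifnot(inherits(t, "enrichment_table"))
  context <- match.arg(context, context_labels())
  col <- c(early = "E_y", cytoplasmic = "C_y", nuclear = "N_y",
           late = "L_y")[[context]]
  scores <- stats::setNames(t[[col]], t$gene_id)
  zero <- scores <= 0
  if (any(zero)) {
    warning(sprintf(
      "%d gene(s) with zero %s score dropped from the distribution",
      sum(zero), context), call. = FALSE)
    scores <- scores[!zero]
  }
  if (!length(scores))
    stop("no positive scores for context '", context, "'", call. = FALSE)
  ord <- order(-scores, names(scores))
  scores <- scores[ord]
  cutoff <- adaptive_cutoff(scores, params)
  sel <- if (params$strict) scores > cutoff else scores >= cutoff
  structure(list(context = context, scores = scores,
                 y_min = min(scores), y_max = max(scores),
                 exponent = params$exponent, strict = params$strict,
                 cutoff = cutoff, selected = names(scores)[sel],
                 n_zero_dropped = sum(zero)),
            class = "context_selection")
}

#' @export
print.context_selection <- function(x, ...) {
  cat(sprintf(
    "context_selection '%s': %d/%d genes %s cutoff %.4g (y_min %.4g, y_max %.4g, exponent %g)\n",
    x$context, length(x$selected), length(x$scores),
    if (x$strict) ">" else ">=", x$cutoff, x$y_min, x$y_max, x$exponent))
  invisible(x)
}

#' Write a context selection as score table plus summary sidecar
#'
#' @param sel A `context_selection`.
#' @param t The `enrichment_table` the selection came from.
#' @param path Output path for the per-gene table; a sidecar
#'   `<path>.summary.tsv` records y_min, y_max, cutoff, exponent and the
#'   selection count.
#' @return Invisibly, `path`.
#' @export
write_context_selection <- function(sel, t, path) {
  stopifnot(inherits(sel, "context_selection"),
            inherits(t, "enrichment_table"))
  idx <- match(names(sel$scores), t$gene_id)
  out <- data.frame(gene_id = names(sel$scores),
                    E_x = t$E_x[idx], C_x = t$C_x[idx], N_x = t$N_x[idx],
                    score = unname(sel$scores),
                    selected = as.integer(names(sel$scores) %in%
                                            sel$selected),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary_df <- data.frame(context = sel$context, y_min = sel$y_min,
                           y_max = sel$y_max, cutoff = sel$cutoff,
                           exponent = sel$exponent,
                           n_selected = length(sel$selected),
                           n_scored = length(sel$scores))
  utils::write.table(summary_df, paste0(path, ".summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
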