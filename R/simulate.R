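#' Simulation configuration
#'
#' Parameters of the synthetic count generator that emulates the
#' processed layer of the study design: three wild-type base libraries
#' (early total, late cytoplasmic, late nuclear) with planted
#' compartment-enrichment classes, and wild-type/mutant whole-embryo
#' pairs with planted depletion.
#'
#' @param n_genes Number of genes.
#' @param mean_depth Mean total expression per gene (reads) across the
#'   libraries of one simulation; default 500.
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives deterministic rounded means.
#'   Default 0.05.
#' @param class_props Named proportions over enrichment classes
#'   `uniform`, `nuclear`, `cytoplasmic`, `early`; must sum to 1.
#'   Default: 10 percent nuclear-enriched, the rest uniform.
#' @param effect Enrichment effect size (>= 1): an enriched gene places
#'   effect/(effect+2) of its expression in its target compartment and
#'   1/(effect+2) in each other compartment; 1 reduces to uniform.
#'   Default 10.
#' @param depleted_fraction Fraction of genes depleted in the mutant;
#'   default 0.1.
#' @param depletion_factor Fold depletion (>= 1) applied to depleted
#'   genes in the mutant; default 8.
#' @param lognorm_sigma Standard deviation of the natural-log-normal
#'   spread of per-gene total expression; default 1 (roughly three
#'   decades of dynamic range, as in real libraries).
#' @param seed Integer random seed governing all draws.
#'
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 1000, mean_depth = 500,
                              dispersion = 0.05,
                              class_props = c(uniform = 0.9, nuclear = 0.1,
                                              cytoplasmic = 0, early = 0),
                              effect = 10, depleted_fraction = 0.1,
                              depletion_factor = 8, lognorm_sigma = 1,
                              seed = 1L) {
  classes <- c("uniform", "nuclear", "cytoplasmic", "early")
  if (is.null(names(class_props)) ||
      !all(names(class_props) %in% classes))
    stop("`class_props` must be named with: ",
         paste(classes, collapse = ", "), call. = FALSE)
  props <- stats::setNames(numeric(length(classes)), classes)
  props[names(class_props)] <- class_props
  if (any(props < 0) || abs(sum(props) - 1) > 1e-9)
    stop("`class_props` must be non-negative and sum to 1", call. = FALSE)
  stopifnot(n_genes >= 1, mean_depth > 0, dispersion >= 0, effect >= 1,
            depleted_fraction >= 0, depleted_fraction <= 1,
            depletion_factor >= 1, lognorm_sigma >= 0)
  structure(list(n_genes = as.integer(n_genes), mean_depth = mean_depth,
                 dispersion = dispersion, class_props = props,
                 effect = effect, depleted_fraction = depleted_fraction,
                 depletion_factor = depletion_factor,
                 lognorm_sigma = lognorm_sigma, seed = as.integer(seed)),
            class = "simulation_config")
}

## One NB draw per mean; dispersion 0 degenerates to rounded means so
## that noise-free tests can assert exact integer equality.
nb_draw <- function(mu, dispersion) {
  if (dispersion == 0) return(as.integer(round(mu)))
  as.integer(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion))
}

## Per-gene totals, log-normal around mean_depth (mean on the raw scale).
draw_totals <- function(cfg) {
  if (cfg$lognorm_sigma == 0) return(rep(cfg$mean_depth, cfg$n_genes))
  stats::rlnorm(cfg$n_genes,
                meanlog = log(cfg$mean_depth) - cfg$lognorm_sigma^2 / 2,
                sdlog = cfg$lognorm_sigma)
}

#' Simulate the three wild-type base libraries with planted classes
#'
#' Each gene's total expression (log-normal around `mean_depth`) is split
#' across the early-total, late-cytoplasmic and late-nuclear libraries:
#' uniform genes get 1/3 in each; a gene enriched in compartment k gets
#' effect/(effect+2) there and 1/(effect+2) in each other compartment.
#' Counts are negative-binomial around the split means. The same
#' configuration and seed always reproduce identical counts.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `counts` (a [count_matrix()] with libraries
#'   `early`, `cyto`, `nuc`) and `truth` (data.frame `gene_id`, `class`).
#' @export
simulate_base_libraries <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  gene_ids <- sprintf("gene%05d", seq_len(cfg$n_genes))
  classes <- sample(names(cfg$class_props), cfg$n_genes, replace = TRUE,
                    prob = cfg$class_props)
  totals <- draw_totals(cfg)
  major <- cfg$effect / (cfg$effect + 2)
  minor <- 1 / (cfg$effect + 2)
  shares <- rbind(uniform = c(1, 1, 1) / 3,
                  early = c(major, minor, minor),
                  cytoplasmic = c(minor, major, minor),
                  nuclear = c(minor, minor, major))
  colnames(shares) <- c("early", "cyto", "nuc")
  mu <- shares[classes, , drop = FALSE] * totals
  counts <- matrix(nb_draw(as.vector(mu), cfg$dispersion),
                   nrow = cfg$n_genes,
                   dimnames = list(gene_ids, colnames(shares)))
  cm <- count_matrix(counts, c(early = "early_total",
                               cyto = "late_cytoplasmic",
                               nuc = "late_nuclear"))
  list(counts = cm,
       truth = data.frame(gene_id = gene_ids, class = classes,
                          stringsAsFactors = FALSE))
}

#' Simulate a wild-type/mutant whole-embryo pair with planted depletion
#'
#' Wild-type means are log-normal around `mean_depth`; a random
#' `depleted_fraction` of genes has its mutant mean divided by
#' `depletion_factor`, the rest are unchanged. Counts are
#' negative-binomial around the means; the seed fixes everything.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `counts` (a [count_matrix()] with libraries `wt`,
#'   `mut`) and `truth` (data.frame `gene_id`, `depleted`,
#'   `true_factor`).
#' @export
simulate_mutant_pair <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  gene_ids <- sprintf("gene%05d", seq_len(cfg$n_genes))
  wt_mu <- draw_totals(cfg)
  depleted <- stats::runif(cfg$n_genes) < cfg$depleted_fraction
  mut_mu <- ifelse(depleted, wt_mu / cfg$depletion_factor, wt_mu)
  counts <- cbind(wt = nb_draw(wt_mu, cfg$dispersion),
                  mut = nb_draw(mut_mu, cfg$dispersion))
  rownames(counts) <- gene_ids
  cm <- count_matrix(counts, c(wt = "wt_whole", mut = "mutant_whole"))
  list(counts = cm,
       truth = data.frame(
         gene_id = gene_ids, depleted = depleted,
         true_factor = ifelse(depleted, cfg$depletion_factor, 1),
         stringsAsFactors = FALSE))
}

#' Recovery of a planted gene set by a selection
#'
#' Confusion-matrix sensitivity and specificity of a selected gene set
#' against planted truth labels.
#'
#' @param selected Character vector of selected gene ids.
#' @param truth_positive Character vector of genes planted as positive.
#' @param all_genes Character vector of the full gene universe scored.
#' @return A list with `sensitivity`, `specificity`, `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
recovery_stats <- function(selected, truth_positive, all_genes) {
  pos <- all_genes %in% truth_positive
  sel <- all_genes %in% selected
  tp <- sum(pos & sel); fn <- sum(pos & !sel)
  fp <- sum(!pos & sel); tn <- sum(!pos & !sel)
  list(sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp) tn / (tn + fp) else NA_real_,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Write simulated counts, truth and resolved configuration
#'
#' @param sim Output of [simulate_base_libraries()] or
#'   [simulate_mutant_pair()].
#' @param cfg The [simulation_config()] used.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, cfg, dir, prefix = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts_path <- file.path(dir, paste0(prefix, "_counts.tsv"))
  truth_path <- file.path(dir, paste0(prefix, "_truth.tsv"))
  cfg_path <- file.path(dir, paste0(prefix, "_config.tsv"))
  df <- data.frame(gene_id = rownames(sim$counts$counts),
                   sim$counts$counts, check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  flat <- unlist(cfg)
  utils::write.table(
    data.frame(key = names(flat), value = unname(flat)),
    cfg_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts = counts_path, truth = truth_path, config = cfg_path))
}
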