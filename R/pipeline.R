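#' Read a pipeline run configuration
#'
#' Configurations are YAML: flat keys for thresholds plus small sections
#' for the role map, simulation parameters and external gene-list files.
#' All defaults are filled in and echoed into the run manifest, so a run
#' is self-describing.
#'
#' @param path Path to a YAML config file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  run_config(yaml::read_yaml(path))
}

#' Build a run configuration from a list
#'
#' @param x Named list of settings; see Details for keys.
#'
#' @details Recognised keys (defaults in parentheses): `output_dir`
#'   ("fracscore_run"), `seed` (1), `min_count` (5), `exponent` (0.6),
#'   `strict` (TRUE), `fold_threshold` (4), `pseudocount` (0), `counts` /
#'   `role_map` (base-library input; omitted when simulating),
#'   `mutant_counts` / `mutant_role_map` (wt+mutant input), `simulate`
#'   (simulation parameter list passed to [simulation_config()]),
#'   `group_lists` (named paths to external gene-list files, e.g. ovarian
#'   and purely-zygotic surveys), `genotype` ("mutant").
#' @return A `run_config` list.
#' @export
run_config <- function(x = list()) {
  defaults <- list(output_dir = "fracscore_run", seed = 1L, min_count = 5,
                   exponent = 0.6, strict = TRUE, fold_threshold = 4,
                   pseudocount = 0, counts = NULL, role_map = NULL,
                   mutant_counts = NULL, mutant_role_map = NULL,
                   simulate = NULL, group_lists = NULL,
                   genotype = "mutant")
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, x, keep.null = TRUE)
  if (cfg$min_count < 0 || cfg$fold_threshold <= 1 ||
      cfg$exponent <= 0 || cfg$exponent >= 1)
    stop("config thresholds out of range: need min_count >= 0, ",
         "fold_threshold > 1, exponent in (0, 1)", call. = FALSE)
  structure(cfg, class = "run_config")
}

log_line <- function(state, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  cat(msg, "\n", sep = "", file = state$log, append = TRUE)
  message(msg)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order: `simulate` (when
#' no count input is configured), `normalize`, `score`, `select`,
#' `mutants` and `compare`. Every intermediate artifact is written as
#' tab-separated text under the configured output directory together
#' with a manifest recording stages, parameters, outputs and their MD5
#' digests. Rerunning with an identical configuration reproduces
#' byte-identical primary outputs.
#'
#' @param cfg A [run_config()] (or list coerced through it), or a path
#'   to a YAML config file.
#' @param stages Character vector of stages to run; default all that the
#'   configuration supports.
#'
#' @return Invisibly, a list with the manifest data.frame and the main
#'   in-memory results (`normalized`, `enrichment`, `selections`,
#'   `fold_change`, `downregulated`, `group_summary`, `correlations`,
#'   `overlaps`).
#' @export
run_pipeline <- function(cfg, stages = NULL) {
  if (is.character(cfg) && length(cfg) == 1) cfg <- read_run_config(cfg)
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)

  all_stages <- c("simulate", "normalize", "score", "select", "mutants",
                  "compare")
  if (is.null(stages)) {
    stages <- all_stages
    if (!is.null(cfg$counts)) stages <- setdiff(stages, "simulate")
  }
  stages <- match.arg(stages, all_stages, several.ok = TRUE)

  ## Fail before any stage runs if a configured input path is missing.
  for (key in c("counts", "mutant_counts")) {
    p <- cfg[[key]]
    if (!is.null(p) && !file.exists(p))
      stop("configured input '", key, "' does not exist: ", p,
           call. = FALSE)
  }
  for (p in cfg$group_lists)
    if (!file.exists(p))
      stop("configured group list does not exist: ", p, call. = FALSE)
  if (!("simulate" %in% stages) && is.null(cfg$counts))
    stop("no `counts` input configured and simulate stage not requested",
         call. = FALSE)

  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  state <- list(log = file.path(cfg$output_dir, "run.log"))
  cat("", file = state$log)  # truncate
  manifest <- list()
  res <- list()
  base_roles <- c("early_total", "late_cytoplasmic", "late_nuclear")

  record <- function(stage, outputs, params = "") {
    digests <- unname(tools::md5sum(outputs))
    manifest[[stage]] <<- data.frame(
      stage = stage, outputs = paste(basename(outputs), collapse = ";"),
      md5 = paste(digests, collapse = ";"), params = params,
      stringsAsFactors = FALSE)
  }

  run_stage <- function(stage, fun) {
    log_line(state, "stage ", stage, ": start")
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      log_line(state, "stage ", stage, ": FAILED - ", conditionMessage(e))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_line(state, "stage ", stage, ": done")
    ok
  }

  base_counts <- NULL
  mutant_counts <- NULL

  if ("simulate" %in% stages) run_stage("simulate", function() {
    sim_cfg <- do.call(simulation_config,
                       c(cfg$simulate, list(seed = cfg$seed)[
                         !("seed" %in% names(cfg$simulate))]))
    base <- simulate_base_libraries(sim_cfg)
    pair_cfg <- sim_cfg
    pair_cfg$seed <- sim_cfg$seed + 1L  # independent stream for the pair
    pair <- simulate_mutant_pair(pair_cfg)
    p1 <- write_simulation(base, sim_cfg, cfg$output_dir, "base")
    p2 <- write_simulation(pair, pair_cfg, cfg$output_dir, "mutant")
    base_counts <<- base$counts
    mutant_counts <<- pair$counts
    res$truth <<- list(base = base$truth, mutant = pair$truth)
    record("simulate", c(p1, p2),
           sprintf("n_genes=%d seed=%d", sim_cfg$n_genes, sim_cfg$seed))
  })

  if (is.null(base_counts) && !is.null(cfg$counts)) {
    base_counts <- read_counts(cfg$counts, unlist(cfg$role_map))
    log_line(state, "read base counts from ", cfg$counts)
  }
  if (is.null(mutant_counts) && !is.null(cfg$mutant_counts)) {
    mutant_counts <- read_counts(cfg$mutant_counts,
                                 unlist(cfg$mutant_role_map))
    log_line(state, "read wt/mutant counts from ", cfg$mutant_counts)
  }

  if ("normalize" %in% stages) run_stage("normalize", function() {
    nm <- filter_low_counts(normalize_counts(base_counts),
                            min_count = cfg$min_count, roles = base_roles)
    dropped <- nrow(base_counts$counts) - nrow(nm$values)
    if (dropped > 0)
      log_line(state, dropped, " gene(s) removed by the low-count filter")
    path <- file.path(cfg$output_dir, "normalized_base.tsv")
    write_normalized_matrix(nm, path)
    res$normalized <<- nm
    record("normalize", c(path, paste0(path, ".meta.tsv")),
           sprintf("min_count=%g", cfg$min_count))
  })

  if ("score" %in% stages) run_stage("score", function() {
    et <- context_score(res$normalized)
    path <- file.path(cfg$output_dir, "enrichment_scores.tsv")
    utils::write.table(et, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    res$enrichment <<- et
    record("score", path)
  })

  if ("select" %in% stages) run_stage("select", function() {
    params <- cutoff_params(cfg$exponent, cfg$strict)
    outs <- character(0)
    res$selections <<- lapply(
      stats::setNames(context_labels(), context_labels()),
      function(ctx) {
        sel <- withCallingHandlers(
          select_enriched(res$enrichment, ctx, params),
          warning = function(w) {
            log_line(state, "select(", ctx, "): ", conditionMessage(w))
            invokeRestart("muffleWarning")
          })
        path <- file.path(cfg$output_dir,
                          sprintf("selection_%s.tsv", ctx))
        write_context_selection(sel, res$enrichment, path)
        lpath <- file.path(cfg$output_dir,
                           sprintf("selected_%s_genes.txt", ctx))
        write_gene_list(gene_set(ctx, sel$selected), lpath)
        outs <<- c(outs, path, paste0(path, ".summary.tsv"), lpath)
        sel
      })
    record("select", outs,
           sprintf("exponent=%g strict=%s", cfg$exponent, cfg$strict))
  })

  if ("mutants" %in% stages && !is.null(mutant_counts))
    run_stage("mutants", function() {
      nm <- normalize_counts(mutant_counts)  # joint wt+mutant factors
      fc <- fold_change(nm, nm, cfg$genotype, min_count = cfg$min_count,
                        pseudocount = cfg$pseudocount)
      down <- select_downregulated(fc, cfg$fold_threshold)
      groups <- pipeline_groups(res$selections, cfg$group_lists, state)
      fc_path <- file.path(cfg$output_dir,
                           sprintf("fold_change_%s.tsv", cfg$genotype))
      utils::write.table(fc, fc_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      down_path <- file.path(cfg$output_dir,
                             sprintf("downregulated_%s.txt", cfg$genotype))
      write_gene_list(gene_set(cfg$genotype, down$genes), down_path)
      outs <- c(fc_path, down_path)
      if (length(groups)) {
        summ <- group_foldchange_summary(fc, groups, cfg$fold_threshold)
        corr <- withCallingHandlers(
          group_correlations(nm, nm, groups, cfg$genotype,
                             min_count = cfg$min_count),
          warning = function(w) {
            log_line(state, "mutants: ", conditionMessage(w))
            invokeRestart("muffleWarning")
          })
        gs <- if (!is.null(corr))
          merge(summ,
                corr[, c("group", "genotype", "spearman_rho", "pearson_r")],
                by = c("group", "genotype"), all.x = TRUE)
        else summ
        gs <- gs[order(gs$group), , drop = FALSE]
        gpath <- file.path(cfg$output_dir, "group_summary.tsv")
        utils::write.table(gs, gpath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        outs <- c(outs, gpath)
        res$group_summary <<- gs
      }
      res$fold_change <<- fc
      res$downregulated <<- down
      record("mutants", outs,
             sprintf("threshold=%g pseudocount=%g", cfg$fold_threshold,
                     cfg$pseudocount))
    })

  if ("compare" %in% stages && !is.null(res$selections))
    run_stage("compare", function() {
      universe <- res$enrichment$gene_id
      sets <- lapply(res$selections, function(s)
        gene_set(s$context, s$selected))
      for (label in names(cfg$group_lists))
        sets[[label]] <- read_gene_list(cfg$group_lists[[label]], label)
      if (!is.null(res$downregulated))
        sets[[paste0("down_", cfg$genotype)]] <-
          gene_set(paste0("down_", cfg$genotype), res$downregulated$genes)
      tab <- withCallingHandlers(
        overlap_table(sets, universe),
        warning = function(w) {
          log_line(state, "compare: ", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      path <- file.path(cfg$output_dir, "overlaps.tsv")
      utils::write.table(tab, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      res$overlaps <<- tab
      record("compare", path)
    })

  manifest_df <- do.call(rbind, c(unname(manifest),
                                  list(make.row.names = FALSE)))
  cfg_flat <- unlist(unclass(cfg)[!vapply(cfg, is.null, logical(1))])
  utils::write.table(
    data.frame(key = names(cfg_flat), value = unname(cfg_flat)),
    file.path(cfg$output_dir, "config_resolved.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(manifest_df,
                     file.path(cfg$output_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line(state, "pipeline complete: ", nrow(manifest_df), " stage(s)")
  invisible(c(list(manifest = manifest_df), res))
}

## The six transcript groups of the depletion comparison: the four
## context selections computed from wt data plus externally supplied
## surveys (e.g. ovarian and purely-zygotic lists).
pipeline_groups <- function(selections, group_lists, state) {
  groups <- list()
  if (!is.null(selections)) {
    lab <- c(early = "early_syncytial", cytoplasmic = "cytoplasmic",
             nuclear = "nuclear", late = "late_blastoderm")
    for (ctx in names(selections))
      groups[[lab[[ctx]]]] <- selections[[ctx]]$selected
  }
  for (label in names(group_lists))
    groups[[label]] <- read_gene_list(group_lists[[label]], label)$members
  if (!length(groups))
    log_line(state, "mutants: no transcript groups available; ",
             "group summary skipped")
  groups
}
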