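## Shared fixture builders for the test suite. All fixtures are built in
## code; no files are shipped.

base_role_map <- c(E = "early_total", C = "late_cytoplasmic",
                   N = "late_nuclear")

## A count_matrix over the three base libraries from a genes x 3 matrix
## (columns E, C, N).
make_base_cm <- function(counts, gene_ids = sprintf("g%02d",
                                                    seq_len(nrow(counts)))) {
  counts <- matrix(as.integer(counts), nrow = length(gene_ids),
                   dimnames = list(gene_ids, names(base_role_map)))
  count_matrix(counts, base_role_map)
}

## A normalized_matrix with unit size factors, bypassing estimation, so
## that scoring tests control the normalized values exactly.
make_base_nm <- function(values, gene_ids = sprintf("g%02d",
                                                    seq_len(nrow(values)))) {
  values <- matrix(as.numeric(values), nrow = length(gene_ids),
                   dimnames = list(gene_ids, names(base_role_map)))
  structure(list(values = values, roles = base_role_map,
                 size_factors = stats::setNames(rep(1, 3),
                                                names(base_role_map)),
                 min_count_threshold = NA_real_),
            class = "normalized_matrix")
}

## wt/mutant pair as one jointly normalized matrix with unit factors.
make_pair_nm <- function(wt, mut, gene_ids = sprintf("g%02d",
                                                     seq_along(wt))) {
  values <- cbind(wt = as.numeric(wt), mut = as.numeric(mut))
  rownames(values) <- gene_ids
  structure(list(values = values,
                 roles = c(wt = "wt_whole", mut = "mutant_whole"),
                 size_factors = c(wt = 1, mut = 1),
                 min_count_threshold = NA_real_),
            class = "normalized_matrix")
}

## Direct evaluation of the cutoff selection rule, gene by gene,
## independent of the select_enriched() code path.
brute_select <- function(scores, exponent = 0.6, strict = TRUE) {
  cutoff <- min(scores) * (max(scores) / min(scores))^exponent
  keep <- vapply(scores,
                 function(s) if (strict) s > cutoff else s >= cutoff,
                 logical(1))
  sort(names(scores)[keep])
}

## Exhaustive hypergeometric upper tail: probability that a uniformly
## random |A|-subset of the universe contains at least k members of B.
enum_overlap_p <- function(k, universe, a_size, b_members) {
  draws <- utils::combn(universe, a_size, simplify = FALSE)
  mean(vapply(draws,
              function(d) length(intersect(d, b_members)) >= k,
              logical(1)))
}

## Write a gene-list file in tmp and return its path.
tmp_gene_list <- function(ids, label = "set") {
  path <- tempfile(fileext = ".txt")
  writeLines(c(paste0("# ", label), ids), path)
  path
}
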