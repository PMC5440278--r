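test_that("read_counts round-trips a well-formed file and validates input", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tE\tC\tN",
               "g1\t10\t0\t5",
               "g2\t3\t7\t2",
               "g3\t0\t0\t1"), path)
  cm <- read_counts(path, base_role_map)
  expect_s3_class(cm, "count_matrix")
  expect_equal(dim(cm), c(3L, 3L))
  expect_equal(rownames(cm$counts), c("g1", "g2", "g3"))
  expect_equal(cm$counts["g1", "N"], 5L)
  expect_equal(unname(cm$roles["N"]), "late_nuclear")

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tE\tC\tN", "g1\t1\t1\t1", "g1\t2\t2\t2"), dup)
  expect_error(read_counts(dup, base_role_map), "g1")

  neg <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tE\tC\tN", "g1\t1\t-4\t1"), neg)
  expect_error(read_counts(neg, base_role_map), "row 1.*library 'C'")

  unmapped <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tE\tC\tX", "g1\t1\t1\t1"), unmapped)
  expect_error(read_counts(unmapped, base_role_map), "X")
})

test_that("size factors follow the median-of-ratios definition", {
  ## identical libraries -> unit factors
  m <- make_base_cm(cbind(c(10, 4, 30), c(10, 4, 30), c(10, 4, 30)))
  expect_equal(unname(compute_size_factors(m)), c(1, 1, 1))

  ## two libraries, B = 2 x A: geometric mean of (a, 2a) is sqrt(2) a,
  ## so every per-gene ratio is 1/sqrt(2) in A and sqrt(2) in B
  counts <- matrix(c(10L, 20L, 4L, 8L, 30L, 60L), nrow = 3, byrow = TRUE,
                   dimnames = list(paste0("g", 1:3), c("A", "B")))
  cm <- count_matrix(counts, c(A = "wt_whole", B = "mutant_whole"))
  expect_equal(unname(compute_size_factors(cm)),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  ## a gene with a zero is excluded from the reference set: factors must
  ## equal a brute-force recomputation on the remaining genes
  counts2 <- rbind(g1 = c(10L, 20L), g2 = c(0L, 8L), g3 = c(30L, 60L),
                   g4 = c(5L, 9L))
  colnames(counts2) <- c("A", "B")
  cm2 <- count_matrix(counts2, c(A = "wt_whole", B = "mutant_whole"))
  ref <- counts2[rowSums(counts2 == 0) == 0, ]
  geo <- exp(rowMeans(log(ref)))
  expected <- apply(ref / geo, 2, median)
  expect_equal(compute_size_factors(cm2), expected, tolerance = 1e-12)

  ## no gene positive everywhere -> hard error
  all_zero <- make_base_cm(cbind(c(1, 0), c(0, 2), c(3, 1)))
  expect_error(compute_size_factors(all_zero), "pre-filter")
})

test_that("size factors agree with the reference median-of-ratios implementation", {
  set.seed(8)
  counts <- matrix(rnbinom(150, mu = 200, size = 5), nrow = 50,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   names(base_role_map)))
  counts[3, 1] <- 0L  # a zero-containing gene exercises reference exclusion
  cm <- count_matrix(counts, base_role_map)
  ref <- suppressMessages(
    DESeq2::estimateSizeFactorsForMatrix(counts))
  expect_equal(compute_size_factors(cm), ref, tolerance = 1e-9)
})

test_that("normalization divides by factors and round-trips", {
  m <- make_base_cm(cbind(c(10, 6), c(20, 2), c(8, 4)))
  nm1 <- normalize_counts(m, c(E = 1, C = 1, N = 1))
  expect_equal(nm1$values, m$counts * 1.0, ignore_attr = FALSE)

  nm2 <- normalize_counts(m, c(E = 2, C = 4, N = 1))
  expect_equal(unname(nm2$values["g01", ]), c(5, 5, 8))
  ## inverse property: value * factor recovers the raw count exactly
  recovered <- sweep(nm2$values, 2, nm2$size_factors, "*")
  expect_identical(round(recovered), round(m$counts * 1.0))

  expect_error(normalize_counts(m, c(E = 1, C = 0, N = 1)), "positive")
  expect_error(normalize_counts(m, c(1, 2)), "one size factor")
})

test_that("low-count filter keeps genes summing past the threshold", {
  ## 10 genes, 4 of which sum below 5 across the base libraries
  sums <- c(12, 3, 8, 0, 4.5, 20, 5, 2, 100, 6)
  values <- cbind(sums, 0, 0)  # all signal in one library; row sum exact
  nm <- make_base_nm(values)
  kept <- filter_low_counts(nm, 5)
  expect_equal(nrow(kept$values), 6L)
  expect_setequal(rownames(kept$values),
                  sprintf("g%02d", which(sums >= 5)))
  expect_equal(kept$min_count_threshold, 5)

  ## zero gene removed, min_count 0 keeps everything
  expect_false("g04" %in% rownames(kept$values))
  expect_equal(nrow(filter_low_counts(nm, 0)$values), 10L)

  ## filtering everything warns rather than errors
  expect_warning(filter_low_counts(nm, 1e6), "every gene")
})

test_that("filter is monotone and normalization is scale-equivariant", {
  set.seed(42)
  counts <- matrix(rpois(60, 50) + 1L, nrow = 20,
                   dimnames = list(sprintf("g%02d", 1:20),
                                   names(base_role_map)))
  cm <- count_matrix(counts, base_role_map)
  nm <- normalize_counts(cm)

  ## monotonicity: higher threshold selects a subset
  for (pair in list(c(0, 5), c(5, 20), c(20, 100))) {
    lo <- rownames(filter_low_counts(nm, pair[1])$values)
    hi <- rownames(filter_low_counts(nm, pair[2])$values)
    expect_true(all(hi %in% lo))
  }

  ## scale equivariance: tripling one library's counts triples its size
  ## factor relative to the others (the gene-wise geometric-mean
  ## reference absorbs a common 3^(1/m)), so normalized values change
  ## only by one global constant and enrichment scores not at all
  f0 <- compute_size_factors(cm)
  scaled <- counts
  scaled[, "C"] <- scaled[, "C"] * 3L
  cm3 <- count_matrix(scaled, base_role_map)
  f3 <- compute_size_factors(cm3)
  expect_equal(unname((f3["C"] / f3["E"]) / (f0["C"] / f0["E"])), 3,
               tolerance = 1e-12)
  expect_equal(unname(f3["N"] / f3["E"]), unname(f0["N"] / f0["E"]),
               tolerance = 1e-12)
  v0 <- normalize_counts(cm, f0)$values
  v3 <- normalize_counts(cm3, f3)$values
  expect_equal(v3 / v0, matrix(3^(1/3), nrow(v0), ncol(v0),
                               dimnames = dimnames(v0)),
               tolerance = 1e-12)
  score_cols <- c("E_y", "C_y", "N_y", "L_y")
  expect_equal(context_score(normalize_counts(cm3, f3))[score_cols],
               context_score(normalize_counts(cm, f0))[score_cols],
               tolerance = 1e-12)

  ## idempotence: renormalizing identical libraries gives unit factors
  ident <- make_base_cm(cbind(c(10, 4, 7), c(10, 4, 7), c(10, 4, 7)))
  expect_equal(unname(compute_size_factors(ident)), rep(1, 3),
               tolerance = 1e-9)
})

test_that("replicate libraries are averaged by role", {
  values <- cbind(E1 = c(10, 2), E2 = c(14, 4), C = c(6, 6), N = c(3, 9))
  rownames(values) <- c("g01", "g02")
  nm <- structure(list(
    values = values,
    roles = c(E1 = "early_total", E2 = "early_total",
              C = "late_cytoplasmic", N = "late_nuclear"),
    size_factors = c(E1 = 1, E2 = 1, C = 1, N = 1),
    min_count_threshold = NA_real_), class = "normalized_matrix")
  avg <- suppressMessages(average_roles(nm))
  expect_equal(unname(avg$values[, "early_total"]), c(12, 3))
  expect_message(average_roles(nm), "2 replicate libraries")
})

test_that("normalized matrices survive a write/read round trip", {
  m <- make_base_cm(matrix(c(10, 6, 20, 2, 8, 4), nrow = 2))
  nm <- filter_low_counts(normalize_counts(m, c(E = 2, C = 1, N = 1)), 1)
  path <- tempfile(fileext = ".tsv")
  write_normalized_matrix(nm, path)
  back <- read_normalized_matrix(path)
  expect_equal(back$values, nm$values)
  expect_equal(back$size_factors, nm$size_factors)
  expect_equal(back$roles, nm$roles)
  expect_equal(back$min_count_threshold, 1)
})
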