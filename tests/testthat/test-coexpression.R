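test_that("pearson correlation handles exact, missing and degenerate cases", {
  expect_equal(pearson_correlation(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson_correlation(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_equal(pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 5)),
               oracle_pearson(c(1, 2, 3, 4), c(1, 3, 2, 5)),
               tolerance = 1e-12)
  # pairwise-complete on the two surviving pairs (1,2) and (4,8)
  expect_equal(pearson_correlation(c(1, 2, NA, 4), c(2, NA, 1, 8)), 1.0)
  expect_true(is.na(pearson_correlation(c(1, NA, NA), c(NA, 1, 2))))
  expect_true(is.na(pearson_correlation(c(1, 1, 1), c(1, 2, 3))))
  expect_error(pearson_correlation(1:3, 1:4), "equal length")
})

test_that("correlation matches the sum-formula oracle under missingness", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(3:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    x[runif(n) < 0.2] <- NA
    y[runif(n) < 0.2] <- NA
    got <- pearson_correlation(x, y)
    want <- oracle_pearson(x, y)
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-12)
    # symmetry
    expect_identical(got, pearson_correlation(y, x))
  }
})

test_that("profile excludes cohorts, masks thin cells, flags missing genes", {
  cfg <- simulation_config(default_gene_specs(n_tcell = 4, n_null = 4),
                           "CD3E", n_cancer_types = 31,
                           n_samples_per_type = 30, seed = 21)
  cohorts <- simulate_pan_cancer(cfg)
  prof <- marker_correlation_profile(cohorts, "CD3E",
                                     excluded_types = "C05")
  expect_equal(ncol(prof$r), 30)
  expect_false("C05" %in% colnames(prof$r))
  # marker's own row is 1 wherever it varies
  expect_equal(unname(prof$r["CD3E", ]), rep(1, 30))

  # a gene absent from one cohort is missing there, computed elsewhere
  cohorts$C01 <- expression_cohort(
    cohorts$C01[rownames(cohorts$C01) != "CD2", ], "C01")
  prof <- marker_correlation_profile(cohorts, "CD3E")
  expect_true(is.na(prof$r["CD2", "C01"]))
  expect_false(anyNA(prof$r["CD2", colnames(prof$r) != "C01"]))

  # marker absent from a cohort is an error naming the cohort
  cohorts$C02 <- expression_cohort(
    cohorts$C02[rownames(cohorts$C02) != "CD3E", ], "C02")
  expect_error(marker_correlation_profile(cohorts, "CD3E"), "C02")

  # cells under min_samples go missing
  small <- simulate_pan_cancer(
    simulation_config(default_gene_specs(n_tcell = 2, n_null = 2), "CD3E",
                      n_cancer_types = 2, n_samples_per_type = 5, seed = 3))
  p <- marker_correlation_profile(small, "CD3E", min_samples = 10)
  expect_true(all(is.na(p$r)))
  p <- marker_correlation_profile(small, "CD3E", min_samples = 2)
  expect_false(anyNA(p$r))
})

test_that("profiles are invariant to per-gene positive affine transforms", {
  cfg <- simulation_config(default_gene_specs(n_tcell = 6, n_null = 6),
                           "CD3E", n_cancer_types = 3,
                           n_samples_per_type = 50, seed = 31)
  cohorts <- simulate_pan_cancer(cfg)
  set.seed(31)
  scaled <- lapply(cohorts, function(m) {
    a <- runif(nrow(m), 0.5, 3); b <- rnorm(nrow(m))
    expression_cohort(m * a + b, attr(m, "cancer_type"))
  })
  p1 <- marker_correlation_profile(cohorts, "CD3E")
  p2 <- marker_correlation_profile(scaled, "CD3E")
  expect_equal(p1$r, p2$r, tolerance = 1e-12)
})

test_that("median across types follows the even-count convention", {
  r <- rbind(A = c(0.2, 0.4, 0.9), B = c(0.1, NA, 0.3))
  colnames(r) <- c("T1", "T2", "T3")
  med <- median_across_types(r)
  expect_equal(unname(med["A"]), 0.4)
  expect_equal(unname(med["B"]), 0.2)
  r4 <- rbind(A = c(0.2, 0.4, 0.6, 0.9))
  colnames(r4) <- paste0("T", 1:4)
  expect_equal(unname(median_across_types(r4)["A"]), 0.5)

  # sort-based oracle on random rows with missingness
  set.seed(41)
  for (i in 1:50) {
    v <- runif(sample(1:9, 1), -1, 1)
    v[runif(length(v)) < 0.3] <- NA
    m <- matrix(v, 1, dimnames = list("G", NULL))
    got <- unname(median_across_types(m))
    s <- sort(v[!is.na(v)])
    want <- if (!length(s)) NA_real_
    else if (length(s) %% 2) s[(length(s) + 1) / 2]
    else mean(s[length(s) / 2 + 0:1])
    expect_equal(got, want)
  }
})

test_that("ranking is descending with symbol tie-break and missing last", {
  med <- c(B = 0.5, A = 0.9, C = 0.5, D = NA)
  rt <- rank_genes(med)
  expect_identical(rt$gene, c("A", "B", "C", "D"))
  expect_identical(rt$rank, c(1L, 2L, 3L, NA))
  expect_identical(rank_genes(c(X = 0.1))$rank, 1L)
  expect_error(rank_genes(c(A = NA_real_)), "non-missing")
})

test_that("estimated correlations converge to the planted closed form", {
  specs <- data.frame(gene = c("CD3E", "G"), lambda = c(1, 0.5),
                      kappa = c(0, 0.4), sigma = c(0, 0.7))
  cfg <- simulation_config(specs, "CD3E", n_cancer_types = 1,
                           n_samples_per_type = 50000, seed = 51)
  m <- simulate_cancer_cohort(cfg, "A", 51)
  want <- 0.5 / sqrt(0.25 + 0.16 + 0.49)
  expect_equal(pearson_correlation(m["G", ], m["CD3E", ]), want,
               tolerance = 0.01 / want)
})
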