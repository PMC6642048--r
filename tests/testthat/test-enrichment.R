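ranked_fixture <- function(n = 100, seed = 91) {
  set.seed(seed)
  data.frame(gene = sprintf("G%03d", seq_len(n)),
             score = sort(rnorm(n), decreasing = TRUE),
             stringsAsFactors = FALSE)
}

test_that("top and bottom sets reach the enrichment-score extremes", {
  rk <- ranked_fixture()
  for (p in c(0, 1, 2)) {
    expect_equal(enrichment_score(rk, rk$gene[1:7], p)$es, 1.0)
    expect_equal(enrichment_score(rk, rev(rk$gene)[1:7], p)$es, -1.0)
  }
  expect_error(enrichment_score(rk, c("ZZZ")), "empty intersection")
})

test_that("ES agrees with the quadratic-time oracle on random instances", {
  set.seed(92)
  for (i in 1:200) {
    n <- sample(10:50, 1)
    rk <- data.frame(gene = sprintf("g%02d", 1:n),
                     score = sort(rnorm(n), decreasing = TRUE))
    k <- sample(1:(n - 1), 1)
    gs <- sample(rk$gene, k)
    p <- sample(c(0, 0.5, 1, 2), 1)
    got <- enrichment_score(rk, gs, p)
    expect_equal(got$es, oracle_es(rk$score, rk$gene %in% gs, p),
                 tolerance = 1e-12)
    expect_true(abs(got$es) <= 1)
  }
})

test_that("ES matches the independent fgsea statistic", {
  rk <- ranked_fixture(80, seed = 93)
  stats <- stats::setNames(rk$score, rk$gene)
  set.seed(93)
  for (i in 1:20) {
    gs <- sample(rk$gene, 12)
    mine <- enrichment_score(rk, gs, weight_exponent = 1)$es
    ref <- fgsea::calcGseaStat(stats, selectedStats = which(rk$gene %in% gs),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("reversing an unweighted ranking negates the ES", {
  rk <- ranked_fixture(60, seed = 94)
  set.seed(94)
  gs <- sample(rk$gene, 9)
  fwd <- enrichment_score(rk, gs, 0)$es
  rev_rk <- data.frame(gene = rev(rk$gene), score = rev(rk$score))
  expect_equal(enrichment_score(rev_rk, gs, 0)$es, -fwd)
  # weighted case with mirrored scores
  mir <- data.frame(gene = rev(rk$gene), score = -rev(rk$score))
  expect_equal(enrichment_score(mir, gs, 1)$es,
               -enrichment_score(rk, gs, 1)$es)
})

test_that("permutation null is seeded, bounded, stable", {
  rk <- ranked_fixture(100, seed = 95)
  null1 <- permutation_null(rk, 10, n_perm = 1000, seed = 7)
  null2 <- permutation_null(rk, 10, n_perm = 1000, seed = 7)
  expect_identical(null1, null2)
  expect_length(null1, 1000)
  expect_true(all(null1 >= -1 & null1 <= 1))
  # positive-side mean |ES| stabilizes across seeds
  m1 <- mean(abs(permutation_null(rk, 10, 5000, seed = 1)[
    permutation_null(rk, 10, 5000, seed = 1) > 0]))
  m2 <- mean(abs(permutation_null(rk, 10, 5000, seed = 2)[
    permutation_null(rk, 10, 5000, seed = 2) > 0]))
  expect_lt(abs(m1 - m2), 0.02)
})

test_that("normalization, p-values and FDR behave by definition", {
  rk <- ranked_fixture(100, seed = 96)
  null <- permutation_null(rk, 10, 1000, seed = 8)
  pos_mean <- mean(null[null > 0])
  res <- normalize_and_fdr(c(SET = pos_mean), list(SET = null))
  expect_equal(res$nes, 1.0, tolerance = 1e-12)
  expect_s3_class(res, "gsea_result")
  # ES = 0 convention
  expect_equal(normalize_and_fdr(c(S = 0), list(S = null))$nes, 0)
  # degenerate all-negative null flagged with the p floor
  res <- normalize_and_fdr(c(S = 0.5), list(S = rep(-0.2, 100)))
  expect_true(res$degenerate)
  expect_equal(res$p, 1 / 101)
  expect_true(all(res$q >= 0 & res$q <= 1, na.rm = TRUE))
})

test_that("preranked run recovers a planted top set and ignores GMT order", {
  rk <- ranked_fixture(120, seed = 97)
  sets <- list(
    TOPSET = list(name = "TOPSET", description = "d", genes = rk$gene[1:15]),
    RND1 = list(name = "RND1", description = "d",
                genes = rk$gene[c(5, 30, 44, 61, 77, 90, 101, 118)]),
    RND2 = list(name = "RND2", description = "d",
                genes = rk$gene[c(12, 25, 38, 59, 72, 95, 110, 119)]))
  res <- suppressMessages(
    preranked_gsea(rk, structure(sets, class = "gene_set_collection"),
                   n_perm = 500, seed = 5))
  expect_identical(res$name[1], "TOPSET")
  expect_false(is.unsorted(rev(res$nes)))
  expect_true(res$nes[1] > 1.5 && res$q[1] < 0.05)

  shuffled <- structure(sets[c(3, 1, 2)], class = "gene_set_collection")
  res2 <- suppressMessages(preranked_gsea(rk, shuffled, n_perm = 500,
                                          seed = 5))
  expect_equal(res, res2)

  # sets outside the size window are dropped; none surviving is an error
  expect_error(suppressMessages(
    preranked_gsea(rk, structure(sets["RND1"], class = "gene_set_collection"),
                   min_size = 50)), "no gene sets")
})
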