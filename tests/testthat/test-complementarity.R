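test_that("score formulas evaluate and validate", {
  expect_equal(pdcd1_complementarity(1.0, 0.0), 1.0)
  expect_equal(pdcd1_complementarity(0.8, 0.8), 0.0)
  expect_equal(pdcd1_complementarity(0.9, 0.5), 0.36)
  expect_equal(pdcd1_complementarity(-0.9, 0.5), 0.36)
  expect_equal(joint_complementarity(1.0, 0.0, 0.0), 1.0)
  expect_equal(joint_complementarity(0.9, 0.3, 0.6), 0.27)
  expect_equal(joint_complementarity(0.8, 0.9, 0.1), -0.08)
  expect_error(pdcd1_complementarity(1.2, 0), "outside")
  expect_error(joint_complementarity(0.5, 0, -1.01), "outside")
  expect_true(is.na(pdcd1_complementarity(NA, 0.5)))
})

test_that("score bounds, monotonicity and degenerate reduction hold", {
  set.seed(61)
  tc <- runif(500, -1, 1); tp <- runif(500, -1, 1); ta <- runif(500, -1, 1)
  sp <- pdcd1_complementarity(tc, tp)
  sj <- joint_complementarity(tc, tp, ta)
  expect_true(all(sp >= -1 & sp <= 1))
  expect_true(all(sj >= -1 & sj <= 1))
  # joint equals the pairwise score iff CTLA4 contributes no smaller margin
  expect_true(all(sj <= sp + 1e-15))
  eq <- abs(ta) <= abs(tp)
  expect_equal(sj[eq], sp[eq])
  # reduction when rho_ta = rho_tp
  expect_equal(joint_complementarity(tc, tp, tp), sp)
  # with |rho_tp| fixed, score increases in |rho_tc| on a grid above |rho_tp|
  for (p in c(0, 0.3, 0.7)) {
    grid <- seq(p, 1, length.out = 25)
    expect_false(is.unsorted(pdcd1_complementarity(grid, p), strictly = TRUE))
  }
})

sim_profiles <- function(seed, n_types = 4, n = 300, extra = NULL) {
  specs <- rbind(default_gene_specs(n_tcell = 3, n_null = 5), extra)
  cfg <- simulation_config(specs, "CD3E", n_cancer_types = n_types,
                           n_samples_per_type = n, seed = seed)
  cohorts <- simulate_pan_cancer(cfg)
  lapply(c(CD3E = "CD3E", PDCD1 = "PDCD1", CTLA4 = "CTLA4"),
         function(m) marker_correlation_profile(cohorts, m))
}

test_that("complementarity table medians per-type scores and dual-ranks", {
  ps <- sim_profiles(71)
  tab <- complementarity_table(ps$CD3E, ps$PDCD1, score_kind = "pdcd1")
  expect_s3_class(tab, "complementarity_table")
  # per-type scores recompute from the two profiles, median matches
  g <- tab$gene[3]
  per_type <- pdcd1_complementarity(ps$CD3E$r[g, ], ps$PDCD1$r[g, ])
  expect_equal(unname(unlist(tab[3, startsWith(names(tab), "score.")])),
               unname(per_type))
  expect_equal(tab$median_score[3], median(per_type))
  # ranked descending with rank 1 the largest
  expect_false(is.unsorted(rev(tab$median_score)))
  expect_identical(tab$score_rank, seq_len(nrow(tab)))
  # PDCD1 never tops its own complementarity ranking (self-correlation 1)
  expect_lte(tab$median_score[tab$gene == "PDCD1"], 0)
  expect_gt(tab$score_rank[tab$gene == "PDCD1"], 1L)

  # planted high-lambda, kappa = 0 gene scores near rho^2 and leads nulls
  planted <- data.frame(gene = "PLANT", lambda = 0.9, kappa = 0,
                        sigma = 0.2)
  ps2 <- sim_profiles(72, extra = planted)
  tab2 <- complementarity_table(ps2$CD3E, ps2$PDCD1, score_kind = "pdcd1")
  rho <- 0.9 / sqrt(0.81 + 0.04)
  rho_tp <- median(abs(ps2$PDCD1$r["PLANT", ]))
  expect_equal(tab2$median_score[tab2$gene == "PLANT"],
               rho * (rho - rho_tp), tolerance = 0.1)
  expect_lt(tab2$score_rank[tab2$gene == "PLANT"],
            min(tab2$score_rank[startsWith(tab2$gene, "NULL")]))
})

test_that("single cancer type: median score equals the per-type score", {
  ps <- sim_profiles(73, n_types = 1)
  tab <- complementarity_table(ps$CD3E, ps$PDCD1, ps$CTLA4,
                               score_kind = "joint")
  expect_equal(tab$median_score, unname(tab[["score.C01"]]))
})

test_that("missing cells and mismatched type sets are handled", {
  ps <- sim_profiles(74)
  ps$PDCD1$r["CD2", "C02"] <- NA
  tab <- complementarity_table(ps$CD3E, ps$PDCD1, score_kind = "pdcd1")
  row <- tab[tab$gene == "CD2", ]
  expect_true(is.na(row[["score.C02"]]))
  # median over the remaining types, not zero-filled
  expect_equal(row$median_score,
               median(unlist(row[startsWith(names(tab), "score.")]),
                      na.rm = TRUE))
  ps$PDCD1$r <- ps$PDCD1$r[, -1]
  expect_error(complementarity_table(ps$CD3E, ps$PDCD1), "C01")
  expect_error(complementarity_table(ps$CD3E, ps$PDCD1, NULL, "joint"),
               "CTLA4")
})

test_that("positive-score filter is a faithful reporting view", {
  tab <- data.frame(gene = c("A", "B", "C"),
                    median_score = c(0.5, 0.0, -0.1))
  class(tab) <- c("complementarity_table", "data.frame")
  kept <- filter_positive_scores(tab)
  expect_identical(kept$gene, "A")
  allneg <- tab; allneg$median_score <- c(-1, -0.5, -0.2)
  expect_equal(nrow(filter_positive_scores(allneg)), 0)
  # brute-force comprehension oracle on random tables
  set.seed(81)
  scores <- round(runif(40, -1, 1), 2)
  rt <- data.frame(gene = sprintf("G%02d", 1:40), median_score = scores)
  expect_identical(filter_positive_scores(rt)$gene,
                   rt$gene[vapply(seq_len(40), function(i)
                     scores[i] > 0, TRUE)])
})
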