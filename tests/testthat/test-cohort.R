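test_that("the Fisher 2x2 p-value equals the hypergeometric tail oracle", {
  healthy <- fake_scores(rep(0L, 10), c(rep(45L, 8), rep(0L, 2)))
  cancer <- fake_scores(rep(0L, 10), c(rep(45L, 2), rep(0L, 8)), prefix = "C")
  ct <- classification_contrast(healthy, cancer)
  expect_equal(unname(ct$table_2x2),
               matrix(c(8, 2, 2, 8), 2, byrow = TRUE))
  expect_equal(ct$p_value, fisher_p_oracle(8, 2, 2, 8), tolerance = 1e-10)
})

test_that("identical label proportions give no association", {
  h <- fake_scores(rep(0L, 8), rep(c(45L, 0L), each = 4))
  c_ <- fake_scores(rep(0L, 8), rep(c(45L, 0L), each = 4), prefix = "C")
  ct <- classification_contrast(h, c_)
  expect_equal(ct$p_value, 1)
  expect_equal(ct$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(ct$proportions["healthy", ], ct$proportions["cancer", ])
})

test_that("zero cells fall back to a finite Haldane odds ratio", {
  h <- fake_scores(rep(0L, 6), rep(45L, 6))          # all SIG2+
  c_ <- fake_scores(rep(37L, 6), rep(0L, 6), prefix = "C")  # none SIG2+
  ct <- classification_contrast(h, c_)
  expect_true(is.finite(ct$odds_ratio))
  expect_equal(ct$odds_ratio_estimator, "haldane")
  expect_equal(ct$odds_ratio, (6.5 * 6.5) / (0.5 * 0.5))
  expect_error(classification_contrast(h[0, ], c_), "insufficient data")
})

test_that("SIG-count balance uses the SIG1-minus-SIG2 convention", {
  res <- fake_scores(c(0L, 10L, 3L), c(45L, 2L, 3L))
  bal <- sig_count_balance(res)
  expect_equal(unname(bal$differences), c(-45, 8, 0))
  expect_equal(sum(bal$bins$count), 3)
  expect_equal(bal$bins$count[bal$bins$midpoint == 8], 1)
  all_sig2 <- fake_scores(rep(0L, 4), rep(45L, 4))
  expect_true(all(sig_count_balance(all_sig2)$differences == -45))
})

test_that("survival correlation recovers a perfect inverse ranking", {
  res <- fake_scores(1:10)
  clin <- data.frame(sample_id = res$sample_id, os_months = 20 - (1:10) * 1.5,
                     os_event = TRUE)
  sc <- survival_correlation(res, clin)
  expect_equal(sc$rho, -1)
  expect_equal(sc$n, 10)
  const <- data.frame(sample_id = res$sample_id, os_months = 5, os_event = TRUE)
  expect_error(survival_correlation(res, const), "undefined correlation")
  expect_error(survival_correlation(res[1:2, ], clin), "insufficient data")
})

test_that("survival correlation matches the hand-coded Spearman oracle under noise", {
  set.seed(19)
  res <- fake_scores(sample(0:20, 40, replace = TRUE))
  clin <- data.frame(sample_id = res$sample_id,
                     os_months = rexp(40, 0.05), os_event = TRUE)
  sc <- survival_correlation(res, clin)
  o <- spearman_oracle(res$n_sig1, clin$os_months)
  expect_equal(sc$rho, o$rho, tolerance = 1e-10)
  expect_equal(sc$p_value, o$p_value, tolerance = 1e-6)
})

test_that("median split separates point-mass arms and rejects empty cases", {
  res <- fake_scores(c(rep(2L, 20), rep(12L, 20)))
  clin <- data.frame(sample_id = res$sample_id,
                     os_months = c(rep(2, 20), rep(1, 20)),
                     os_event = TRUE)
  ms <- median_split_survival(res, clin, endpoint = "os")
  expect_equal(ms$threshold, 7)
  expect_equal(ms$median_low, 2)
  expect_equal(ms$median_high, 1)
  expect_lt(ms$p_value, 1e-6)
  # KM estimates are valid non-increasing step functions in [0, 1]
  s <- ms$fit$surv
  expect_true(all(s >= 0 & s <= 1))
  for (arm_surv in split(s, rep(seq_along(ms$fit$strata), ms$fit$strata))) {
    expect_true(all(diff(arm_surv) <= 1e-12))
  }
  censored <- within(clin, os_event <- FALSE)
  expect_error(median_split_survival(res, censored), "no events")
  expect_error(median_split_survival(res, clin, threshold = 20),
               "degenerate split")
})

test_that("the log-rank statistic is invariant to arm relabeling", {
  set.seed(23)
  res <- fake_scores(sample(0:15, 60, replace = TRUE))
  clin <- data.frame(sample_id = res$sample_id,
                     os_months = rexp(60, 0.04), os_event = runif(60) < 0.8)
  ms <- median_split_survival(res, clin, threshold = 7)
  flipped <- res
  flipped$n_sig1 <- max(res$n_sig1) - res$n_sig1  # reverses the split exactly
  ms2 <- median_split_survival(flipped, clin,
                               threshold = max(res$n_sig1) - 7 - 1)
  expect_equal(ms$logrank_chisq, ms2$logrank_chisq, tolerance = 1e-8)
})

test_that("identical groups yield null volcano results", {
  set.seed(7)
  vals <- matrix(rlnorm(20 * 8, log(0.5), 1), 20, 8)
  tab <- toy_table(rbind(vals, vals), sprintf("tx %02d", 1:8))
  clr <- clr_transform(tab)
  res <- fake_scores(c(rep(2L, 20), rep(12L, 20)))
  res$sample_id <- rownames(tab$values)
  vd <- volcano_differential(clr, res)
  expect_true(all(abs(vd$effect) < 1e-12))
  expect_true(all(vd$q_value > 0.9))
})

test_that("a planted CLR shift is the top volcano hit with BH matching the oracle", {
  set.seed(8)
  n <- 100; p <- 10
  lo <- matrix(rlnorm(n * p, log(0.4), 0.8), n, p)
  hi <- matrix(rlnorm(n * p, log(0.4), 0.8), n, p)
  hi[, 3] <- hi[, 3] * exp(2)  # +2 CLR units (up to centering) in one taxon
  tab <- toy_table(rbind(lo, hi), sprintf("tx %02d", 1:p))
  clr <- clr_transform(tab)
  res <- fake_scores(c(rep(2L, n), rep(12L, n)))
  res$sample_id <- rownames(tab$values)
  vd <- volcano_differential(clr, res)
  expect_equal(vd$taxon[1], "tx 03")
  expect_lt(vd$q_value[1], 0.05)
  expect_equal(vd$effect[vd$taxon == "tx 03"],
               max(vd$effect), tolerance = 1e-12)
  expect_equal(sort(vd$q_value), sort(bh_oracle(vd$p_value)),
               tolerance = 1e-12)
  expect_true(all(vd$q_value >= vd$p_value - 1e-12))
  expect_error(volcano_differential(clr, res[c(1:2, 101:200), ]),
               "insufficient data")
})

test_that("dysbiosis subtypes follow the retention/oral-fraction rules", {
  cat_ <- default_sig_catalog()
  res <- fake_scores(
    n_sig1 = c(10L, 6L, 8L, 0L),
    n_sig2 = c(3L, 25L, 20L, 45L),
    oral = c(0L, 4L, 2L, 0L))
  st <- assign_subtype(res, cat_)
  expect_equal(st$subtype[1], "type2")        # retention 3/45, all gut SIG1
  expect_equal(st$subtype[2], "type1")        # retention 25/45, 4/6 oral
  expect_equal(st$subtype[3], "unclassified") # mixed configuration
  expect_equal(st$subtype[4], "unclassified") # eubiotic sample
  expect_equal(st$sig2_retention, c(3, 25, 20, 45) / 45)
  expect_equal(st$oral_fraction, c(0, 4 / 6, 2 / 8, 0))
  expect_equal(st$retention_class, c("collapsed", "retained", "retained",
                                     "retained"))
  expect_true(all(st$sig2_retention >= 0 & st$sig2_retention <= 1))
  expect_true(all(st$oral_fraction >= 0 & st$oral_fraction <= 1))
})
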