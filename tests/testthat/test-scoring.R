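test_that("presence counts follow the detection-threshold definition", {
  cat_ <- default_sig_catalog()
  sig1_in <- cat_$sig1$canonical[c(1, 2, 20)]   # 2 oral + 1 gut member
  sig2_in <- cat_$sig2$canonical[1:5]
  taxa <- c(sig1_in, sig2_in, "unrelated taxon", "akkermansia muciniphila SGB9226")
  vals <- rbind(c(0.4, 0.2, 1.5, 0.9, 0.8, 0.7, 0.6, 0.5, 3, 2.1),
                rep(0, 10))
  tab <- toy_table(vals, taxa)
  pres <- detect_presence(tab, cat_)
  expect_equal(pres$n_sig1, c(3L, 0L))
  expect_equal(pres$n_sig2, c(5L, 0L))
  expect_equal(pres$n_sig1_oral, c(2L, 0L))
  expect_equal(pres$akk_abundance, c(2.1, 0))
  expect_equal(pres$akk_detected, c(TRUE, FALSE))
  # raising the threshold above every abundance wipes the counts
  high <- detect_presence(tab, cat_, detection_threshold = 5)
  expect_equal(high$n_sig1, c(0L, 0L))
  expect_equal(high$n_sig2, c(0L, 0L))
  expect_false(any(high$akk_detected))
})

test_that("catalog taxa missing from the table count as undetected", {
  tab <- toy_table(matrix(c(1, 2), 1), c("some taxon", "other taxon"))
  pres <- detect_presence(tab, default_sig_catalog())
  expect_equal(pres$n_sig1, 0L)
  expect_equal(pres$n_sig2, 0L)
  expect_equal(pres$akk_abundance, 0)
})

test_that("counts are monotone non-increasing in the detection threshold", {
  set.seed(5)
  cat_ <- default_sig_catalog()
  vals <- matrix(rexp(20 * 82, rate = 2), 20, 82)
  vals[vals < 0.3] <- 0
  tab <- toy_table(vals / 2, c(cat_$sig1$canonical, cat_$sig2$canonical))
  prev <- NULL
  for (thr in c(0, 0.1, 0.25, 0.5, 1)) {
    cur <- detect_presence(tab, cat_, thr)
    if (!is.null(prev)) {
      expect_true(all(cur$n_sig1 <= prev$n_sig1))
      expect_true(all(cur$n_sig2 <= prev$n_sig2))
    }
    prev <- cur
  }
})

test_that("the SIG score formula matches hand arithmetic and its extremes", {
  expect_equal(compute_sig_score(0, 0), 0.5)
  expect_equal(compute_sig_score(37, 45), 0.5)
  expect_equal(compute_sig_score(37, 0), 0)
  expect_equal(compute_sig_score(0, 45), 1)
  expect_equal(compute_sig_score(10, 20), 0.5 * (20 / 45 - 10 / 37 + 1),
               tolerance = 1e-12)
  expect_error(compute_sig_score(-1, 0), "invalid input")
  expect_error(compute_sig_score(0, 46), "invalid input")
})

test_that("the score is exhaustively correct and strictly monotone in both counts", {
  grid <- expand.grid(n1 = 0:37, n2 = 0:45)
  s <- compute_sig_score(grid$n1, grid$n2)
  independent <- (grid$n2 / 45 - grid$n1 / 37 + 1) / 2
  expect_equal(s, independent, tolerance = 1e-12)
  expect_true(all(s >= 0 & s <= 1))
  m <- matrix(s, nrow = 38)  # rows n1, cols n2
  expect_true(all(diff(m) < 0))      # decreasing in n_sig1 at fixed n_sig2
  expect_true(all(diff(t(m)) > 0))   # increasing in n_sig2 at fixed n_sig1
})

test_that("classification honors the printed threshold inequalities", {
  cat_ <- default_sig_catalog()
  cases <- data.frame(
    score = c(0.50, 0.535, 0.791, 0.60, 0.60, 0.60, 0.60),
    akk   = c(1,    1,     1,     0,    5.0,  4.799, 1.0),
    det   = c(TRUE, TRUE,  TRUE,  FALSE, TRUE, TRUE, TRUE),
    final = c("SIG1+", "SIG1+", "SIG2+", "SIG1+", "SIG1+", "SIG2+", "SIG2+"),
    res   = c("not_gray", "not_gray", "not_gray", "akk_absent", "akk_over",
              "akk_normal", "akk_normal"),
    stringsAsFactors = FALSE
  )
  got <- classify_sample(cases$score, cases$akk, cases$det, cat_)
  expect_equal(got$final_label, cases$final)
  expect_equal(got$gray_resolution, cases$res)
  expect_error(classify_sample(1.2, 0, FALSE, cat_), "\\[0, 1\\]")
})

test_that("the three-way primary partition is exhaustive and exclusive on a score grid", {
  cat_ <- default_sig_catalog()
  grid <- (0:1000) / 1000
  got <- classify_sample(grid, rep(1, length(grid)), TRUE, cat_)
  expect_true(all(got$primary_label %in% c("SIG1+", "GRAY", "SIG2+")))
  expect_false(any(got$final_label == "GRAY"))
  expect_true(all((got$gray_resolution == "not_gray") ==
                    (got$primary_label != "GRAY")))
})

test_that("an all-zero cohort scores 0.5 and is dysbiotic by the primary rule", {
  tab <- toy_table(matrix(0, 3, 4),
                   c("tx one", "tx two", "tx three", "tx four"))
  res <- score_cohort(tab)
  expect_equal(res$score, rep(0.5, 3))
  # 0.5 <= 0.535, so the primary threshold already classifies; the gray-zone
  # arbiter is never consulted
  expect_equal(res$primary_label, rep("SIG1+", 3))
  expect_equal(res$gray_resolution, rep("not_gray", 3))
  expect_equal(res$final_label, rep("SIG1+", 3))
})

test_that("cohort scoring equals a brute-force oracle and is deterministic", {
  cfg <- simulation_config(seed = 31L, n_healthy = 5L, n_cancer = 5L)
  sim <- simulate_cohort(cfg)
  cat_ <- default_sig_catalog()
  got <- score_cohort(sim$table, cat_)
  oracle <- brute_force_score(sim$table, cat_)
  expect_equal(got$n_sig1, oracle$n_sig1)
  expect_equal(got$n_sig2, oracle$n_sig2)
  expect_equal(got$score, oracle$score, tolerance = 1e-12)
  expect_equal(got$primary_label, oracle$primary_label)
  expect_equal(got$final_label, oracle$final_label)
  expect_equal(got$gray_resolution, oracle$gray_resolution)
  expect_identical(got, score_cohort(sim$table, cat_))
})
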