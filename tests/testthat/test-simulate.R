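test_that("simulation is exactly reproducible from its seed", {
  cfg <- simulation_config(seed = 12L, n_healthy = 40L, n_cancer = 40L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$table$values, b$table$values)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_cohort(simulation_config(seed = 13L, n_healthy = 40L,
                                          n_cancer = 40L))
  expect_false(identical(a$table$values, c_$table$values))
})

test_that("config validation names the offending field", {
  expect_error(simulation_config(akk_mix_healthy = c(absent = 0.5,
                                                     normal = 0.2,
                                                     over = 0.1)),
               "akk_mix_healthy")
  expect_error(simulation_config(censor_rate = 1.4), "censor_rate")
  expect_error(simulation_config(followup_max = 0), "followup_max")
  expect_error(simulation_config(n_healthy = -1), "n_healthy")
})

test_that("an all-absent configuration composes with scoring as expected", {
  strata0 <- data.frame(name = c("a", "b", "c"),
                        p_sig1 = 0, p_sig2 = 0)
  cfg <- simulation_config(
    seed = 2L, n_healthy = 5L, n_cancer = 5L, strata = strata0,
    ecology_mix_healthy = c(a = 1, b = 0, c = 0),
    ecology_mix_cancer = c(a = 1, b = 0, c = 0),
    akk_mix_healthy = c(absent = 1, normal = 0, over = 0),
    akk_mix_cancer = c(absent = 1, normal = 0, over = 0),
    filler_taxa = 5L)
  sim <- simulate_cohort(cfg)
  res <- score_cohort(sim$table)
  expect_true(all(res$score == 0.5))
  # 0.5 falls at or below the dysbiotic threshold, so classification is
  # immediate and the Akkermansia arbiter is bypassed
  expect_true(all(res$primary_label == "SIG1+"))
  expect_true(all(res$gray_resolution == "not_gray"))
  expect_true(all(res$final_label == "SIG1+"))
})

test_that("empirical detection frequencies converge to configured prevalences", {
  strata_flat <- data.frame(name = c("x", "y", "z"),
                            p_sig1 = 0.3, p_sig2 = 0.6)
  cfg <- simulation_config(
    seed = 4L, n_healthy = 5000L, n_cancer = 0L, strata = strata_flat,
    ecology_mix_healthy = c(x = 1, y = 0, z = 0),
    ecology_mix_cancer = c(x = 1, y = 0, z = 0))
  sim <- simulate_cohort(cfg)
  cat_ <- default_sig_catalog()
  freq1 <- colMeans(sim$table$values[, cat_$sig1$canonical] > 0)
  freq2 <- colMeans(sim$table$values[, cat_$sig2$canonical] > 0)
  # binomial tolerance: 4 sd at n = 5000
  expect_true(all(abs(freq1 - 0.3) < 4 * sqrt(0.3 * 0.7 / 5000)))
  expect_true(all(abs(freq2 - 0.6) < 4 * sqrt(0.6 * 0.4 / 5000)))
})

test_that("Akkermansia strata respect their boundaries and survive renormalization", {
  cfg <- simulation_config(seed = 6L, n_healthy = 400L, n_cancer = 400L)
  sim <- simulate_cohort(cfg)
  akk_col <- grep("akkermansia", sim$table$taxa$canonical)
  akk <- sim$table$values[, akk_col]
  expect_equal(unname(akk), sim$truth$akk_abundance)
  expect_true(all(akk[sim$truth$akk_stratum == "absent"] == 0))
  nrm <- akk[sim$truth$akk_stratum == "normal"]
  expect_true(all(nrm > 0 & nrm <= 4.799))
  ovr <- akk[sim$truth$akk_stratum == "over"]
  expect_true(all(ovr > 4.799 & ovr <= 15))
  expect_true(all(rowSums(sim$table$values) <= 100))
})

test_that("scoring the written-and-reread table matches the generative truth", {
  cfg <- simulation_config(seed = 8L, n_healthy = 25L, n_cancer = 25L)
  sim <- simulate_cohort(cfg)
  prefix <- file.path(withr::local_tempdir(), "cohort")
  paths <- write_simulated_cohort(sim, prefix)
  back <- read_abundance_table(paths[["abundance"]])
  res <- score_cohort(back)
  expect_equal(res$n_sig1, sim$truth$n_sig1_true)
  expect_equal(res$n_sig2, sim$truth$n_sig2_true)
  direct <- score_cohort(sim$table)
  expect_equal(res$score, direct$score, tolerance = 1e-12)
  expect_equal(res$final_label, direct$final_label)
})

test_that("higher SIG1 burden shortens simulated survival; a null effect does not", {
  cfg <- simulation_config(seed = 14L, n_healthy = 0L, n_cancer = 500L)
  sim <- simulate_cohort(cfg)
  hi <- sim$truth$n_sig1_true > median(sim$truth$n_sig1_true)
  expect_lt(median(sim$clinical$os_months[hi]),
            median(sim$clinical$os_months[!hi]))
  cfg0 <- simulation_config(seed = 14L, n_healthy = 0L, n_cancer = 500L,
                            beta_sig1 = 0)
  sim0 <- simulate_cohort(cfg0)
  expect_true(all(sim0$truth$hazard == cfg0$baseline_hazard))
})

test_that("planted blocks carry their designed rank-correlation structure", {
  one <- planted_block_table(60, data.frame(size = 4, within_rho = 1),
                             seed = 5)
  rho <- cor(one$values, method = "spearman")
  expect_true(all(rho == 1))
  two <- planted_block_table(
    500, data.frame(size = c(3, 3), within_rho = 0.9), between_rho = -0.9,
    seed = 16)
  rho2 <- cor(two$values, method = "spearman")
  lab <- attr(two, "planted_blocks")
  cross <- rho2[lab == 1, lab == 2]
  expect_true(all(cross < -0.5))
  expect_identical(two$values,
                   planted_block_table(
                     500, data.frame(size = c(3, 3), within_rho = 0.9),
                     between_rho = -0.9, seed = 16)$values)
  expect_error(
    planted_block_table(50, data.frame(size = c(2, 2), within_rho = -0.9),
                        between_rho = 0.9, seed = 1),
    "positive.*semi-definite")
})
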