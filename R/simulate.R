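#' Exact label probabilities for a detection-probability stratum
#'
#' For independent per-taxon detection with probability `p_sig1` across the
#' SIG1 group and `p_sig2` across SIG2, the two counts are binomial and the
#' probability of each primary label (SIG1+/GRAY/SIG2+) follows exactly by
#' convolving the two binomial mass functions over the score grid.
#'
#' @param p_sig1,p_sig2 Per-taxon detection probabilities.
#' @param catalog A [sig_catalog()] (supplies group sizes and thresholds).
#' @return Named numeric vector `c(sig1, gray, sig2)` summing to 1.
#' @export
label_probabilities <- function(p_sig1, p_sig2,
                                catalog = default_sig_catalog()) {
  k1 <- nrow(catalog$sig1); k2 <- nrow(catalog$sig2)
  pmf1 <- stats::dbinom(0:k1, k1, p_sig1)
  pmf2 <- stats::dbinom(0:k2, k2, p_sig2)
  s <- outer(0:k1, 0:k2, function(a, b) 0.5 * (b / k2 - a / k1 + 1))
  joint <- outer(pmf1, pmf2)
  c(sig1 = sum(joint[s <= catalog$t_low]),
    gray = sum(joint[s > catalog$t_low & s < catalog$t_high]),
    sig2 = sum(joint[s >= catalog$t_high]))
}

#' Solve ecology-stratum weights against target label fractions
#'
#' Each simulated sample belongs to one of three ecology strata (eubiotic,
#' intermediate, dysbiotic), each with its own per-taxon detection
#' probabilities. Given target primary-label fractions for SIG1+ and SIG2+,
#' the mixing weights are obtained exactly by solving the 3 x 3 linear
#' system formed by the strata's [label_probabilities()] and the simplex
#' constraint.
#'
#' @param strata Data frame with columns `name`, `p_sig1`, `p_sig2`
#'   (3 rows).
#' @param target Named vector `c(sig1 = ..., sig2 = ...)` of target
#'   fractions.
#' @param catalog A [sig_catalog()].
#' @return Named weight vector on the 3 strata, summing to 1.
#' @export
calibrate_ecology_mix <- function(strata, target,
                                  catalog = default_sig_catalog()) {
  stopifnot(nrow(strata) == 3L)
  lp <- vapply(seq_len(3L), function(i) {
    label_probabilities(strata$p_sig1[i], strata$p_sig2[i], catalog)
  }, numeric(3))
  a <- rbind(lp["sig1", ], lp["sig2", ], rep(1, 3))
  b <- c(target[["sig1"]], target[["sig2"]], 1)
  w <- solve(a, b)
  if (any(w < -1e-9)) {
    stop("validation error: target label mix is not reachable as a convex ",
         "combination of the configured strata (weights ",
         paste(signif(w, 3), collapse = ", "), ")", call. = FALSE)
  }
  w <- pmax(w, 0); w <- w / sum(w)
  stats::setNames(w, strata$name)
}

.default_strata <- function() {
  data.frame(
    name = c("eubiotic", "intermediate", "dysbiotic"),
    p_sig1 = c(0.10, 0.26, 0.55),
    p_sig2 = c(0.80, 0.47, 0.15),
    stringsAsFactors = FALSE
  )
}

#' Build a validated simulation configuration
#'
#' The defaults describe the study-like conditions the generator emulates:
#' healthy subjects predominantly eubiotic (~68% SIG2+, ~4% SIG1+ primary
#' labels) and cancer patients predominantly dysbiotic (34% SIG1+, ~23%
#' SIG2+); an Akkermansia trichotomy per group (absent / normal in
#' (0, 4.799] / overabundant in (4.799, `akk_over_max`]); log-normal
#' abundances for detected taxa; 150 non-catalog filler taxa; and
#' exponential survival with hazard multiplied by `exp(beta_sig1)` per
#' detected SIG1 taxon (positive `beta_sig1` means higher SIG1 burden gives
#' shorter survival). Ecology-mixture weights are solved against the target
#' label fractions with [calibrate_ecology_mix()] unless supplied.
#'
#' @param seed Integer seed; every draw of the generator flows from it.
#' @param n_healthy,n_cancer Samples per group.
#' @param strata Ecology strata (data frame `name`, `p_sig1`, `p_sig2`).
#' @param target_mix_healthy,target_mix_cancer Target primary-label
#'   fractions `c(sig1 = , sig2 = )`.
#' @param ecology_mix_healthy,ecology_mix_cancer Explicit stratum weights;
#'   when `NULL` they are calibrated against the targets.
#' @param akk_mix_healthy,akk_mix_cancer Akkermansia stratum proportions
#'   `c(absent = , normal = , over = )`, summing to 1.
#' @param abundance_meanlog,abundance_sdlog Log-normal parameters for
#'   detected-taxon abundance (percent scale).
#' @param filler_taxa,filler_prevalence Count and detection probability of
#'   non-catalog background taxa.
#' @param beta_sig1 Log-hazard increment per detected SIG1 taxon.
#' @param baseline_hazard Events per month at zero SIG1 burden.
#' @param censor_rate Fraction subjected to random early censoring.
#' @param followup_max Administrative censoring horizon (months).
#' @param akk_over_max Upper bound of the overabundant Akkermansia stratum
#'   (percent).
#' @param catalog Catalog used for calibration.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_healthy = 2000L, n_cancer = 2000L,
                              strata = .default_strata(),
                              target_mix_healthy = c(sig1 = 0.04, sig2 = 0.68),
                              target_mix_cancer = c(sig1 = 0.34, sig2 = 0.23),
                              ecology_mix_healthy = NULL,
                              ecology_mix_cancer = NULL,
                              akk_mix_healthy = c(absent = 0.20, normal = 0.70, over = 0.10),
                              akk_mix_cancer = c(absent = 0.40, normal = 0.45, over = 0.15),
                              abundance_meanlog = log(0.2),
                              abundance_sdlog = 1,
                              filler_taxa = 150L,
                              filler_prevalence = 0.3,
                              beta_sig1 = 0.15,
                              baseline_hazard = 0.02,
                              censor_rate = 0.2,
                              followup_max = 60,
                              akk_over_max = 15,
                              catalog = default_sig_catalog()) {
  chk_prob <- function(x, field) {
    if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
      stop("validation error in field '", field, "': probabilities must lie ",
           "in [0, 1]", call. = FALSE)
    }
  }
  chk_prob(strata$p_sig1, "strata$p_sig1")
  chk_prob(strata$p_sig2, "strata$p_sig2")
  chk_prob(filler_prevalence, "filler_prevalence")
  chk_prob(censor_rate, "censor_rate")
  for (nm in c("akk_mix_healthy", "akk_mix_cancer")) {
    mix <- get(nm)
    chk_prob(mix, nm)
    if (abs(sum(mix) - 1) > 1e-8) {
      stop("validation error in field '", nm, "': proportions must sum to 1",
           call. = FALSE)
    }
  }
  if (n_healthy < 0 || n_cancer < 0) {
    stop("validation error in field 'n_healthy/n_cancer': counts must be >= 0",
         call. = FALSE)
  }
  if (followup_max <= 0) {
    stop("validation error in field 'followup_max': must be > 0", call. = FALSE)
  }
  if (baseline_hazard <= 0) {
    stop("validation error in field 'baseline_hazard': must be > 0",
         call. = FALSE)
  }
  if (is.null(ecology_mix_healthy)) {
    ecology_mix_healthy <- calibrate_ecology_mix(strata, target_mix_healthy,
                                                 catalog)
  }
  if (is.null(ecology_mix_cancer)) {
    ecology_mix_cancer <- calibrate_ecology_mix(strata, target_mix_cancer,
                                                catalog)
  }
  structure(
    list(seed = as.integer(seed), n_healthy = n_healthy, n_cancer = n_cancer,
         strata = strata,
         target_mix_healthy = target_mix_healthy,
         target_mix_cancer = target_mix_cancer,
         ecology_mix_healthy = ecology_mix_healthy,
         ecology_mix_cancer = ecology_mix_cancer,
         akk_mix_healthy = akk_mix_healthy, akk_mix_cancer = akk_mix_cancer,
         abundance_meanlog = abundance_meanlog,
         abundance_sdlog = abundance_sdlog,
         filler_taxa = as.integer(filler_taxa),
         filler_prevalence = filler_prevalence,
         beta_sig1 = beta_sig1, baseline_hazard = baseline_hazard,
         censor_rate = censor_rate, followup_max = followup_max,
         akk_over_max = akk_over_max),
    class = "simulation_config"
  )
}

#' Simulate a synthetic cohort with the structure the analysis assumes
#'
#' For each sample: an ecology stratum is drawn from the group's mixture;
#' every catalog taxon is detected independently with its stratum's
#' probability and detected taxa receive log-normal abundances; the
#' Akkermansia stratum is drawn from the group's trichotomy (absent = 0,
#' normal uniform on (0, 4.799], overabundant uniform on (4.799,
#' `akk_over_max`]); filler taxa are added; samples whose total would
#' exceed 100% have their non-Akkermansia portion scaled down (so the drawn
#' Akkermansia stratum is never crossed); survival times are exponential
#' with hazard `baseline_hazard * exp(beta_sig1 * n_sig1)`, censored
#' administratively at `followup_max` and randomly at rate `censor_rate`.
#' The whole cohort reproduces exactly from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param catalog A [sig_catalog()].
#' @return A list of class `simulated_cohort`: `table`
#'   (an [abundance_table()]), `clinical` (data frame `sample_id`, `group`,
#'   `cancer_type`, `os_months`, `os_event`, `pfs_months`, `pfs_event`),
#'   `truth` (per-sample generative record) and `config`.
#' @export
simulate_cohort <- function(config, catalog = default_sig_catalog()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  h <- .simulate_group(config$n_healthy, "H", "healthy",
                       config$ecology_mix_healthy, config$akk_mix_healthy,
                       config, catalog)
  c_ <- .simulate_group(config$n_cancer, "C", "cancer",
                        config$ecology_mix_cancer, config$akk_mix_cancer,
                        config, catalog)
  vals <- rbind(h$values, c_$values)
  taxa_names <- c(
    catalog$sig1$canonical, catalog$sig2$canonical,
    paste(catalog$akkermansia$canonical, catalog$akkermansia$sgb),
    sprintf("filler taxon %03d", seq_len(config$filler_taxa))
  )
  table <- abundance_table(vals, sample_ids = rownames(vals),
                           taxa = taxa_names)
  clinical <- rbind(h$clinical, c_$clinical)
  truth <- rbind(h$truth, c_$truth)
  rownames(clinical) <- rownames(truth) <- NULL
  structure(list(table = table, clinical = clinical, truth = truth,
                 config = config),
            class = "simulated_cohort")
}

.simulate_group <- function(n, prefix, group, ecology_mix, akk_mix,
                            config, catalog) {
  k1 <- nrow(catalog$sig1); k2 <- nrow(catalog$sig2)
  kf <- config$filler_taxa
  ids <- sprintf("%s%05d", prefix, seq_len(n))
  if (n == 0L) {
    empty <- matrix(numeric(), 0, k1 + k2 + 1 + kf)
    return(list(values = empty,
                clinical = data.frame(), truth = data.frame()))
  }
  stratum <- sample(names(ecology_mix), n, replace = TRUE, prob = ecology_mix)
  p1 <- config$strata$p_sig1[match(stratum, config$strata$name)]
  p2 <- config$strata$p_sig2[match(stratum, config$strata$name)]

  draw_block <- function(k, p) {
    det <- matrix(stats::runif(n * k), n, k) < p
    ab <- matrix(0, n, k)
    nd <- sum(det)
    ab[det] <- stats::rlnorm(nd, config$abundance_meanlog,
                             config$abundance_sdlog)
    ab
  }
  ab1 <- draw_block(k1, p1)
  ab2 <- draw_block(k2, p2)
  abf <- draw_block(kf, config$filler_prevalence)

  akk_stratum <- sample(names(akk_mix), n, replace = TRUE, prob = akk_mix)
  akk <- numeric(n)
  nrm <- akk_stratum == "normal"; ovr <- akk_stratum == "over"
  akk[nrm] <- stats::runif(sum(nrm), 0, catalog$akk_over_cutoff)
  akk[ovr] <- stats::runif(sum(ovr), catalog$akk_over_cutoff,
                           config$akk_over_max)

  other_total <- rowSums(ab1) + rowSums(ab2) + rowSums(abf)
  cap <- 99.5
  scale <- ifelse(other_total + akk > cap,
                  (cap - akk) / pmax(other_total, .Machine$double.eps), 1)
  ab1 <- ab1 * scale; ab2 <- ab2 * scale; abf <- abf * scale
  vals <- cbind(ab1, ab2, akk, abf)
  rownames(vals) <- ids

  n1_true <- as.integer(rowSums(ab1 > 0))
  n2_true <- as.integer(rowSums(ab2 > 0))
  hazard <- config$baseline_hazard * exp(config$beta_sig1 * n1_true)
  t_os <- stats::rexp(n, rate = hazard)
  t_pfs <- pmin(stats::rexp(n, rate = 1.6 * hazard), t_os)
  rand_cens <- ifelse(stats::runif(n) < config$censor_rate,
                      stats::runif(n) * config$followup_max, Inf)
  cens <- pmin(config$followup_max, rand_cens)
  cancer_types <- c(NSCLC = 556, RCC = 82, UC = 133, CRC = 182)
  clinical <- data.frame(
    sample_id = ids, group = group,
    cancer_type = if (group == "cancer") {
      sample(names(cancer_types), n, replace = TRUE,
             prob = cancer_types / sum(cancer_types))
    } else NA_character_,
    os_months = pmin(t_os, cens), os_event = t_os <= cens,
    pfs_months = pmin(t_pfs, cens), pfs_event = t_pfs <= cens,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    sample_id = ids, group = group, stratum = stratum,
    n_sig1_true = n1_true, n_sig2_true = n2_true,
    akk_stratum = akk_stratum, akk_abundance = akk, hazard = hazard,
    stringsAsFactors = FALSE
  )
  list(values = vals, clinical = clinical, truth = truth)
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("simulated_cohort:", sum(x$clinical$group == "healthy"), "healthy +",
      sum(x$clinical$group == "cancer"), "cancer samples,",
      ncol(x$table$values), "taxa (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Write a simulated cohort to plain-text files
#'
#' Writes `<prefix>_abundance.tsv` (merged-TSV dialect), `<prefix>_clinical.csv`
#' and `<prefix>_truth.json`.
#'
#' @param cohort A `simulated_cohort`.
#' @param prefix Output path prefix.
#' @return Invisibly, the three paths.
#' @export
write_simulated_cohort <- function(cohort, prefix) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  paths <- c(abundance = paste0(prefix, "_abundance.tsv"),
             clinical = paste0(prefix, "_clinical.csv"),
             truth = paste0(prefix, "_truth.json"))
  write_abundance_table(cohort$table, paths[["abundance"]])
  utils::write.csv(cohort$clinical, paths[["clinical"]], row.names = FALSE)
  jsonlite::write_json(cohort$truth, paths[["truth"]], digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Generate an abundance table with planted correlation blocks
#'
#' Draws taxa from a Gaussian copula whose correlation matrix has planted
#' blocks (`within_rho` inside each block, `between_rho` across blocks) and
#' maps the margins to log-normal relative abundances. Monotone mapping
#' preserves rank correlations, so the planted structure is what a
#' Spearman-based co-abundance network should recover. Abundances are kept
#' sub-compositional (per-sample totals well below 100%) so closure does
#' not distort the planted correlations.
#'
#' @param n_samples Number of samples.
#' @param blocks Data frame with columns `size` and `within_rho`, one row
#'   per block (or a list coercible to it).
#' @param between_rho Correlation between taxa of different blocks.
#' @param seed Integer seed.
#' @param meanlog,sdlog Log-normal margin parameters (percent scale).
#' @return An [abundance_table()] with attribute `planted_blocks` (integer
#'   block label per taxon).
#' @export
planted_block_table <- function(n_samples, blocks, between_rho = 0, seed = 1L,
                                meanlog = log(0.3), sdlog = 1) {
  blocks <- as.data.frame(blocks)
  if (any(abs(blocks$within_rho) > 1) || abs(between_rho) > 1) {
    stop("validation error: correlations must lie in [-1, 1]", call. = FALSE)
  }
  p <- sum(blocks$size)
  lab <- rep(seq_len(nrow(blocks)), blocks$size)
  sigma <- matrix(between_rho, p, p)
  for (b in seq_len(nrow(blocks))) {
    i <- which(lab == b)
    sigma[i, i] <- blocks$within_rho[b]
  }
  diag(sigma) <- 1
  e <- eigen(sigma, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    stop("validation error: target correlation matrix is not positive ",
         "semi-definite", call. = FALSE)
  }
  l <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), p)
  set.seed(seed)
  z <- matrix(stats::rnorm(n_samples * p), n_samples, p) %*% t(l)
  vals <- exp(meanlog + sdlog * z)
  over <- rowSums(vals) > 99
  if (any(over)) vals[over, ] <- vals[over, ] * (99 / rowSums(vals)[over])
  tab <- abundance_table(
    vals,
    sample_ids = sprintf("S%04d", seq_len(n_samples)),
    taxa = sprintf("block%02d taxon%02d", lab,
                   unlist(lapply(blocks$size, seq_len)))
  )
  attr(tab, "planted_blocks") <- lab
  tab
}
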