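#' Contrast classification outcomes between two cohorts
#'
#' Tabulates primary labels (SIG1+/GRAY/SIG2+) by group, collapses to a
#' 2 x 2 table of eubiotic (SIG2+) against everything else, and tests the
#' association with Fisher's exact test. The odds ratio is the conditional
#' maximum-likelihood estimate; when a zero cell makes it degenerate
#' (0 or infinite), a Haldane-Anscombe estimate (0.5 added to every cell)
#' is reported as the point estimate instead.
#'
#' @param healthy,cancer [score_cohort()] results for the two groups.
#' @param test `"2x2"` (default) tests the SIG2+-vs-not collapse; `"2x3"`
#'   runs the exact test on the full three-label table.
#' @return A list of class `classification_contrast`: `table_2x3`,
#'   `table_2x2`, `p_value`, `odds_ratio`, `odds_ratio_estimator`
#'   (`"conditional_mle"` or `"haldane"`), and `proportions` (per-group
#'   label fractions).
#' @export
classification_contrast <- function(healthy, cancer, test = c("2x2", "2x3")) {
  test <- match.arg(test)
  if (!nrow(healthy) || !nrow(cancer)) {
    stop("insufficient data: both groups must be non-empty", call. = FALSE)
  }
  lv <- c("SIG1+", "GRAY", "SIG2+")
  t23 <- rbind(
    healthy = table(factor(healthy$primary_label, levels = lv)),
    cancer  = table(factor(cancer$primary_label, levels = lv))
  )
  t22 <- cbind(`SIG2+` = t23[, "SIG2+"], other = rowSums(t23[, 1:2]))
  ft <- stats::fisher.test(if (test == "2x2") t22 else t23)
  or <- if (test == "2x2") unname(ft$estimate) else NA_real_
  estimator <- "conditional_mle"
  if (test == "2x2" && (!is.finite(or) || or == 0)) {
    h <- t22 + 0.5
    or <- (h[1, 1] * h[2, 2]) / (h[1, 2] * h[2, 1])
    estimator <- "haldane"
  }
  structure(
    list(table_2x3 = t23, table_2x2 = t22, p_value = ft$p.value,
         odds_ratio = or, odds_ratio_estimator = estimator, test = test,
         proportions = sweep(t23, 1, rowSums(t23), "/")),
    class = "classification_contrast"
  )
}

#' @export
print.classification_contrast <- function(x, ...) {
  cat("classification contrast (Fisher exact,", x$test, "):\n")
  print(x$table_2x3)
  cat("p-value:", format.pval(x$p_value), " odds ratio (SIG2+ vs other):",
      signif(x$odds_ratio, 4), "[", x$odds_ratio_estimator, "]\n")
  invisible(x)
}

#' SIG-count balance per sample
#'
#' The balance `n_sig1 - n_sig2` per sample (positive values = SIG1
#' dominance, the dysbiotic direction), with binned counts ready for
#' mirror-histogram plotting.
#'
#' @param results A [score_cohort()] result.
#' @param breaks Histogram breaks over the difference range (default unit
#'   bins spanning the observed differences).
#' @return A list: `differences` (named numeric vector), `bins` (data frame
#'   `midpoint`, `count`).
#' @export
sig_count_balance <- function(results, breaks = NULL) {
  if (!nrow(results)) stop("insufficient data: empty cohort", call. = FALSE)
  d <- results$n_sig1 - results$n_sig2
  names(d) <- results$sample_id
  if (is.null(breaks)) breaks <- seq(min(d) - 0.5, max(d) + 0.5, by = 1)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  list(differences = d,
       bins = data.frame(midpoint = h$mids, count = h$counts))
}

.merge_clinical <- function(results, clinical) {
  m <- merge(as.data.frame(results), clinical, by = "sample_id")
  if (!nrow(m)) {
    stop("insufficient data: no samples shared between scores and clinical ",
         "records", call. = FALSE)
  }
  m
}

#' Correlate SIG counts with survival time
#'
#' Spearman rank correlation between the per-sample count of detected SIG1
#' (or SIG2) taxa and overall-survival months, over every sample with a
#' recorded time. By default the recorded follow-up time is used regardless
#' of event status (mirroring a direct count-vs-survival reading);
#' `events_only = TRUE` restricts to samples with an observed death, the
#' statistically safer variant under censoring.
#'
#' @param results A [score_cohort()] result.
#' @param clinical Data frame with `sample_id`, `os_months`, `os_event`.
#' @param which `"sig1"` or `"sig2"`.
#' @param events_only Restrict to deceased subjects.
#' @return A list: `rho`, `p_value`, `n`.
#' @export
survival_correlation <- function(results, clinical, which = c("sig1", "sig2"),
                                 events_only = FALSE) {
  which <- match.arg(which)
  m <- .merge_clinical(results, clinical)
  m <- m[!is.na(m$os_months), , drop = FALSE]
  if (events_only) m <- m[isTRUE_vec(m$os_event), , drop = FALSE]
  if (nrow(m) < 3L) {
    stop("insufficient data: need >= 3 paired observations", call. = FALSE)
  }
  x <- if (which == "sig1") m$n_sig1 else m$n_sig2
  if (stats::sd(x) == 0 || stats::sd(m$os_months) == 0) {
    stop("undefined correlation: constant counts or constant times",
         call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(x, m$os_months, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(m))
}

#' Median-split Kaplan-Meier analysis on SIG1 burden
#'
#' Splits the cohort at a SIG1-count threshold (default: the cohort median
#' of `n_sig1`), arms `high` (`> threshold`) vs `low` (`<= threshold`),
#' estimates Kaplan-Meier curves with right censoring and compares the arms
#' with the log-rank test.
#'
#' @param results A [score_cohort()] result.
#' @param clinical Data frame with `sample_id` and, per endpoint,
#'   `os_months`/`os_event` or `pfs_months`/`pfs_event`.
#' @param endpoint `"os"` or `"pfs"`.
#' @param threshold SIG1-count cut-off; defaults to the cohort median.
#' @return A list of class `median_split_survival`: `threshold`, `fit`
#'   (a [survival::survfit] object), `logrank_chisq`, `p_value`, `n_high`,
#'   `n_low`, `median_high`, `median_low`.
#' @export
median_split_survival <- function(results, clinical,
                                  endpoint = c("os", "pfs"),
                                  threshold = NULL) {
  endpoint <- match.arg(endpoint)
  m <- .merge_clinical(results, clinical)
  tcol <- paste0(endpoint, "_months")
  ecol <- paste0(endpoint, "_event")
  if (!all(c(tcol, ecol) %in% names(m))) {
    stop("insufficient data: clinical table lacks ", tcol, "/", ecol,
         call. = FALSE)
  }
  m <- m[!is.na(m[[tcol]]) & !is.na(m[[ecol]]), , drop = FALSE]
  if (is.null(threshold)) threshold <- stats::median(m$n_sig1)
  arm <- factor(ifelse(m$n_sig1 > threshold, "high", "low"),
                levels = c("low", "high"))
  if (any(table(arm) == 0L)) {
    stop("degenerate split: one arm is empty at threshold ", threshold,
         call. = FALSE)
  }
  if (!any(as.logical(m[[ecol]]))) {
    stop("no events: log-rank test undefined on a fully censored cohort",
         call. = FALSE)
  }
  surv <- survival::Surv(m[[tcol]], as.logical(m[[ecol]]))
  fit <- survival::survfit(surv ~ arm)
  sd <- survival::survdiff(surv ~ arm)
  p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
  med <- summary(fit)$table[, "median"]
  structure(
    list(endpoint = endpoint, threshold = threshold, fit = fit,
         logrank_chisq = unname(sd$chisq), p_value = p,
         n_low = sum(arm == "low"), n_high = sum(arm == "high"),
         median_low = unname(med[["arm=low"]]),
         median_high = unname(med[["arm=high"]])),
    class = "median_split_survival"
  )
}

#' @export
print.median_split_survival <- function(x, ...) {
  cat("median-split survival (", x$endpoint, "), SIG1 threshold ",
      x$threshold, ":\n", sep = "")
  cat("  low arm n =", x$n_low, "(median", x$median_low, "mo ), high arm n =",
      x$n_high, "(median", x$median_high, "mo )\n")
  cat("  log-rank chisq =", signif(x$logrank_chisq, 4), ", p =",
      format.pval(x$p_value), "\n")
  invisible(x)
}

#' Rank-based differential abundance between SIG1-high and SIG1-low samples
#'
#' Splits the cohort at the median SIG1 count and, per taxon, compares CLR
#' abundances between the high and low groups with a two-sided Wilcoxon
#' rank-sum test; effects are CLR mean differences (high minus low) and
#' p-values are Benjamini-Hochberg adjusted across taxa. The output is the
#' volcano-plot table (effect vs adjusted significance).
#'
#' @param clr A [clr_transform()] result.
#' @param results A [score_cohort()] result covering the same samples.
#' @param threshold SIG1-count split point; defaults to the cohort median.
#' @param min_group Minimum samples per group (default 3).
#' @return A data frame: `taxon`, `effect`, `p_value`, `q_value`, sorted by
#'   `q_value`.
#' @export
volcano_differential <- function(clr, results, threshold = NULL,
                                 min_group = 3L) {
  stopifnot(inherits(clr, "clr_table"))
  idx <- match(results$sample_id, rownames(clr$values))
  if (any(is.na(idx))) {
    stop("alignment error: scored samples missing from the CLR table: ",
         paste(results$sample_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if (is.null(threshold)) threshold <- stats::median(results$n_sig1)
  hi <- results$n_sig1 > threshold
  if (sum(hi) < min_group || sum(!hi) < min_group) {
    stop("insufficient data: each group needs >= ", min_group, " samples",
         call. = FALSE)
  }
  v_hi <- clr$values[idx[hi], , drop = FALSE]
  v_lo <- clr$values[idx[!hi], , drop = FALSE]
  p <- vapply(seq_len(ncol(v_hi)), function(j) {
    suppressWarnings(
      stats::wilcox.test(v_hi[, j], v_lo[, j], exact = FALSE)$p.value)
  }, 0)
  p[is.na(p)] <- 1  # constant taxa carry no evidence
  out <- data.frame(
    taxon = colnames(clr$values),
    effect = colMeans(v_hi) - colMeans(v_lo),
    p_value = p,
    q_value = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$q_value, out$p_value), ]
}

#' Assign compositional dysbiosis subtypes to dysbiotic samples
#'
#' Dysbiotic (final SIG1+) samples are typed from two quantities: SIG2
#' retention (`n_sig2 / |SIG2|` — the fraction of the health-associated
#' consortium still detected) and the oral fraction (share of detected SIG1
#' taxa that belong to the oral-cavity sub-cluster). Type 1 dysbiosis is a
#' modest SIG2 loss with oral-species spillover (retention at or above
#' `retention_collapse`, oral fraction at or above `oral_min`); Type 2 is a
#' near-complete collapse of SIG2 with gut-anaerobe SIG1 dominance
#' (retention below `retention_collapse`, oral fraction below `oral_min`).
#' Mixed configurations, and all eubiotic samples, are `unclassified`. The
#' cutoffs operationalize a qualitative description and are deliberately
#' configurable.
#'
#' @param results A [score_cohort()] result (needs `n_sig1_oral`).
#' @param catalog A [sig_catalog()].
#' @param retention_collapse SIG2-retention below which the consortium
#'   counts as collapsed (default 0.15).
#' @param retention_modest Retention boundary between a "modest" loss and a
#'   largely retained consortium, used for the descriptive
#'   `retention_class` column (default 0.4).
#' @param oral_min Minimum oral fraction for oral spillover (default 0.5).
#' @return A data frame of class `dysbiosis_subtype`: `sample_id`,
#'   `subtype` (`"type1"`, `"type2"`, `"unclassified"`), `sig2_retention`,
#'   `oral_fraction`, `retention_class` (`"collapsed"`, `"modest"`,
#'   `"retained"`).
#' @export
assign_subtype <- function(results, catalog = default_sig_catalog(),
                           retention_collapse = 0.15, retention_modest = 0.4,
                           oral_min = 0.5) {
  retention <- results$n_sig2 / nrow(catalog$sig2)
  oral_frac <- results$n_sig1_oral / pmax(1, results$n_sig1)
  subtype <- rep("unclassified", nrow(results))
  dys <- results$final_label == "SIG1+"
  subtype[dys & retention < retention_collapse & oral_frac < oral_min] <- "type2"
  subtype[dys & retention >= retention_collapse & oral_frac >= oral_min] <- "type1"
  out <- data.frame(
    sample_id = results$sample_id,
    subtype = subtype,
    sig2_retention = retention,
    oral_fraction = oral_frac,
    retention_class = ifelse(retention < retention_collapse, "collapsed",
                      ifelse(retention < retention_modest, "modest",
                             "retained")),
    stringsAsFactors = FALSE
  )
  class(out) <- c("dysbiosis_subtype", "data.frame")
  out
}
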