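#' Count detected SIG taxa and measure Akkermansia abundance per sample
#'
#' A catalog taxon counts as detected in a sample when its relative
#' abundance is strictly greater than `detection_threshold` (default 0, so
#' any nonzero profiler call counts). Catalog members absent from the
#' table's taxon list are undetected. Matching is by canonical name, with a
#' fallback on the SGB code when both the catalog entry and a table taxon
#' carry one; the Akkermansia arbiter is matched SGB-first.
#'
#' @param table An [abundance_table()].
#' @param catalog A [sig_catalog()].
#' @param detection_threshold Relative abundance (percent) a taxon must
#'   exceed to count as detected; `>= 0`.
#' @return A data frame with one row per sample: `sample_id`, `n_sig1`,
#'   `n_sig2`, `n_sig1_oral` (detected SIG1 taxa from the oral sub-cluster),
#'   `akk_abundance` (percent, 0 when absent) and `akk_detected`.
#' @export
detect_presence <- function(table, catalog, detection_threshold = 0) {
  stopifnot(inherits(table, "abundance_table"), inherits(catalog, "sig_catalog"))
  if (!is.numeric(detection_threshold) || detection_threshold < 0) {
    stop("invalid parameter: detection_threshold must be >= 0", call. = FALSE)
  }
  vals <- table$values
  det <- vals > detection_threshold

  col_of <- function(entries) {
    idx <- match(entries$canonical, table$taxa$canonical)
    fallback <- which(is.na(idx) & !is.na(entries$sgb))
    if (length(fallback)) {
      idx[fallback] <- match(entries$sgb[fallback], table$taxa$sgb)
    }
    idx
  }
  count_over <- function(idx) {
    idx <- idx[!is.na(idx)]
    if (!length(idx)) return(rep(0L, nrow(vals)))
    as.integer(rowSums(det[, idx, drop = FALSE]))
  }
  idx1 <- col_of(catalog$sig1)
  idx2 <- col_of(catalog$sig2)
  oral <- idx1[catalog$sig1$subcluster == "oral"]

  akk_idx <- match(catalog$akkermansia$sgb, table$taxa$sgb)
  if (is.na(akk_idx)) {
    akk_idx <- match(catalog$akkermansia$canonical, table$taxa$canonical)
  }
  akk_ab <- if (is.na(akk_idx)) rep(0, nrow(vals)) else unname(vals[, akk_idx])

  data.frame(
    sample_id = rownames(vals),
    n_sig1 = count_over(idx1),
    n_sig2 = count_over(idx2),
    n_sig1_oral = count_over(oral),
    akk_abundance = akk_ab,
    akk_detected = akk_ab > detection_threshold,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Compute the SIG score
#'
#' `S = ((n_sig2 / |SIG2|) - (n_sig1 / |SIG1|) + 1) / 2`, an unweighted
#' balance of detected health-associated against detected
#' dysbiosis-associated taxa, bounded in `[0, 1]`: 0 when every SIG1 species
#' and no SIG2 species is detected, 1 in the opposite extreme, and exactly
#' 0.5 when the two detection fractions coincide (including the all-absent
#' case).
#'
#' @param n_sig1,n_sig2 Integer counts of detected taxa (vectorized).
#' @param sig1_size,sig2_size Catalog group sizes (defaults 37 and 45).
#' @return Numeric score(s) in `[0, 1]`.
#' @export
compute_sig_score <- function(n_sig1, n_sig2, sig1_size = 37L, sig2_size = 45L) {
  if (any(is.na(n_sig1)) || any(is.na(n_sig2)) ||
      any(n_sig1 < 0) || any(n_sig1 > sig1_size) ||
      any(n_sig2 < 0) || any(n_sig2 > sig2_size)) {
    stop("invalid input: counts must lie in [0, ", sig1_size, "] and [0, ",
         sig2_size, "]", call. = FALSE)
  }
  0.5 * (n_sig2 / sig2_size - n_sig1 / sig1_size + 1)
}

#' Classify a sample from its SIG score
#'
#' Scores at or below `t_low` are dysbiotic (SIG1+); scores at or above
#' `t_high` are eubiotic (SIG2+); scores strictly between fall in the gray
#' zone and are arbitrated by *Akkermansia muciniphila*: samples lacking it,
#' or carrying it above the overabundance cutoff (strictly greater than
#' 4.799% by default), resolve to SIG1+, while samples with "normal" levels
#' resolve to SIG2+.
#'
#' @param score SIG score(s) in `[0, 1]`.
#' @param akk_abundance Akkermansia relative abundance (percent), same
#'   length.
#' @param akk_detected Logical; whether Akkermansia was detected.
#' @param catalog A [sig_catalog()] supplying `t_low`, `t_high` and
#'   `akk_over_cutoff`.
#' @return A data frame with columns `primary_label` (`"SIG1+"`, `"GRAY"`,
#'   `"SIG2+"`), `final_label` (never `"GRAY"`), and `gray_resolution`
#'   (`"not_gray"`, `"akk_absent"`, `"akk_over"`, `"akk_normal"`).
#' @export
classify_sample <- function(score, akk_abundance, akk_detected,
                            catalog = default_sig_catalog()) {
  if (any(is.na(score)) || any(score < 0) || any(score > 1)) {
    stop("invalid input: score must lie in [0, 1]", call. = FALSE)
  }
  n <- length(score)
  akk_abundance <- rep_len(akk_abundance, n)
  akk_detected <- rep_len(akk_detected, n)
  primary <- ifelse(score <= catalog$t_low, "SIG1+",
             ifelse(score >= catalog$t_high, "SIG2+", "GRAY"))
  resolution <- rep("not_gray", n)
  final <- primary
  gray <- primary == "GRAY"
  absent <- gray & !akk_detected
  over <- gray & akk_detected & akk_abundance > catalog$akk_over_cutoff
  normal <- gray & akk_detected & !(akk_abundance > catalog$akk_over_cutoff)
  resolution[absent] <- "akk_absent"
  resolution[over] <- "akk_over"
  resolution[normal] <- "akk_normal"
  final[absent | over] <- "SIG1+"
  final[normal] <- "SIG2+"
  data.frame(primary_label = primary, final_label = final,
             gray_resolution = resolution, stringsAsFactors = FALSE)
}

#' Score and classify every sample of a cohort
#'
#' Composes [detect_presence()], [compute_sig_score()] and
#' [classify_sample()] over all samples of an abundance table. The result is
#' deterministic and in table order.
#'
#' @inheritParams detect_presence
#' @return A data frame of class `sig_score_result` with columns
#'   `sample_id`, `n_sig1`, `n_sig2`, `n_sig1_oral`, `score`,
#'   `primary_label`, `final_label`, `gray_resolution`, `akk_abundance`.
#' @export
score_cohort <- function(table, catalog = default_sig_catalog(),
                         detection_threshold = 0) {
  pres <- detect_presence(table, catalog, detection_threshold)
  score <- compute_sig_score(pres$n_sig1, pres$n_sig2,
                             sig1_size = nrow(catalog$sig1),
                             sig2_size = nrow(catalog$sig2))
  cls <- classify_sample(score, pres$akk_abundance, pres$akk_detected, catalog)
  out <- data.frame(
    sample_id = pres$sample_id,
    n_sig1 = pres$n_sig1, n_sig2 = pres$n_sig2,
    n_sig1_oral = pres$n_sig1_oral,
    score = score,
    primary_label = cls$primary_label,
    final_label = cls$final_label,
    gray_resolution = cls$gray_resolution,
    akk_abundance = pres$akk_abundance,
    stringsAsFactors = FALSE
  )
  class(out) <- c("sig_score_result", "data.frame")
  out
}
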