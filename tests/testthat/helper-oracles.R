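# Independent oracles, deliberately coded without reusing the package's
# (or stats's) implementation paths they are checked against.

# Two-sided Fisher exact p for rbind(c(a, b), c(c, d)) as the sum of
# hypergeometric probabilities not exceeding the observed one.
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0, k - n):min(k, m)
  probs <- exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  p_obs <- exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Benjamini-Hochberg step-up, written directly from the definition:
# q_(i) = min_{j >= i} p_(j) * n / j on the ascending order statistics.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}

# Spearman rho via explicit ranking + the Pearson product-moment formula,
# with the large-sample t approximation for the two-sided p-value.
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  n <- length(x)
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  list(rho = r, p_value = 2 * pt(-abs(t_stat), df = n - 2))
}

# Brute-force cohort scorer: per-sample loops and direct string matching,
# no matrix shortcuts shared with the implementation.
brute_force_score <- function(table, catalog, detection_threshold = 0) {
  out <- NULL
  for (i in seq_len(nrow(table$values))) {
    n1 <- 0L; n2 <- 0L
    for (tx in catalog$sig1$canonical) {
      j <- which(table$taxa$canonical == tx)
      if (length(j) == 1 && table$values[i, j] > detection_threshold) n1 <- n1 + 1L
    }
    for (tx in catalog$sig2$canonical) {
      j <- which(table$taxa$canonical == tx)
      if (length(j) == 1 && table$values[i, j] > detection_threshold) n2 <- n2 + 1L
    }
    j <- which(table$taxa$sgb == catalog$akkermansia$sgb)
    if (length(j) != 1) {
      j <- which(table$taxa$canonical == catalog$akkermansia$canonical)
    }
    akk <- if (length(j) == 1) table$values[i, j] else 0
    s <- 0.5 * (n2 / nrow(catalog$sig2) - n1 / nrow(catalog$sig1) + 1)
    if (s <= catalog$t_low) {
      lab <- c("SIG1+", "SIG1+", "not_gray")
    } else if (s >= catalog$t_high) {
      lab <- c("SIG2+", "SIG2+", "not_gray")
    } else if (!(akk > detection_threshold)) {
      lab <- c("GRAY", "SIG1+", "akk_absent")
    } else if (akk > catalog$akk_over_cutoff) {
      lab <- c("GRAY", "SIG1+", "akk_over")
    } else {
      lab <- c("GRAY", "SIG2+", "akk_normal")
    }
    out <- rbind(out, data.frame(
      sample_id = rownames(table$values)[i], n_sig1 = n1, n_sig2 = n2,
      score = s, primary_label = lab[1], final_label = lab[2],
      gray_resolution = lab[3], akk_abundance = akk,
      stringsAsFactors = FALSE))
  }
  out
}

# Adjusted Rand index from the pair-counting definition.
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_index <- sum_a * sum_b / n
  (sum_ij - exp_index) / ((sum_a + sum_b) / 2 - exp_index)
}

# Small toy catalog (sizes relaxed) used where exercising the full default
# catalog would obscure the arithmetic being checked.
toy_catalog <- function() {
  sig_catalog(
    sig1 = c("Veillonella parvula", "Streptococcus mitis",
             "Hungatella hathewayi", "Clostridium innocuum"),
    sig2 = c("Faecalibacterium prausnitzii", "Eubacterium rectale",
             "Coprococcus comes"),
    sig1_oral = c("Veillonella parvula", "Streptococcus mitis"),
    expect_sizes = NULL
  )
}

# Abundance table fixture built in code: samples in rows, percent values.
toy_table <- function(values, taxa) {
  abundance_table(values,
                  sample_ids = sprintf("S%02d", seq_len(nrow(values))),
                  taxa = taxa)
}

# Hand-built score-result frames for exercising the cohort statistics with
# exactly chosen counts and labels.
fake_scores <- function(n_sig1, n_sig2 = NULL, label = NULL, oral = 0L,
                        prefix = "S") {
  n <- length(n_sig1)
  if (is.null(n_sig2)) n_sig2 <- rep(0L, n)
  score <- compute_sig_score(n_sig1, n_sig2)
  if (is.null(label)) {
    label <- ifelse(score <= 0.535, "SIG1+",
             ifelse(score >= 0.791, "SIG2+", "GRAY"))
  }
  out <- data.frame(
    sample_id = sprintf("%s%03d", prefix, seq_len(n)),
    n_sig1 = n_sig1, n_sig2 = n_sig2, n_sig1_oral = rep_len(oral, n),
    score = score, primary_label = label,
    final_label = ifelse(label == "GRAY", "SIG1+", label),
    gray_resolution = ifelse(label == "GRAY", "akk_absent", "not_gray"),
    akk_abundance = 0, stringsAsFactors = FALSE)
  class(out) <- c("sig_score_result", "data.frame")
  out
}
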