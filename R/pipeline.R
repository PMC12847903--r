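#' Run the full retrospective dysbiosis analysis on a cohort
#'
#' Chains every analysis stage over a scored cohort: per-sample SIG scoring
#' and classification; the healthy-vs-cancer classification contrast;
#' Spearman correlations of SIG1 and SIG2 counts with overall survival;
#' median-split Kaplan-Meier comparisons (overall and progression-free
#' survival); rank-based differential abundance between SIG1-high and
#' SIG1-low samples per group; and compositional dysbiosis subtyping. When
#' no clinical table is supplied, only the scoring and subtype stages run
#' and the skipped stages are recorded in `notes`. The report is a pure
#' function of its inputs and parameters; identical invocations produce
#' identical numeric content.
#'
#' @param table An [abundance_table()].
#' @param clinical Optional data frame (`sample_id`, `group`, `cancer_type`,
#'   `os_months`, `os_event`, `pfs_months`, `pfs_event`). Its `sample_id`
#'   set must match the table's samples exactly.
#' @param catalog A [sig_catalog()].
#' @param detection_threshold Passed to [score_cohort()].
#' @param pseudocount Passed to [clr_transform()].
#' @param subtype_params List with `retention_collapse`, `retention_modest`,
#'   `oral_min` overrides for [assign_subtype()].
#' @return A list of class `analysis_report` with components `scores`,
#'   `contrast`, `correlation_sig1`, `correlation_sig2`, `median_split_os`,
#'   `median_split_pfs`, `volcano` (per group), `subtypes`, `notes`, and
#'   `provenance` (catalog checksum, parameters, package version).
#' @export
run_retrospective_analysis <- function(table, clinical = NULL,
                                       catalog = default_sig_catalog(),
                                       detection_threshold = 0,
                                       pseudocount = 1e-5,
                                       subtype_params = list()) {
  stopifnot(inherits(table, "abundance_table"))
  notes <- character()
  if (!is.null(clinical)) {
    orphans_c <- setdiff(clinical$sample_id, rownames(table$values))
    orphans_t <- setdiff(rownames(table$values), clinical$sample_id)
    if (length(orphans_c) || length(orphans_t)) {
      stop("alignment error: sample ids do not match; ",
           "clinical-only: [", paste(orphans_c, collapse = ", "),
           "]; table-only: [", paste(orphans_t, collapse = ", "), "]",
           call. = FALSE)
    }
  }
  scores <- score_cohort(table, catalog, detection_threshold)
  sp <- utils::modifyList(
    list(retention_collapse = 0.15, retention_modest = 0.4, oral_min = 0.5),
    subtype_params)
  subtypes <- assign_subtype(scores, catalog,
                             retention_collapse = sp$retention_collapse,
                             retention_modest = sp$retention_modest,
                             oral_min = sp$oral_min)
  report <- list(scores = scores, subtypes = subtypes,
                 balance = sig_count_balance(scores))

  if (is.null(clinical)) {
    notes <- c(notes, "no clinical table: contrast, survival and volcano stages skipped")
  } else {
    by_group <- split(scores, clinical$group[match(scores$sample_id,
                                                   clinical$sample_id)])
    if (all(c("healthy", "cancer") %in% names(by_group))) {
      report$contrast <- classification_contrast(by_group$healthy,
                                                 by_group$cancer)
    } else {
      notes <- c(notes, "single-group cohort: classification contrast skipped")
    }
    has_surv <- "os_months" %in% names(clinical) &&
      any(!is.na(clinical$os_months))
    if (has_surv) {
      surv_scores <- if ("cancer" %in% names(by_group)) by_group$cancer else scores
      report$correlation_sig1 <- survival_correlation(surv_scores, clinical,
                                                      which = "sig1")
      report$correlation_sig2 <- survival_correlation(surv_scores, clinical,
                                                      which = "sig2")
      report$median_split_os <- median_split_survival(surv_scores, clinical,
                                                      endpoint = "os")
      if ("pfs_months" %in% names(clinical) &&
          any(!is.na(clinical$pfs_months))) {
        report$median_split_pfs <- median_split_survival(surv_scores, clinical,
                                                         endpoint = "pfs")
      }
    } else {
      notes <- c(notes, "no survival times: correlation and median-split stages skipped")
    }
    clr <- clr_transform(table, pseudocount)
    report$volcano <- lapply(by_group, function(gr) {
      if (nrow(gr) >= 6L && length(unique(gr$n_sig1)) > 1L) {
        tryCatch(volcano_differential(clr, gr), error = function(e) NULL)
      } else NULL
    })
  }

  report$notes <- notes
  report$provenance <- list(
    catalog_md5 = .catalog_checksum(catalog),
    parameters = list(detection_threshold = detection_threshold,
                      pseudocount = pseudocount, subtype_params = sp,
                      t_low = catalog$t_low, t_high = catalog$t_high,
                      akk_over_cutoff = catalog$akk_over_cutoff),
    n_samples = nrow(table$values),
    package_version = as.character(utils::packageVersion("sigscore"))
  )
  class(report) <- "analysis_report"
  report
}

.catalog_checksum <- function(catalog) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_sig_catalog(catalog, tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report over", x$provenance$n_samples, "samples\n")
  tab <- table(x$scores$final_label)
  cat("  final labels:", paste(names(tab), tab, sep = " = ", collapse = ", "),
      "\n")
  if (!is.null(x$contrast)) {
    cat("  contrast p =", format.pval(x$contrast$p_value), "\n")
  }
  if (!is.null(x$correlation_sig1)) {
    cat("  SIG1 count vs OS: rho =", signif(x$correlation_sig1$rho, 3),
        ", p =", format.pval(x$correlation_sig1$p_value), "\n")
  }
  if (!is.null(x$median_split_os)) {
    cat("  median split (OS) at n_sig1 >", x$median_split_os$threshold,
        ": log-rank p =", format.pval(x$median_split_os$p_value), "\n")
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Write an analysis report to a directory of plain-text files
#'
#' Writes the score table, subtype table, contrast tables, volcano tables
#' (TSV), survival/correlation summaries and provenance (JSON).
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_analysis_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wt <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wt(report$scores, "scores.tsv")
  wt(report$subtypes, "subtypes.tsv")
  if (!is.null(report$contrast)) {
    wt(as.data.frame.matrix(report$contrast$table_2x3), "contrast_2x3.tsv")
  }
  for (g in names(report$volcano)) {
    if (!is.null(report$volcano[[g]])) {
      wt(report$volcano[[g]], paste0("volcano_", g, ".tsv"))
    }
  }
  summaries <- list(
    contrast = if (!is.null(report$contrast)) {
      list(p_value = report$contrast$p_value,
           odds_ratio = report$contrast$odds_ratio)
    },
    correlation_sig1 = report$correlation_sig1,
    correlation_sig2 = report$correlation_sig2,
    median_split_os = if (!is.null(report$median_split_os)) {
      report$median_split_os[c("threshold", "logrank_chisq", "p_value",
                               "median_low", "median_high")]
    },
    median_split_pfs = if (!is.null(report$median_split_pfs)) {
      report$median_split_pfs[c("threshold", "logrank_chisq", "p_value",
                                "median_low", "median_high")]
    },
    notes = report$notes,
    provenance = report$provenance
  )
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(summaries, p, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
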