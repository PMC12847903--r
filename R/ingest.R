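#' Construct an abundance table
#'
#' A samples-by-taxa matrix of species-level relative abundances in percent,
#' with normalized taxon metadata. The constructor validates the
#' compositional structure: values in `[0, 100]`, per-sample totals at most
#' 100 plus a small tolerance (totals below 100 are legal — the unclassified
#' fraction is not carried), unique sample ids and unique canonical taxa.
#'
#' @param values Numeric matrix, samples in rows, taxa in columns,
#'   relative abundance in percent.
#' @param sample_ids Character vector of unique sample identifiers
#'   (defaults to `rownames(values)`).
#' @param taxa Character vector of taxon names, or a data frame as returned
#'   by [normalize_taxon_name()] (defaults to `colnames(values)`).
#' @param sum_tolerance Allowed excess over 100 in a per-sample total.
#' @return An object of class `abundance_table`: a list with `values`
#'   (rownames = sample ids, colnames = canonical taxa) and `taxa`
#'   (data frame `raw_name`, `canonical`, `sgb`).
#' @export
abundance_table <- function(values, sample_ids = rownames(values),
                            taxa = colnames(values), sum_tolerance = 0.5) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) stop("sample ids are required", call. = FALSE)
  tf <- if (is.data.frame(taxa)) taxa else normalize_taxon_name(taxa)
  if (nrow(tf) != ncol(values)) {
    stop("taxa metadata does not match the number of columns", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("validation error: duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  dup <- tf$canonical[duplicated(tf$canonical)]
  if (length(dup)) {
    stop("validation error: duplicate canonical taxa: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("validation error: abundances must be finite and >= 0", call. = FALSE)
  }
  totals <- rowSums(values)
  # proportion-scale auto-detection: per-sample sums ~ 1 instead of ~ 100
  if (nrow(values) > 0 && ncol(values) > 0 &&
      all(totals <= 1 + sum_tolerance / 100) && any(totals > 0.5)) {
    warning("per-sample totals look like proportions in [0, 1]; ",
            "rescaling to percent", call. = FALSE)
    values <- values * 100
    totals <- totals * 100
  }
  if (any(values > 100)) {
    stop("validation error: abundances above 100 percent", call. = FALSE)
  }
  bad <- which(totals > 100 + sum_tolerance)
  if (length(bad)) {
    stop("validation error: per-sample abundance totals exceed 100 (+",
         sum_tolerance, ") for: ",
         paste(sample_ids[bad], collapse = ", "), call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, tf$canonical)
  structure(list(values = values, taxa = tf), class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table:", nrow(x$values), "samples x", ncol(x$values),
      "taxa (percent relative abundance)\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Read a MetaPhlAn-style merged abundance table
#'
#' Parses a tab-separated merged profile (first column clade names, one
#' column per sample, `#`-prefixed comment lines tolerated, a commented
#' header line such as `#clade_name` recognized) and keeps only rows at the
#' requested taxonomic rank.
#'
#' @param path Path to the TSV file.
#' @param rank_filter `"species"` keeps rows whose deepest clade marker is
#'   `s__` (or every row when the file carries no rank prefixes at all);
#'   `"sgb"` keeps `t__SGB` rows; `"all"` keeps everything.
#' @param sum_tolerance Passed to [abundance_table()].
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path,
                                 rank_filter = c("species", "sgb", "all"),
                                 sum_tolerance = 0.5) {
  rank_filter <- match.arg(rank_filter)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_comment <- startsWith(lines, "#")
  header_guess <- is_comment & grepl("clade_name|clade name|taxon", lines,
                                     ignore.case = TRUE)
  lines[header_guess] <- sub("^#+\\s*", "", lines[header_guess])
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop("empty-table error: no rows in ", path, call. = FALSE)
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop("validation error: expected a clade column plus at least one sample",
         call. = FALSE)
  }
  clade <- as.character(df[[1L]])
  has_prefixes <- any(grepl("__", clade, fixed = TRUE))
  keep <- switch(rank_filter,
    all = rep(TRUE, length(clade)),
    sgb = grepl("t__SGB", clade),
    species = if (has_prefixes) {
      grepl("s__", clade, fixed = TRUE) & !grepl("|t__", clade, fixed = TRUE)
    } else rep(TRUE, length(clade))
  )
  if (!any(keep)) {
    stop("empty-table error: no rows at rank '", rank_filter, "'",
         call. = FALSE)
  }
  vals <- as.matrix(df[keep, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  abundance_table(t(vals), sample_ids = colnames(df)[-1L],
                  taxa = clade[keep], sum_tolerance = sum_tolerance)
}

#' Write an abundance table back to the merged-TSV dialect
#'
#' Round-trip companion of [read_abundance_table()]: writes a `clade_name`
#' header, the original (raw) taxon names and one column per sample.
#'
#' @param table An `abundance_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_abundance_table <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  df <- data.frame(clade_name = table$taxa$raw_name,
                   t(table$values), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[-1L] <- rownames(table$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Centered log-ratio transform
#'
#' Transforms each sample's composition to centered log-ratios:
#' `clr(x)_j = ln((x_j + pc) / g)` where `g` is the geometric mean of the
#' pseudocounted sample vector. The pseudocount makes zeros (undetected
#' taxa) finite; per-sample CLR values sum to exactly zero.
#'
#' @param table An `abundance_table`.
#' @param pseudocount Additive constant in percent, `> 0`. Default `1e-5`.
#' @return An object of class `clr_table` with the same axes as `table`.
#' @export
clr_transform <- function(table, pseudocount = 1e-5) {
  stopifnot(inherits(table, "abundance_table"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      pseudocount <= 0) {
    stop("invalid parameter: pseudocount must be a single positive number",
         call. = FALSE)
  }
  lx <- log(table$values + pseudocount)
  clr <- lx - rowMeans(lx)
  structure(list(values = clr, taxa = table$taxa,
                 pseudocount = pseudocount), class = "clr_table")
}

#' @export
print.clr_table <- function(x, ...) {
  cat("clr_table:", nrow(x$values), "samples x", ncol(x$values),
      "taxa (centered log-ratio, pseudocount", x$pseudocount, "%)\n")
  invisible(x)
}
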