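#' Normalize a taxon name to its canonical form
#'
#' Collapses the spelling variants produced by different MetaPhlAn dialects
#' (full clade strings with `k__...|s__` prefixes, underscore vs space
#' separators, mixed case, trailing SGB codes) onto a single canonical
#' species token, and extracts the species-level genome bin (SGB) code when
#' one is present.
#'
#' @param raw Character vector of taxon names. Each element may be a plain
#'   species name (`"Faecalibacterium prausnitzii"`), an underscore variant,
#'   a full MetaPhlAn clade string, or a name carrying an SGB code
#'   (`"Akkermansia muciniphila SGB9226"`).
#' @return A data frame with one row per input and columns `raw_name`,
#'   `canonical` (non-empty, lower case, single-space separated) and `sgb`
#'   (`"SGB"` + digits, or `NA`).
#' @examples
#' normalize_taxon_name("k__Bacteria|p__Firmicutes|s__Faecalibacterium_prausnitzii")
#' normalize_taxon_name("Akkermansia muciniphila SGB9226")
#' @export
normalize_taxon_name <- function(raw) {
  if (length(raw) == 0L) {
    stop("invalid input: no taxon names supplied", call. = FALSE)
  }
  if (any(is.na(raw)) || any(!nzchar(trimws(raw)))) {
    stop("invalid input: taxon names must be non-empty strings", call. = FALSE)
  }
  rows <- lapply(raw, .normalize_one)
  out <- data.frame(
    raw_name  = vapply(rows, `[[`, "", "raw_name"),
    canonical = vapply(rows, `[[`, "", "canonical"),
    sgb       = vapply(rows, `[[`, "", "sgb"),
    stringsAsFactors = FALSE
  )
  out$sgb[out$sgb == ""] <- NA_character_
  out
}

.normalize_one <- function(raw) {
  segs <- trimws(strsplit(raw, "|", fixed = TRUE)[[1L]])
  segs <- segs[nzchar(segs)]
  sgb <- ""
  m <- regmatches(raw, regexpr("SGB[0-9]+", raw))
  if (length(m) == 1L) sgb <- m
  sp <- grep("^s__", segs, value = TRUE)
  base <- if (length(sp)) {
    sub("^s__", "", sp[[length(sp)]])
  } else {
    sub("^[a-zA-Z]__", "", segs[[length(segs)]])
  }
  base <- gsub("SGB[0-9]+", " ", base)
  base <- gsub("[_[:space:]]+", " ", base)
  base <- tolower(trimws(base))
  if (!nzchar(base) && nzchar(sgb)) base <- tolower(sgb)
  if (!nzchar(base)) {
    stop("invalid input: taxon name '", raw, "' has no usable species token",
         call. = FALSE)
  }
  list(raw_name = raw, canonical = base, sgb = sgb)
}

#' Construct a SIG reference catalog
#'
#' A SIG catalog holds the two antagonistic species interacting groups the
#' classifier counts over: SIG1 (37 species associated with dysbiosis and
#' worse outcome under immunotherapy, split into an oral-cavity sub-cluster
#' and a gut-resident obligate-anaerobe sub-cluster) and SIG2 (45
#' health-associated gut anaerobes), together with the score thresholds and
#' the *Akkermansia muciniphila* gray-zone cutoff.
#'
#' @param sig1,sig2 Character vectors (or data frames from
#'   [normalize_taxon_name()] with an optional `placeholder` column) naming
#'   the member species of each group.
#' @param sig1_oral Character vector naming the SIG1 members that form the
#'   oral-cavity sub-cluster; the remainder form the gut sub-cluster.
#' @param akkermansia Single taxon name for the gray-zone arbiter
#'   (default carries the SGB9226 bin code).
#' @param t_low,t_high Score thresholds: scores `<= t_low` are dysbiotic
#'   (SIG1+), scores `>= t_high` eubiotic (SIG2+). Defaults 0.535 and 0.791.
#' @param akk_over_cutoff Relative-abundance cutoff (percent) above which
#'   gray-zone Akkermansia counts as overabundant. Default 4.799.
#' @param expect_sizes Integer vector of length 2; the required sizes of the
#'   two groups (default `c(37, 45)`). Set to `NULL` to skip the size check
#'   (e.g. for toy catalogs in examples and tests).
#' @return An object of class `sig_catalog`: a list with data-frame members
#'   `sig1` (columns `canonical`, `sgb`, `placeholder`, `subcluster`),
#'   `sig2`, a one-row `akkermansia`, and numeric thresholds.
#' @export
sig_catalog <- function(sig1, sig2, sig1_oral = character(),
                        akkermansia = "Akkermansia muciniphila SGB9226",
                        t_low = 0.535, t_high = 0.791,
                        akk_over_cutoff = 4.799,
                        expect_sizes = c(37L, 45L)) {
  sig1 <- .as_taxon_frame(sig1)
  sig2 <- .as_taxon_frame(sig2)
  oral <- if (length(sig1_oral)) normalize_taxon_name(sig1_oral)$canonical else character()
  sig1$subcluster <- ifelse(sig1$canonical %in% oral, "oral", "gut")
  akk <- .as_taxon_frame(akkermansia)
  cat <- structure(
    list(sig1 = sig1, sig2 = sig2, akkermansia = akk,
         t_low = t_low, t_high = t_high, akk_over_cutoff = akk_over_cutoff,
         expect_sizes = expect_sizes),
    class = "sig_catalog"
  )
  validate_sig_catalog(cat)
  cat
}

.as_taxon_frame <- function(x) {
  if (is.data.frame(x)) {
    tf <- normalize_taxon_name(x$name %||% x$raw_name)
    tf$placeholder <- if (!is.null(x$placeholder)) {
      isTRUE_vec(x$placeholder)
    } else rep(FALSE, nrow(tf))
    if (!is.null(x$sgb)) {
      have <- !is.na(x$sgb) & nzchar(x$sgb)
      tf$sgb[have] <- x$sgb[have]
    }
  } else {
    tf <- normalize_taxon_name(x)
    tf$placeholder <- rep(FALSE, nrow(tf))
  }
  tf
}

`%||%` <- function(a, b) if (is.null(a)) b else a
isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Validate a SIG catalog against its structural invariants
#'
#' Checks group sizes, disjointness of SIG1 and SIG2, the oral/gut partition
#' of SIG1, exclusion of the Akkermansia arbiter from both groups,
#' uniqueness of canonical names, and threshold ordering. Errors name the
#' violated invariant.
#'
#' @param cat A `sig_catalog`.
#' @return Invisibly, `cat`.
#' @export
validate_sig_catalog <- function(cat) {
  stopifnot(inherits(cat, "sig_catalog"))
  sizes <- cat$expect_sizes
  if (!is.null(sizes)) {
    if (nrow(cat$sig1) != sizes[[1L]]) {
      stop("catalog validation error: |sig1| = ", nrow(cat$sig1),
           " but the catalog requires ", sizes[[1L]], call. = FALSE)
    }
    if (nrow(cat$sig2) != sizes[[2L]]) {
      stop("catalog validation error: |sig2| = ", nrow(cat$sig2),
           " but the catalog requires ", sizes[[2L]], call. = FALSE)
    }
  }
  both <- intersect(cat$sig1$canonical, cat$sig2$canonical)
  if (length(both)) {
    stop("catalog validation error: sig1 and sig2 must be disjoint; shared: ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  for (nm in c("sig1", "sig2")) {
    dup <- cat[[nm]]$canonical[duplicated(cat[[nm]]$canonical)]
    if (length(dup)) {
      stop("catalog validation error: duplicate canonical taxa in ", nm, ": ",
           paste(unique(dup), collapse = ", "), call. = FALSE)
    }
  }
  akk <- cat$akkermansia$canonical
  if (akk %in% cat$sig1$canonical || akk %in% cat$sig2$canonical) {
    stop("catalog validation error: the Akkermansia arbiter must not be a ",
         "member of sig1 or sig2", call. = FALSE)
  }
  if (!all(cat$sig1$subcluster %in% c("oral", "gut"))) {
    stop("catalog validation error: sig1 subclusters must partition into ",
         "'oral' and 'gut'", call. = FALSE)
  }
  if (!(is.numeric(cat$t_low) && is.numeric(cat$t_high) &&
        cat$t_low > 0 && cat$t_low < cat$t_high && cat$t_high < 1)) {
    stop("catalog validation error: thresholds must satisfy 0 < t_low < t_high < 1",
         call. = FALSE)
  }
  if (!(is.numeric(cat$akk_over_cutoff) && cat$akk_over_cutoff > 0)) {
    stop("catalog validation error: akk_over_cutoff must be > 0", call. = FALSE)
  }
  invisible(cat)
}

#' Load a SIG catalog from a JSON file
#'
#' The file format has keys `sig1`, `sig2` (arrays of objects with `name`,
#' optional `sgb`, optional boolean `placeholder`), `sig1_oral` (array of
#' names), `akkermansia` (object) and `thresholds` (`t_low`, `t_high`,
#' `akk_over_cutoff`). The shipped default catalog can be regenerated with
#' [write_sig_catalog()] and edited to substitute placeholder entries with a
#' published species list without any code change.
#'
#' @param path Path to the catalog JSON file.
#' @param expect_sizes Required group sizes, as in [sig_catalog()].
#' @return A validated `sig_catalog`.
#' @export
load_sig_catalog <- function(path, expect_sizes = c(37L, 45L)) {
  if (!file.exists(path)) {
    stop("catalog file not found: ", path, call. = FALSE)
  }
  j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  th <- j$thresholds %||% list()
  akk <- j$akkermansia
  akk_name <- if (is.list(akk) || is.data.frame(akk)) akk$name else akk
  if (!is.null(akk$sgb) && !grepl("SGB[0-9]+", akk_name)) {
    akk_name <- paste(akk_name, akk$sgb)
  }
  sig_catalog(
    sig1 = as.data.frame(j$sig1), sig2 = as.data.frame(j$sig2),
    sig1_oral = unlist(j$sig1_oral),
    akkermansia = akk_name,
    t_low = th$t_low %||% 0.535,
    t_high = th$t_high %||% 0.791,
    akk_over_cutoff = th$akk_over_cutoff %||% 4.799,
    expect_sizes = expect_sizes
  )
}

#' Write a SIG catalog to JSON
#'
#' @param cat A `sig_catalog`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sig_catalog <- function(cat, path) {
  validate_sig_catalog(cat)
  ent <- function(df) {
    out <- data.frame(name = df$canonical, stringsAsFactors = FALSE)
    out$sgb <- df$sgb
    out$placeholder <- df$placeholder
    out
  }
  j <- list(
    sig1 = ent(cat$sig1),
    sig2 = ent(cat$sig2),
    sig1_oral = cat$sig1$canonical[cat$sig1$subcluster == "oral"],
    akkermansia = list(name = cat$akkermansia$canonical,
                       sgb = cat$akkermansia$sgb),
    thresholds = list(t_low = cat$t_low, t_high = cat$t_high,
                      akk_over_cutoff = cat$akk_over_cutoff)
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' The default SIG catalog
#'
#' Loads the catalog shipped with the package. It contains every species the
#' source describes by name (SIG1 oral cluster: *Veillonella* spp.,
#' *Streptococcus* spp., *Bifidobacterium dentium*; SIG1 gut cluster:
#' *Hungatella hathewayi*, *Clostridium innocuum*, *Enterocloster* spp.,
#' *Clostridium symbiosum*, *Erysipelatoclostridium ramosum*; SIG2:
#' *Faecalibacterium* spp., *Eubacterium rectale*, *Coprococcus comes*,
#' *Roseburia inulinivorans*, *Oscillibacter* sp. ER4), padded with
#' clearly-flagged placeholder identifiers to the reference sizes of exactly
#' 37 (SIG1) and 45 (SIG2). Placeholders carry `placeholder = TRUE` and can
#' be replaced by a published list by editing the JSON file — no code change
#' is needed.
#'
#' @return A validated `sig_catalog`.
#' @export
default_sig_catalog <- function() {
  path <- system.file("extdata", "sig_catalog.json", package = "sigscore",
                      mustWork = TRUE)
  load_sig_catalog(path)
}

#' @export
print.sig_catalog <- function(x, ...) {
  cat("SIG catalog:", nrow(x$sig1), "SIG1 species (",
      sum(x$sig1$subcluster == "oral"), "oral /",
      sum(x$sig1$subcluster == "gut"), "gut ),",
      nrow(x$sig2), "SIG2 species\n")
  cat("  placeholders:", sum(x$sig1$placeholder), "in SIG1,",
      sum(x$sig2$placeholder), "in SIG2\n")
  cat("  thresholds: S <=", x$t_low, "=> SIG1+ ; S >=", x$t_high,
      "=> SIG2+ ; gray-zone Akkermansia cutoff", x$akk_over_cutoff, "%\n")
  invisible(x)
}
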