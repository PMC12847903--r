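#' Reconstruct a taxon co-abundance network
#'
#' Nodes are taxa present (abundance > 0) in at least `min_prevalence` of
#' samples. For every taxon pair, Spearman rank correlation is computed on
#' centered log-ratio abundances; two-sided p-values (t approximation) are
#' Benjamini-Hochberg adjusted across all tested pairs, and pairs with
#' adjusted p at or below `alpha` become edges. Positive edges are
#' co-occurrence, negative edges co-exclusion.
#'
#' @param table An [abundance_table()] with at least 10 samples.
#' @param min_prevalence Minimum fraction of samples a taxon must be
#'   detected in to enter the network (default 0.1).
#' @param alpha Significance level on BH-adjusted p-values (default 0.05).
#' @param pseudocount Passed to [clr_transform()].
#' @return An object of class `coabundance_network`: a list with `nodes`
#'   (taxon metadata), `rho` (full Spearman correlation matrix over nodes),
#'   `edges` (data frame `taxon_a`, `taxon_b`, `weight`, `sign`, `p_value`,
#'   `q_value`), and `n_samples`.
#' @export
build_coabundance_network <- function(table, min_prevalence = 0.1,
                                      alpha = 0.05, pseudocount = 1e-5) {
  stopifnot(inherits(table, "abundance_table"))
  n <- nrow(table$values)
  if (n < 10L) {
    stop("insufficient data: co-abundance estimation needs >= 10 samples, got ",
         n, call. = FALSE)
  }
  if (min_prevalence < 0 || min_prevalence > 1) {
    stop("invalid parameter: min_prevalence must lie in [0, 1]", call. = FALSE)
  }
  prev <- colMeans(table$values > 0)
  keep <- which(prev >= min_prevalence)
  if (length(keep) < 2L) {
    stop("insufficient data: fewer than 2 taxa pass the prevalence filter",
         call. = FALSE)
  }
  clr <- clr_transform(table, pseudocount)$values[, keep, drop = FALSE]
  rho <- stats::cor(clr, method = "spearman")
  p <- ncol(clr)
  pairs <- which(upper.tri(rho), arr.ind = TRUE)
  pvals <- .spearman_p(rho[pairs], n)
  qvals <- stats::p.adjust(pvals, method = "BH")
  sig <- qvals <= alpha
  w <- rho[pairs][sig]
  edges <- data.frame(
    taxon_a = colnames(clr)[pairs[sig, 1L]],
    taxon_b = colnames(clr)[pairs[sig, 2L]],
    weight = w,
    sign = ifelse(w > 0, "positive", "negative"),
    p_value = pvals[sig],
    q_value = qvals[sig],
    stringsAsFactors = FALSE
  )
  structure(
    list(nodes = table$taxa[keep, , drop = FALSE], rho = rho,
         edges = edges, n_samples = n, alpha = alpha,
         min_prevalence = min_prevalence),
    class = "coabundance_network"
  )
}

# two-sided p for a Spearman rho via the t approximation (the standard
# large-sample test; exact enumeration is infeasible at cohort n)
.spearman_p <- function(rho, n) {
  rho <- pmin(pmax(rho, -1), 1)
  t_stat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  2 * stats::pt(-abs(t_stat), df = n - 2)
}

#' @export
print.coabundance_network <- function(x, ...) {
  cat("coabundance_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges (", sum(x$edges$sign == "positive"), "positive /",
      sum(x$edges$sign == "negative"), "negative ) from", x$n_samples,
      "samples\n")
  invisible(x)
}

#' Partition taxa by Ward-linkage hierarchical clustering
#'
#' Agglomerates taxa with Ward's minimum-variance criterion on the distance
#' `d = 1 - rho`, where `rho` is the Spearman correlation of CLR abundances
#' (taken from a prebuilt network, or computed from a table). Exactly one of
#' `n_clusters` / `height_cut` selects the partition; the full merge tree is
#' returned for dendrogram rendering.
#'
#' @param x A `coabundance_network` or an [abundance_table()].
#' @param n_clusters Number of clusters to cut the tree into (default 10,
#'   mirroring the ten major clusters of the reference network).
#' @param height_cut Alternatively, a merge-height threshold.
#' @param pseudocount Used only when `x` is an abundance table.
#' @return A list of class `ward_partition`: `cluster_of` (named integer
#'   vector, one cluster index per taxon) and `linkage` (an [stats::hclust]
#'   tree).
#' @export
ward_partition <- function(x, n_clusters = 10L, height_cut = NULL,
                           pseudocount = 1e-5) {
  if (!is.null(n_clusters) && !is.null(height_cut)) {
    stop("invalid parameter: supply exactly one of n_clusters / height_cut",
         call. = FALSE)
  }
  rho <- if (inherits(x, "coabundance_network")) {
    x$rho
  } else if (inherits(x, "abundance_table")) {
    if (ncol(x$values) < 2L) stop("need >= 2 taxa to cluster", call. = FALSE)
    stats::cor(clr_transform(x, pseudocount)$values, method = "spearman")
  } else {
    stop("x must be a coabundance_network or abundance_table", call. = FALSE)
  }
  if (!is.null(n_clusters) && n_clusters > nrow(rho)) {
    stop("invalid parameter: n_clusters (", n_clusters,
         ") exceeds the number of nodes (", nrow(rho), ")", call. = FALSE)
  }
  d <- stats::as.dist(1 - rho)
  h <- stats::hclust(d, method = "ward.D2")
  cluster_of <- if (!is.null(n_clusters)) {
    stats::cutree(h, k = n_clusters)
  } else {
    stats::cutree(h, h = height_cut)
  }
  structure(list(cluster_of = cluster_of, linkage = h),
            class = "ward_partition")
}

#' @export
print.ward_partition <- function(x, ...) {
  cat("ward_partition:", length(x$cluster_of), "taxa in",
      length(unique(x$cluster_of)), "clusters\n")
  invisible(x)
}

#' Export a co-abundance network
#'
#' `write_network_edges()` writes the edge list as TSV (`taxon_a`,
#' `taxon_b`, `weight`, `sign`, `q_value`); `write_network_graphml()` writes
#' a GraphML graph with edge weight/sign attributes;
#' `write_cluster_assignments()` writes a taxon-to-cluster TSV for a
#' [ward_partition()].
#'
#' @param network A `coabundance_network`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_network_edges <- function(network, path) {
  stopifnot(inherits(network, "coabundance_network"))
  utils::write.table(
    network$edges[, c("taxon_a", "taxon_b", "weight", "sign", "q_value")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_edges
#' @export
write_network_graphml <- function(network, path) {
  stopifnot(inherits(network, "coabundance_network"))
  g <- igraph::graph_from_data_frame(
    network$edges[, c("taxon_a", "taxon_b", "weight", "sign")],
    directed = FALSE,
    vertices = data.frame(name = network$nodes$canonical,
                          stringsAsFactors = FALSE))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_edges
#' @param partition A `ward_partition`.
#' @export
write_cluster_assignments <- function(partition, path) {
  stopifnot(inherits(partition, "ward_partition"))
  utils::write.table(
    data.frame(taxon = names(partition$cluster_of),
               cluster = unname(partition$cluster_of),
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
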