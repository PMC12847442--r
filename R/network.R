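# Correlation-threshold co-occurrence networks and topology metrics.
#
# Edges join taxon pairs whose abundance correlation passes both a magnitude
# threshold (default |r| > 0.8) and a significance threshold (default
# p < 0.05, unadjusted to match common practice; BH adjustment available).

#' All-pairs correlation matrix with p-values
#'
#' Pairwise Spearman (default) or Pearson correlations between the rows
#' (features) of a taxa-by-samples table, with two-sided p-values from the
#' t approximation `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom. Zero-variance features get `NA` correlations (and are excluded
#' from any downstream network).
#'
#' @param table Feature tibble or numeric taxa-by-samples matrix with at
#'   least 4 samples.
#' @param method `"spearman"` (default; rank-based, robust for skewed count
#'   data) or `"pearson"`.
#' @param prevalence_min Minimum fraction of samples in which a taxon must be
#'   present (count > 0) to be kept; default 1/3. Set to 0 to keep all.
#' @return A list of class `"stoichnet_cor"` with elements `r`, `p`
#'   (symmetric matrices, unit/zero diagonal), `n_samples`, `method`.
#' @export
correlation_matrix <- function(table, method = c("spearman", "pearson"),
                               prevalence_min = 1 / 3) {
  method <- match.arg(method)
  counts <- if (is.data.frame(table)) feature_counts(table) else table
  n <- ncol(counts)
  if (n < 4) abort("At least 4 samples are required for correlation p-values.")
  keep <- rowMeans(counts > 0) >= prevalence_min
  counts <- counts[keep, , drop = FALSE]
  r <- suppressWarnings(cor(t(counts), method = method))
  constant <- apply(counts, 1, function(x) length(unique(x)) == 1)
  r[constant, ] <- NA_real_
  r[, constant] <- NA_real_
  diag(r) <- 1
  # two-sided p from the t approximation; clamp r away from +/-1
  rr <- pmin(pmax(r, -1), 1)
  tt <- abs(rr) * sqrt((n - 2) / pmax(1 - rr^2, .Machine$double.eps))
  p <- 2 * pt(tt, df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  structure(list(r = r, p = p, n_samples = n, method = method),
            class = "stoichnet_cor")
}

#' Threshold a correlation matrix into a co-occurrence edge list
#'
#' Retains each unordered feature pair with `|r| > r_min` and (optionally
#' BH-adjusted) `p < p_max`, recording the correlation sign: positive edges
#' are read as putative cooperation, negative as competition.
#'
#' @param cors A `"stoichnet_cor"` object from [correlation_matrix()], or a
#'   list with symmetric conformable `r` and `p` matrices.
#' @param r_min Correlation magnitude threshold in (0, 1]; default 0.8.
#' @param p_max Significance threshold in (0, 1]; default 0.05.
#' @param adjust `"none"` (default) or `"BH"` (Benjamini-Hochberg across the
#'   upper-triangle p-values).
#' @return A tibble of class `"stoichnet_edges"` with columns `taxon_a`,
#'   `taxon_b` (a < b), `r`, `p` (adjusted if requested), `sign`.
#' @export
build_network <- function(cors, r_min = 0.8, p_max = 0.05,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (r_min <= 0 || r_min > 1 || p_max <= 0 || p_max > 1) {
    abort("Thresholds r_min and p_max must lie in (0, 1].")
  }
  r <- cors$r
  p <- cors$p
  if (!all(dim(r) == dim(p))) abort("r and p matrices are not conformable.")
  ut <- upper.tri(r)
  idx <- which(ut, arr.ind = TRUE)
  p_ut <- p[ut]
  if (adjust == "BH") p_ut <- stats::p.adjust(p_ut, method = "BH")
  r_ut <- r[ut]
  # tiny tolerance so pairs at the threshold itself (e.g. |r| = 1 with
  # r_min = 1) are retained
  keep <- !is.na(r_ut) & abs(r_ut) > r_min - 1e-12 & p_ut < p_max
  nm <- rownames(r) %||% as.character(seq_len(nrow(r)))
  edges <- tibble::tibble(
    taxon_a = nm[idx[keep, 1]],
    taxon_b = nm[idx[keep, 2]],
    r = r_ut[keep],
    p = p_ut[keep],
    sign = ifelse(r_ut[keep] > 0, "positive", "negative")
  )
  # canonical ordering for determinism
  swap <- edges$taxon_a > edges$taxon_b
  tmp <- edges$taxon_a[swap]
  edges$taxon_a[swap] <- edges$taxon_b[swap]
  edges$taxon_b[swap] <- tmp
  edges <- dplyr::arrange(edges, .data$taxon_a, .data$taxon_b)
  class(edges) <- c("stoichnet_edges", class(edges))
  edges
}

edges_to_igraph <- function(edges, nodes) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(edges) > 0) {
    missing_nodes <- setdiff(unique(c(edges$taxon_a, edges$taxon_b)), nodes)
    if (length(missing_nodes) > 0) {
      abort(paste0("Edge endpoint(s) not in node set: ",
                   paste(missing_nodes, collapse = ", ")))
    }
    g <- igraph::add_edges(g, rbind(edges$taxon_a, edges$taxon_b),
                           r = edges$r, p = edges$p, sign = edges$sign)
  }
  g
}

#' Topology summary of a co-occurrence network
#'
#' Metrics on the undirected simple graph over `nodes`: node and edge
#' counts, average degree, density, mean local clustering coefficient
#' (nodes with degree < 2, including isolates, contribute 0), diameter and
#' average shortest path length on the largest connected component,
#' modularity of the deterministic fast-greedy community partition on the
#' unweighted sign-blind graph, and the positive/negative edge fractions.
#' With no edges, diameter and path length are reported as `NA`.
#'
#' @param edges Edge tibble from [build_network()].
#' @param nodes Character vector of all node names (superset of endpoints);
#'   isolated taxa count towards clustering and density denominators.
#' @return A one-row tibble: `n_nodes`, `n_edges`, `avg_degree`, `density`,
#'   `avg_clustering`, `diameter`, `avg_path_length`, `modularity`,
#'   `pos_edge_frac`, `neg_edge_frac`.
#' @export
network_topology <- function(edges, nodes) {
  if (length(nodes) == 0) abort("Empty node set.")
  g <- edges_to_igraph(edges, nodes)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  local_cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  local_cc[is.nan(local_cc)] <- 0
  if (m > 0) {
    comp <- igraph::components(g)
    giant <- igraph::induced_subgraph(
      g, which(comp$membership == which.max(comp$csize)))
    diam <- igraph::diameter(giant, unconnected = FALSE)
    apl <- igraph::mean_distance(giant, unconnected = FALSE)
    fg <- igraph::cluster_fast_greedy(igraph::simplify(g))
    mod <- igraph::modularity(g, igraph::membership(fg))
    posf <- mean(edges$sign == "positive")
  } else {
    diam <- NA_real_
    apl <- NA_real_
    mod <- 0
    posf <- NA_real_
  }
  tibble::tibble(
    n_nodes = n, n_edges = m,
    avg_degree = 2 * m / n,
    density = if (n > 1) 2 * m / (n * (n - 1)) else NA_real_,
    avg_clustering = mean(local_cc),
    diameter = as.numeric(diam),
    avg_path_length = apl,
    modularity = mod,
    pos_edge_frac = posf,
    neg_edge_frac = if (m > 0) 1 - posf else NA_real_
  )
}

#' Export a co-occurrence network
#'
#' `"graphml"` writes a GraphML document (via igraph) carrying `r`, `p` and
#' `sign` as edge attributes, readable by Gephi/Cytoscape; `"edge_tsv"`
#' writes the edge list as TSV so that re-reading reproduces the edge set.
#'
#' @param edges Edge tibble from [build_network()].
#' @param path Output file path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @param nodes Node universe for GraphML (defaults to edge endpoints).
#' @return `path`, invisibly.
#' @export
export_network <- function(edges, path, format = c("graphml", "edge_tsv"),
                           nodes = NULL) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    readr::write_tsv(edges, path, progress = FALSE)
  } else {
    if (is.null(nodes)) nodes <- sort(unique(c(edges$taxon_a, edges$taxon_b)))
    g <- edges_to_igraph(edges, nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read an edge-TSV network back into an edge tibble
#'
#' @param path Path written by [export_network()] with `format = "edge_tsv"`.
#' @return An edge tibble with the same columns as [build_network()].
#' @export
read_network <- function(path) {
  edges <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  class(edges) <- c("stoichnet_edges", class(edges))
  edges
}

`%||%` <- function(a, b) if (is.null(a)) b else a
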