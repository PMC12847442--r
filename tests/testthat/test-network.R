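test_that("correlation matrices have unit diagonal and detect exact dependence", {
  set.seed(3)
  x <- runif(10)
  m <- rbind(a = x, b = -x, c = runif(10))
  cm <- correlation_matrix(m, method = "pearson", prevalence_min = 0)
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  expect_equal(cm$r["a", "b"], -1)
  expect_lt(cm$p["a", "b"], 1e-12)
  expect_equal(cm$r, t(cm$r))

  expect_error(correlation_matrix(m[, 1:3]), "4 samples")

  flat <- rbind(a = x, k = rep(2, 10))
  cf <- correlation_matrix(flat, method = "pearson", prevalence_min = 0)
  expect_true(is.na(cf$r["a", "k"]))
})

test_that("correlations match a brute-force rank-then-moment oracle", {
  set.seed(19)
  m <- matrix(rpois(6 * 12, 8), 6, 12,
              dimnames = list(sprintf("f%d", 1:6), NULL))
  cm <- correlation_matrix(m, method = "spearman", prevalence_min = 0)
  n <- 12
  for (i in 1:5) {
    for (j in (i + 1):6) {
      ri <- rank(m[i, ]); rj <- rank(m[j, ])
      r_oracle <- sum((ri - mean(ri)) * (rj - mean(rj))) /
        sqrt(sum((ri - mean(ri))^2) * sum((rj - mean(rj))^2))
      expect_equal(cm$r[i, j], r_oracle, tolerance = 1e-10)
      t_oracle <- abs(r_oracle) * sqrt((n - 2) / (1 - r_oracle^2))
      expect_equal(cm$p[i, j], 2 * pt(t_oracle, n - 2, lower.tail = FALSE),
                   tolerance = 1e-10)
    }
  }
  # pearson p agrees with cor.test
  cp <- correlation_matrix(m, method = "pearson", prevalence_min = 0)
  ct <- cor.test(m[1, ], m[2, ])
  expect_equal(cp$p[1, 2], ct$p.value, tolerance = 1e-9)
})

test_that("network thresholding keeps the right edges and records signs", {
  r <- matrix(c(1, 0.9, -0.85, 0.9, 1, 0.1, -0.85, 0.1, 1), 3,
              dimnames = rep(list(c("a", "b", "c")), 2))
  p <- matrix(0.001, 3, 3); diag(p) <- 0
  cors <- list(r = r, p = p)
  edges <- build_network(cors)
  expect_equal(nrow(edges), 2)
  expect_equal(edges$sign, c("positive", "negative"))

  # boundary: r_min = 1 retains only perfect correlations
  r1 <- r; r1["a", "b"] <- r1["b", "a"] <- 1
  e1 <- build_network(list(r = r1, p = p), r_min = 1)
  expect_equal(nrow(e1), 1)
  expect_equal(e1$taxon_a, "a")

  # identity correlation matrix gives an empty edge set
  expect_equal(nrow(build_network(list(r = diag(3), p = p))), 0)

  expect_error(build_network(cors, r_min = 0), "Thresholds")
  expect_error(build_network(cors, p_max = 1.5), "Thresholds")
})

test_that("raising r_min or lowering p_max never adds edges", {
  set.seed(5)
  com <- simulate_community(20, 40,
                            list(list(size = 4, rho = 0.9),
                                 list(size = 3, rho = 0.85)), seed = 5)
  cors <- correlation_matrix(com$table)
  key <- function(e) paste(e$taxon_a, e$taxon_b)
  for (rm in c(0.5, 0.7, 0.9)) {
    e_lo <- build_network(cors, r_min = rm)
    e_hi <- build_network(cors, r_min = rm + 0.05)
    expect_true(all(key(e_hi) %in% key(e_lo)))
  }
  for (pm in c(0.1, 0.01, 0.001)) {
    e_lo <- build_network(cors, r_min = 0.5, p_max = pm)
    e_hi <- build_network(cors, r_min = 0.5, p_max = pm / 10)
    expect_true(all(key(e_hi) %in% key(e_lo)))
  }
  # BH adjustment can only lose edges relative to raw p at the same cutoffs
  e_raw <- build_network(cors, r_min = 0.5)
  e_bh <- build_network(cors, r_min = 0.5, adjust = "BH")
  expect_true(all(key(e_bh) %in% key(e_raw)))
})

test_that("topology metrics are exact on closed-form graphs", {
  nodes4 <- c("a", "b", "c", "d")
  k4 <- t(combn(nodes4, 2))
  edges_k4 <- tibble::tibble(taxon_a = k4[, 1], taxon_b = k4[, 2],
                             r = 0.9, p = 0.001, sign = "positive")
  topo <- network_topology(edges_k4, nodes4)
  expect_equal(topo$n_edges, 6)
  expect_equal(topo$density, 1)
  expect_equal(topo$avg_degree, 3)
  expect_equal(topo$avg_clustering, 1)
  expect_equal(topo$diameter, 1)
  expect_equal(topo$pos_edge_frac, 1)

  # path graph P4: diameter 3, mean distance 10/6 over the 6 pairs
  p4 <- tibble::tibble(taxon_a = c("a", "b", "c"), taxon_b = c("b", "c", "d"),
                       r = c(0.9, -0.9, 0.9), p = 0.001,
                       sign = c("positive", "negative", "positive"))
  tp <- network_topology(p4, nodes4)
  expect_equal(tp$diameter, 3)
  expect_equal(tp$avg_path_length, 10 / 6, tolerance = 1e-9)
  expect_equal(tp$pos_edge_frac, 2 / 3)
  expect_equal(tp$pos_edge_frac + tp$neg_edge_frac, 1)

  # isolates contribute zero clustering; empty networks stay defined
  iso <- network_topology(edges_k4, c(nodes4, "e", "f"))
  expect_equal(iso$avg_clustering, 4 / 6)
  empty <- tibble::tibble(taxon_a = character(), taxon_b = character(),
                          r = numeric(), p = numeric(), sign = character())
  te <- network_topology(empty, nodes4)
  expect_equal(te$n_edges, 0)
  expect_true(is.na(te$diameter) && is.na(te$avg_path_length))
  expect_error(network_topology(empty, character()), "Empty node set")
})

test_that("modularity matches the exhaustive-partition oracle on two triangles", {
  nodes <- letters[1:6]
  tri2 <- tibble::tibble(
    taxon_a = c("a", "a", "b", "d", "d", "e"),
    taxon_b = c("b", "c", "c", "e", "f", "f"),
    r = 0.9, p = 0.001, sign = "positive")
  topo <- network_topology(tri2, nodes)

  # brute force: maximum modularity over all partitions of 6 nodes
  adj <- matrix(0, 6, 6, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(tri2))) {
    adj[tri2$taxon_a[k], tri2$taxon_b[k]] <- 1
    adj[tri2$taxon_b[k], tri2$taxon_a[k]] <- 1
  }
  deg <- rowSums(adj)
  m <- sum(adj) / 2
  mod_of <- function(mem) {
    q <- 0
    for (c in unique(mem)) {
      idx <- which(mem == c)
      q <- q + sum(adj[idx, idx]) / (2 * m) - (sum(deg[idx]) / (2 * m))^2
    }
    q
  }
  # enumerate set partitions via restricted growth strings
  best <- -Inf
  mem <- integer(6)
  recurse <- function(i, mx) {
    if (i > 6) {
      best <<- max(best, mod_of(mem))
      return()
    }
    for (c in seq_len(mx + 1)) {
      mem[i] <<- c
      recurse(i + 1, max(mx, c))
    }
  }
  recurse(1, 0)
  expect_equal(best, 0.5) # the two-triangle partition
  expect_equal(topo$modularity, best, tolerance = 1e-9)
  # greedy modularity is at least that of the one-community partition
  expect_gte(topo$modularity, 0)
})

test_that("network export round-trips and produces valid GraphML", {
  edges <- tibble::tibble(taxon_a = c("a", "a", "b"),
                          taxon_b = c("b", "c", "c"),
                          r = c(0.9, -0.85, 0.95), p = c(1e-4, 1e-3, 1e-5),
                          sign = c("positive", "negative", "positive"))
  tsv <- tempfile(fileext = ".tsv")
  export_network(edges, tsv, "edge_tsv")
  back <- read_network(tsv)
  expect_equal(as.data.frame(back), as.data.frame(edges), tolerance = 1e-12)

  gml <- tempfile(fileext = ".graphml")
  export_network(edges, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), 3)
  expect_equal(sort(igraph::edge_attr(g, "sign")),
               c("negative", "positive", "positive"))

  empty <- edges[0, ]
  gml2 <- tempfile(fileext = ".graphml")
  export_network(empty, gml2, "graphml", nodes = c("a", "b"))
  g2 <- igraph::read_graph(gml2, format = "graphml")
  expect_equal(igraph::ecount(g2), 0)
  expect_equal(igraph::vcount(g2), 2)
})
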