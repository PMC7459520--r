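path_graph <- function() {
  graph_from_edges(data.frame(from = c("n1", "n2"), to = c("n2", "n3")), 3)
}

test_that("hand-computed centralities on a path, a star, and a single directed edge", {
  # undirected path a-b-c
  rep_path <- centralities(path_graph(), treat_directed = FALSE)
  nd <- rep_path$nodes
  expect_equal(nd$betweenness[nd$id == "n2"], 1)
  expect_equal(nd$betweenness[nd$id != "n2"], c(0, 0))
  expect_equal(nd$radiality[nd$id == "n2"], 2)
  expect_equal(nd$radiality[nd$id == "n1"], 1.5)
  # undirected star: center n1, 4 leaves
  star <- graph_from_edges(
    data.frame(from = "n1", to = paste0("n", 2:5)), 5)
  rep_star <- centralities(star, treat_directed = FALSE)
  ns <- rep_star$nodes
  expect_equal(ns$betweenness[ns$id == "n1"], 1)
  # bridging = raw betweenness * (1/4) / (4/1); raw betweenness = C(4,2) = 6
  expect_equal(ns$bridging[ns$id == "n1"], 6 * (1 / 4) / 4)
  # single directed edge a -> b
  one <- graph_from_edges(data.frame(from = "n1", to = "n2"), 2)
  rep_one <- suppressWarnings(centralities(one, treat_directed = TRUE))
  no <- rep_one$nodes
  expect_equal(no$closeness[no$id == "n1"], 1)
  expect_equal(no$eccentricity[no$id == "n1"], 1)
  expect_equal(no$betweenness, c(0, 0))
  # node with empty out-reachable set scores 0 on distance indexes
  expect_equal(no$closeness[no$id == "n2"], 0)
  expect_equal(no$eigenvector, rep(1 / sqrt(2), 2))
})

test_that("all distance-based indexes match the simple-path enumeration oracle", {
  set.seed(2024)
  n_checked <- 0
  for (i in 1:50) {
    n <- sample(3:8, 1)
    edges <- random_edges(n, p = 0.35)
    if (!nrow(edges)) next
    directed <- i %% 2 == 0
    net <- graph_from_edges(edges, n)
    got <- suppressWarnings(centralities(net, treat_directed = directed))
    want <- oracle_centralities(paste0("n", seq_len(n)), edges, directed)
    got_n <- got$nodes[match(want$nodes$id, got$nodes$id), ]
    for (idx in c("degree", "in_degree", "out_degree", "stress")) {
      expect_equal(as.numeric(got_n[[idx]]), as.numeric(want$nodes[[idx]]))
    }
    for (idx in c("betweenness", "radiality", "bridging", "centroid",
                  "closeness", "eccentricity")) {
      expect_equal(got_n[[idx]], want$nodes[[idx]], tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
    key <- function(a, b) if (directed) paste(match(a, want$nodes$id),
                                              match(b, want$nodes$id)) else
      paste(pmin(match(a, want$nodes$id), match(b, want$nodes$id)),
            pmax(match(a, want$nodes$id), match(b, want$nodes$id)))
    got_eb <- got$edges
    expect_equal(unname(want$edge_betweenness[key(got_eb$from, got_eb$to)]),
                 got_eb$edge_betweenness, tolerance = 1e-9)
    # degree conservation
    expect_equal(sum(got$nodes$in_degree), nrow(edges))
    expect_equal(sum(got$nodes$out_degree), nrow(edges))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 45)
})

test_that("eigenvector centrality is the non-negative unit principal vector of the symmetrized adjacency", {
  set.seed(77)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    edges <- random_edges(n, p = 0.4)
    if (!nrow(edges)) next
    net <- graph_from_edges(edges, n)
    got <- suppressWarnings(centralities(net, treat_directed = FALSE))
    v <- got$nodes$eigenvector
    A <- matrix(0, n, n, dimnames = list(paste0("n", 1:n), paste0("n", 1:n)))
    A[cbind(edges$from, edges$to)] <- 1
    S <- (A + t(A) > 0) * 1
    expect_true(all(v >= 0))
    expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-9)
    lambda <- drop(t(v) %*% S %*% v)
    expect_lt(max(abs(S %*% v - lambda * v)), 1e-8)
  }
})

test_that("z-scores use the population sd and flag degenerate indexes", {
  edges <- data.frame(from = c("n1", "n1", "n1", "n4"),
                      to = c("n2", "n3", "n4", "n2"))
  rep <- zscores(centralities(graph_from_edges(edges, 4)))
  # direct check of the standardization on the degree column
  x <- rep$nodes$degree
  expect_equal(rep$nodes$z_degree,
               (x - mean(x)) / sqrt(mean((x - mean(x))^2)))
  # hand example: values (0,0,0,8) -> z of the large value = 6/sqrt(12)
  z <- (c(0, 0, 0, 8) - 2) / sqrt(12)
  expect_equal(round(z[4], 3), 1.732)
  # degenerate index: all values equal
  tri <- graph_from_edges(data.frame(from = c("n1", "n2", "n3"),
                                     to = c("n2", "n3", "n1")), 3)
  rep2 <- zscores(centralities(tri))
  expect_true("degree" %in% attr(rep2, "degenerate_indices"))
  expect_true(all(is.na(rep2$nodes$z_degree)))
  expect_length(relevant_nodes(rep, "degree", z_min = 2), 0)
})

test_that("the printed candidate-TF centrality table selects exactly SPIB, NFKB1, TBP", {
  hubs <- select_hubs(table2_centralities())
  expect_equal(hubs, c("SPIB", "NFKB1", "TBP"))
})

test_that("tertile selection uses intersection semantics with inclusive boundary ties", {
  t2 <- table2_centralities()
  # 9 candidates -> tertile size 3 on each index
  expect_length(select_hubs(t2), 3)
  # demote one selected TF on a single index: it drops out of the intersection
  t2b <- t2
  t2b$radiality[t2b$id == "TBP"] <- 2.40
  expect_equal(select_hubs(t2b), c("SPIB", "NFKB1"))
  # boundary ties are retained
  t2c <- t2
  t2c$degree[4:9] <- 74
  t2c$betweenness <- 0.5
  t2c$radiality <- 3
  expect_equal(select_hubs(t2c), t2c$id[order(-t2c$degree, t2c$id)])
  # three or fewer candidates: returned whole with a warning
  expect_warning(all3 <- select_hubs(t2[1:3, ]), "degenerate")
  expect_setequal(all3, c("SPIB", "NFKB1", "TBP"))
})

test_that("out-degree, radiality, and closeness are strongly correlated on hub-structured extended networks", {
  for (s in c(5, 11)) {
    w <- gen_world(rng_seed = s)
    res <- run_pipeline(w)
    nd <- res$extended_report$nodes
    m <- stats::cor(nd[, c("out_degree", "radiality", "closeness")])
    expect_true(all(m[lower.tri(m)] > 0.6))
  }
})

test_that("the GRN is bipartite with TF out-degrees equal to target unions", {
  w <- tiny_world(4)
  enr <- enrich(w$db, w$seed_genes, tiny_params())
  clusters <- annotate_clusters(cluster_motifs(enr, w$db), w$annotations)
  clusters <- clusters[!vapply(clusters, `[[`, logical(1), "flagged")]
  grn <- build_grn(clusters)
  kinds <- igraph::V(grn)$kind
  el <- igraph::as_edgelist(grn)
  expect_true(all(kinds[match(el[, 1], igraph::V(grn)$name)] == "tf"))
  expect_true(all(kinds[match(el[, 2], igraph::V(grn)$name)] == "gene"))
  # a shared target gets in-degree 2
  shared <- list(
    structure(list(cluster_id = "M1", assigned_tf = "A",
                   target_union = c("x", "y")), class = "motif_cluster"),
    structure(list(cluster_id = "M2", assigned_tf = "B",
                   target_union = c("y")), class = "motif_cluster"))
  g2 <- build_grn(shared)
  expect_equal(igraph::degree(g2, "y", mode = "in"), 2, ignore_attr = TRUE)
  expect_equal(igraph::vcount(g2), 4)
})
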