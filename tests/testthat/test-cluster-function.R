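simple_net <- function() {
  edges <- data.frame(from = c("H", "H", "K"), to = c("a", "b", "H"),
                      provenance = c("motif", "motif", "kinase"),
                      stringsAsFactors = FALSE)
  vert <- data.frame(name = c("H", "a", "b", "K"),
                     kind = c("tf", "gene", "gene", "kinase"),
                     stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vert)
}

test_that("transcriptional clusters are the hub plus all first neighbors", {
  expect_equal(transcriptional_cluster(simple_net(), "H"),
               sort(c("H", "a", "b", "K")))
  expect_error(transcriptional_cluster(simple_net(), "nope"), "unknown hub")
  iso <- igraph::make_empty_graph() + igraph::vertices("H")
  expect_warning(cl <- transcriptional_cluster(iso, "H"), "isolated")
  expect_equal(cl, "H")
  # two hubs sharing a target give overlapping, non-disjoint clusters
  edges <- data.frame(from = c("H1", "H2"), to = c("x", "x"))
  net <- igraph::graph_from_data_frame(edges, directed = TRUE)
  expect_true("x" %in% transcriptional_cluster(net, "H1"))
  expect_true("x" %in% transcriptional_cluster(net, "H2"))
})

test_that("overlap p-values match the enumeration oracle and k = 0 is never reported", {
  # N = 10, K = 4, n = 5, k = 4 -> 6/252
  coll <- gene_set_collection(list(S = paste0("u", 1:4),
                                   filler = paste0("u", 1:10)))
  clusters <- list(C1 = c(paste0("u", 1:4), "u9"))
  res <- overlap_analysis(clusters, coll, alpha_adj = 1, min_fraction = 0)
  p_s <- res$p_nominal[res$set_name == "S"]
  expect_equal(p_s, 6 / 252, tolerance = 1e-12)
  expect_equal(p_s, oracle_hyper_tail(10, 4, 5, 4), tolerance = 1e-12)
  # a set disjoint from the cluster (k = 0) is never reported
  coll2 <- gene_set_collection(list(S = paste0("u", 1:4),
                                    D = paste0("u", 5:8),
                                    filler = paste0("u", 1:10)))
  res2 <- overlap_analysis(list(C1 = paste0("u", 1:4)), coll2,
                           alpha_adj = 1, min_fraction = 0)
  expect_false("D" %in% res2$set_name)
  # random configurations against the oracle
  set.seed(5)
  for (i in 1:10) {
    N <- sample(8:12, 1)
    U <- paste0("u", seq_len(N))
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    coll_i <- gene_set_collection(list(S = U[seq_len(K)], all = U))
    cl_i <- list(C = sample(U, n))
    r <- overlap_analysis(cl_i, coll_i, alpha_adj = 2, min_fraction = 0)
    k_obs <- length(intersect(cl_i$C, U[seq_len(K)]))
    if (k_obs == 0) {
      expect_false("S" %in% r$set_name)
    } else {
      expect_equal(r$p_nominal[r$set_name == "S"],
                   oracle_hyper_tail(N, K, n, k_obs), tolerance = 1e-9)
    }
  }
})

test_that("a planted set covering half of a 20-gene cluster in universe 1000 is significant", {
  U <- paste0("u", 1:1000)
  cluster <- U[1:20]
  coll <- gene_set_collection(list(planted = cluster,
                                   noise1 = U[301:400], noise2 = U[501:550],
                                   all = U))
  res <- overlap_analysis(list(C = cluster), coll)
  expect_true("planted" %in% res$set_name)
  expect_lt(res$p_adjusted[res$set_name == "planted"], 0.01)
  expect_gte(res$overlap_fraction[res$set_name == "planted"], 0.05)
})

test_that("filters are monotone: stricter settings never add results", {
  w <- tiny_world(6)
  clusters <- list(C1 = sample(unique(unlist(w$gene_sets$sets)), 30),
                   C2 = w$truth[[1]]$target_genes)
  base <- overlap_analysis(clusters, w$gene_sets, alpha_adj = 0.5,
                           min_fraction = 0)
  stricter_alpha <- overlap_analysis(clusters, w$gene_sets, alpha_adj = 0.01,
                                     min_fraction = 0)
  higher_fraction <- overlap_analysis(clusters, w$gene_sets, alpha_adj = 0.5,
                                      min_fraction = 0.2)
  key <- function(d) paste(d$cluster_id, d$set_name)
  expect_true(all(key(stricter_alpha) %in% key(base)))
  expect_true(all(key(higher_fraction) %in% key(base)))
})

test_that("BH correction is joint across the full cluster-by-set grid", {
  U <- paste0("u", 1:60)
  coll <- gene_set_collection(list(S1 = U[1:12], S2 = U[13:30], S3 = U[31:45],
                                   all = U))
  clusters <- list(C1 = U[c(1:10, 50:55)], C2 = U[c(13:24, 31:34)])
  res <- overlap_analysis(clusters, coll, alpha_adj = 1, min_fraction = 0)
  # recompute the full grid by hand: 2 clusters x 4 sets = 8 joint hypotheses
  grid <- expand.grid(cl = names(clusters), s = names(coll$sets),
                      stringsAsFactors = FALSE)
  raw <- vapply(seq_len(nrow(grid)), function(i) {
    K <- length(coll$sets[[grid$s[i]]])
    k <- length(intersect(clusters[[grid$cl[i]]], coll$sets[[grid$s[i]]]))
    stats::phyper(k - 1, K, 60 - K, length(clusters[[grid$cl[i]]]),
                  lower.tail = FALSE)
  }, numeric(1))
  joint <- stats::p.adjust(raw, "BH")
  idx <- match(paste(res$cluster_id, res$set_name), paste(grid$cl, grid$s))
  expect_equal(res$p_adjusted, joint[idx], tolerance = 1e-12)
  # a per-cluster correction would disagree on this grid (regression guard)
  per_cluster <- unlist(lapply(names(clusters), function(cl) {
    stats::p.adjust(raw[grid$cl == cl], "BH")
  }))[order(order(grid$cl))]
  expect_false(isTRUE(all.equal(joint, per_cluster)))
})

test_that("the enrichment network is a weighted bipartite graph with set attributes", {
  U <- paste0("u", 1:200)
  coll <- gene_set_collection(list(A = U[1:20], B = U[5:30], all = U),
                              score = c(A = 2.5, B = -1.8, all = 1))
  clusters <- list(C = U[1:25])
  res <- overlap_analysis(clusters, coll, alpha_adj = 0.05, min_fraction = 0.05)
  net <- enrichment_network(res, coll)
  expect_setequal(igraph::V(net)$kind,
                  c("cluster", rep("gene_set", length(unique(res$set_name)))))
  for (i in seq_len(nrow(res))) {
    eid <- igraph::get_edge_ids(net, c(res$cluster_id[i], res$set_name[i]))
    expect_equal(igraph::E(net)$weight[eid], res$overlap[i])
  }
  sn <- res$set_name[1]
  expect_equal(igraph::V(net)$score[igraph::V(net)$name == sn],
               unname(coll$score[sn]))
  # no significant result: an empty graph, not an error
  empty <- enrichment_network(res[0, ], coll)
  expect_equal(igraph::vcount(empty), 0)
})
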