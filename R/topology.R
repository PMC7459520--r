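#' Build the TF-to-gene regulatory network from annotated motif clusters
#'
#' A bipartite directed graph with one `tf` node per assigned cluster TF and
#' one `gene` node per target, and an edge TF -> gene for every gene in the
#' cluster's target union (edge provenance `motif`). A TF's out-degree thus
#' equals the size of its cluster's target union. Clusters without an
#' assigned TF are skipped with a warning.
#'
#' @param clusters List of annotated `motif_cluster` objects
#'   (see [annotate_clusters()]).
#' @return An igraph object with vertex attribute `kind` (`tf`/`gene`) and
#'   edge attribute `provenance`.
#' @export
build_grn <- function(clusters) {
  has_tf <- !vapply(clusters, function(cl) is.na(cl$assigned_tf), logical(1))
  if (any(!has_tf))
    warning("skipping ", sum(!has_tf), " cluster(s) without an assigned TF")
  clusters <- clusters[has_tf]
  if (!length(clusters)) stop("no cluster has an assigned TF")
  edges <- unique(do.call(rbind, lapply(clusters, function(cl) {
    data.frame(from = cl$assigned_tf, to = cl$target_union,
               stringsAsFactors = FALSE)
  })))
  loops <- edges$from == edges$to
  if (any(loops)) {
    warning("dropping ", sum(loops), " self-loop(s) (TF among its own targets)")
    edges <- edges[!loops, , drop = FALSE]
  }
  edges$provenance <- "motif"
  tfs <- unique(vapply(clusters, `[[`, character(1), "assigned_tf"))
  genes <- setdiff(unique(edges$to), tfs)
  nodes <- data.frame(name = c(tfs, genes),
                      kind = c(rep("tf", length(tfs)), rep("gene", length(genes))),
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}

# all-pairs shortest-path counts by breadth-first search (unweighted)
shortest_path_counts <- function(g, directed) {
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g, mode = if (directed) "out" else "all")
  adj <- lapply(adj, as.integer)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- rep(NA_integer_, n)
    sg <- numeric(n)
    d[s] <- 0L
    sg[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.na(d[w])) {
            d[w] <- d[v] + 1L
            nxt <- c(nxt, w)
          }
          if (d[w] == d[v] + 1L) sg[w] <- sg[w] + sg[v]
        }
      }
      frontier <- unique(nxt)
    }
    sigma[s, ] <- sg
  }
  sigma
}

#' Centrality battery for a regulatory network
#'
#' Computes, for every node: degree (in + out), in-/out-degree, normalized
#' betweenness, radiality, stress, bridging, centroid, closeness,
#' eccentricity, and eigenvector centrality; and for every edge its
#' unnormalized edge betweenness. Conventions:
#' \itemize{
#'   \item Distances are unweighted shortest-path lengths over the chosen
#'     orientation (`treat_directed = FALSE` collapses the graph to
#'     undirected, the appropriate treatment for a pure source-to-sink
#'     bipartite TF-gene network, where directed betweenness would vanish
#'     identically).
#'   \item Unreachable pairs are skipped in sums and maxima; a node with an
#'     empty reachable set scores 0 on the distance-based indexes (with a
#'     warning when the node is fully isolated).
#'   \item `betweenness` is normalized by `(n-1)(n-2)/2` (undirected) or
#'     `(n-1)(n-2)` (directed); `stress` is the raw count of shortest paths
#'     passing through the node.
#'   \item `radiality(v) = sum_w (diam + 1 - d(v, w)) / (n - 1)` over
#'     reachable `w`, with `diam` the diameter over reachable pairs.
#'   \item `closeness(v) = 1 / sum_w d(v, w)` and
#'     `eccentricity(v) = 1 / max_w d(v, w)` over reachable `w`
#'     (reciprocal conventions: higher = more central).
#'   \item `centroid(v) = min_w (gamma_v(w) - gamma_w(v))` with
#'     `gamma_v(w)` the number of nodes strictly closer to `v` than to `w`.
#'   \item `bridging(v)` is the raw betweenness weighted by
#'     `(1/deg(v)) / sum_{i in N(v)} 1/deg(i)`.
#'   \item `eigenvector` is the non-negative principal eigenvector of the
#'     symmetrized adjacency matrix, scaled to unit Euclidean norm.
#' }
#'
#' @param net An igraph regulatory network.
#' @param treat_directed Use edge directions for distances and path counts
#'   (default `FALSE`).
#' @return An object of class `centrality_report`: list with `nodes` (data
#'   frame of per-node indexes plus `n_reachable`), `edges` (data frame with
#'   `from`, `to`, `edge_betweenness`), `directed`, and `diameter`.
#' @export
centralities <- function(net, treat_directed = FALSE) {
  n <- igraph::vcount(net)
  if (n == 0) stop("empty network")
  ids <- igraph::V(net)$name
  kind <- igraph::V(net)$kind
  if (is.null(kind)) kind <- rep(NA_character_, n)
  g <- if (treat_directed) net else
    igraph::as_undirected(net, mode = "collapse")
  mode <- if (treat_directed) "out" else "all"

  in_deg <- igraph::degree(net, mode = "in")
  out_deg <- igraph::degree(net, mode = "out")
  deg <- in_deg + out_deg
  deg_g <- igraph::degree(g, mode = "all")
  if (any(deg == 0))
    warning(sum(deg == 0), " isolated node(s): distance-based indexes set to 0")

  dist <- igraph::distances(g, mode = mode, weights = NA)
  reach <- is.finite(dist) & dist > 0
  n_reachable <- rowSums(reach)
  finite_pos <- dist[reach]
  diam <- if (length(finite_pos)) max(finite_pos) else 0

  radiality <- vapply(seq_len(n), function(v) {
    d <- dist[v, reach[v, ]]
    if (!length(d) || n < 2) return(0)
    sum(diam + 1 - d) / (n - 1)
  }, numeric(1))
  closeness <- vapply(seq_len(n), function(v) {
    s <- sum(dist[v, reach[v, ]])
    if (s > 0) 1 / s else 0
  }, numeric(1))
  eccentricity <- vapply(seq_len(n), function(v) {
    d <- dist[v, reach[v, ]]
    if (!length(d)) 0 else 1 / max(d)
  }, numeric(1))

  # centroid: gamma[v, w] = #{u : d(u, v) < d(u, w)}
  centroid <- rep(0, n)
  if (n >= 2) {
    gamma <- matrix(0L, n, n)
    for (v in seq_len(n)) gamma[v, ] <- colSums(dist[, v] < dist)
    diffs <- gamma - t(gamma)
    diag(diffs) <- NA
    centroid <- apply(diffs, 1, min, na.rm = TRUE)
  }

  btw_raw <- igraph::betweenness(g, directed = treat_directed, weights = NA)
  denom <- if (treat_directed) (n - 1) * (n - 2) else (n - 1) * (n - 2) / 2
  btw <- if (n >= 3) btw_raw / denom else rep(0, n)

  sigma <- shortest_path_counts(g, treat_directed)
  stress <- vapply(seq_len(n), function(v) {
    through <- outer(sigma[, v], sigma[v, ])
    on_sp <- outer(dist[, v], dist[v, ], `+`) == dist
    on_sp[!is.finite(dist)] <- FALSE
    through[!on_sp] <- 0
    through[v, ] <- 0
    through[, v] <- 0
    diag(through) <- 0
    s <- sum(through)
    if (treat_directed) s else s / 2
  }, numeric(1))

  bridging <- vapply(seq_len(n), function(v) {
    if (deg_g[v] == 0) return(0)
    nb <- unique(as.integer(igraph::neighbors(g, v, mode = "all")))
    denom_b <- sum(1 / deg_g[nb])
    if (denom_b == 0) return(0)
    btw_raw[v] * (1 / deg_g[v]) / denom_b
  }, numeric(1))

  A <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  S <- (A + t(A) > 0) * 1
  if (any(S > 0)) {
    es <- eigen(S, symmetric = TRUE)
    ev <- es$vectors[, 1]
    if (sum(ev) < 0) ev <- -ev
    ev[abs(ev) < 1e-12] <- 0
    ev <- pmax(ev, 0)
    nrm <- sqrt(sum(ev^2))
    ev <- if (nrm > 0) ev / nrm else rep(0, n)
  } else ev <- rep(0, n)

  eb <- igraph::edge_betweenness(g, directed = treat_directed, weights = NA)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(from = el[, 1], to = el[, 2], edge_betweenness = eb,
                      stringsAsFactors = FALSE)

  nodes <- data.frame(id = ids, kind = kind,
                      degree = deg, in_degree = in_deg, out_degree = out_deg,
                      betweenness = btw, radiality = radiality,
                      stress = stress, bridging = bridging,
                      centroid = centroid, closeness = closeness,
                      eccentricity = eccentricity, eigenvector = ev,
                      n_reachable = n_reachable,
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(nodes = nodes, edges = edges, directed = treat_directed,
                 diameter = diam),
            class = "centrality_report")
}

#' @export
print.centrality_report <- function(x, ...) {
  cat("Centrality report:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges (",
      if (x$directed) "directed" else "undirected", "), diameter", x$diameter, "\n")
  invisible(x)
}

centrality_index_names <- c("degree", "in_degree", "out_degree", "betweenness",
                            "radiality", "stress", "bridging", "centroid",
                            "closeness", "eccentricity", "eigenvector")

#' Standardize centrality indexes into z-scores
#'
#' Adds a `z_<index>` column per index, standardized across nodes with the
#' population standard deviation. Nodes with `z >= 2` on an index are
#' conventionally deemed very relevant for it, `1.5 <= z < 2` near-relevant
#' (see [relevant_nodes()]). Indexes that are constant across nodes are
#' flagged degenerate (z undefined, set `NA`).
#'
#' @param report A `centrality_report` (>= 2 nodes).
#' @return The report with z-score columns and attribute
#'   `degenerate_indices`.
#' @export
zscores <- function(report) {
  nodes <- report$nodes
  if (nrow(nodes) < 2) stop("need at least two nodes for z-scores")
  degenerate <- character()
  for (idx in intersect(centrality_index_names, names(nodes))) {
    x <- nodes[[idx]]
    sdp <- sqrt(mean((x - mean(x))^2))
    if (sdp == 0) {
      degenerate <- c(degenerate, idx)
      nodes[[paste0("z_", idx)]] <- NA_real_
    } else {
      nodes[[paste0("z_", idx)]] <- (x - mean(x)) / sdp
    }
  }
  report$nodes <- nodes
  attr(report, "degenerate_indices") <- degenerate
  report
}

#' Nodes whose z-score on an index reaches a relevance level
#'
#' @param report A `centrality_report` processed by [zscores()].
#' @param index Index name (e.g. `"betweenness"`).
#' @param z_min,z_max Relevance band (default `z >= 2`, the very-relevant
#'   convention; use `z_min = 1.5, z_max = 2` for the near-relevant band).
#' @return Character vector of node ids.
#' @export
relevant_nodes <- function(report, index, z_min = 2, z_max = Inf) {
  z <- report$nodes[[paste0("z_", index)]]
  if (is.null(z)) stop("no z-scores for index ", index, "; run zscores() first")
  report$nodes$id[!is.na(z) & z >= z_min & z < z_max]
}

#' Select hub regulators by upper-tertile intersection
#'
#' Candidates (by default the `tf` nodes) are ranked separately on each
#' index; the upper tertile of an index is the top `ceiling(n/3)` rank
#' positions, values tied with the boundary included. Hubs are the
#' candidates falling in the upper tertile of every index, returned in
#' descending order of degree. Candidate sets of three or fewer are
#' degenerate for tertile selection and are returned whole with a warning.
#'
#' @param x A `centrality_report`, or a data frame with an `id` column, one
#'   column per index, and optionally a `kind` column (this lets printed
#'   degree/betweenness/radiality tables be fed directly).
#' @param indices Index columns to intersect (default degree, betweenness,
#'   radiality).
#' @param kind Candidate node kind(s); `NULL` keeps all rows.
#' @return Character vector of hub node ids.
#' @export
select_hubs <- function(x, indices = c("degree", "betweenness", "radiality"),
                        kind = "tf") {
  df <- if (inherits(x, "centrality_report")) x$nodes else as.data.frame(x)
  if (!"id" %in% names(df)) stop("candidate table needs an 'id' column")
  if (!is.null(kind) && "kind" %in% names(df))
    df <- df[df$kind %in% kind, , drop = FALSE]
  missing <- setdiff(indices, names(df))
  if (length(missing)) stop("missing index column(s): ",
                            paste(missing, collapse = ", "))
  n <- nrow(df)
  if (n == 0) return(character())
  ord_cols <- intersect(c("degree", indices), names(df))
  if (n <= 3) {
    warning("3 or fewer candidates; tertile selection is degenerate, returning all")
    return(df$id[order(-df[[ord_cols[1]]], df$id)])
  }
  keep <- rep(TRUE, n)
  t_size <- ceiling(n / 3)
  for (idx in indices) {
    v <- df[[idx]]
    cut <- sort(v, decreasing = TRUE)[t_size]
    keep <- keep & v >= cut
  }
  out <- df[keep, , drop = FALSE]
  out$id[order(-out[[ord_cols[1]]], out$id)]
}
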