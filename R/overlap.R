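#' Merge regulatory, PPI, and kinase layers into one network
#'
#' Stacks the TF-to-gene regulatory edges, the PPI expansion edges, and
#' kinase-to-substrate edges (for the selected kinases, restricted to
#' substrates already present among the merged nodes) into a single typed
#' directed graph. Node kinds are merged with priority
#' tf > kinase > protein > gene.
#'
#' @param grn TF-gene regulatory network (igraph) or `NULL`.
#' @param expansion PPI expansion network (igraph) or `NULL`.
#' @param kinases Selected kinase symbols (possibly empty).
#' @param kdb A [kinase_substrate_table] (required when `kinases` is
#'   non-empty).
#' @return An igraph object with vertex `kind` and edge `provenance`
#'   attributes.
#' @export
combined_network <- function(grn = NULL, expansion = NULL, kinases = character(),
                             kdb = NULL) {
  part_edges <- list()
  part_nodes <- list()
  grab <- function(g) {
    e <- igraph::as_data_frame(g, what = "edges")
    v <- igraph::as_data_frame(g, what = "vertices")
    list(edges = e[intersect(c("from", "to", "provenance"), names(e))],
         nodes = v[c("name", "kind")])
  }
  if (!is.null(grn)) {
    p <- grab(grn); part_edges <- c(part_edges, list(p$edges))
    part_nodes <- c(part_nodes, list(p$nodes))
  }
  if (!is.null(expansion)) {
    p <- grab(expansion); part_edges <- c(part_edges, list(p$edges))
    part_nodes <- c(part_nodes, list(p$nodes))
  }
  if (!length(part_nodes)) stop("need at least one network layer")
  nodes <- do.call(rbind, part_nodes)
  if (length(kinases)) {
    if (is.null(kdb)) stop("kinase edges require a kinase_substrate_table")
    kin_edges <- do.call(rbind, lapply(kinases, function(k) {
      subs <- intersect(kdb$substrates[[k]], nodes$name)
      if (!length(subs)) return(NULL)
      data.frame(from = k, to = subs, provenance = "kinase",
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(kin_edges)) {
      part_edges <- c(part_edges, list(kin_edges))
      part_nodes <- c(part_nodes,
                      list(data.frame(name = kinases, kind = "kinase",
                                      stringsAsFactors = FALSE)))
    }
  }
  edges <- unique(do.call(rbind, part_edges))
  nodes <- do.call(rbind, part_nodes)
  pri <- c(tf = 1, kinase = 2, cofactor = 3, protein = 4, gene = 5)
  nodes <- nodes[order(pri[nodes$kind]), , drop = FALSE]
  nodes <- nodes[!duplicated(nodes$name), , drop = FALSE]
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}

#' Hub-centered transcriptional cluster
#'
#' The cluster of a hub TF is the hub itself plus all its in- and
#' out-neighbors across every edge provenance (target genes, PPI
#' interactors, upstream kinases) of the combined network.
#'
#' @param net Combined regulatory network (igraph).
#' @param hub Hub node id (must exist in the network).
#' @return Sorted character vector of member symbols.
#' @export
transcriptional_cluster <- function(net, hub) {
  if (!hub %in% igraph::V(net)$name) stop("unknown hub: ", hub)
  nb <- igraph::neighbors(net, hub, mode = "all")$name
  if (!length(nb)) warning("hub ", hub, " is isolated; cluster is the hub alone")
  sort(unique(c(hub, nb)))
}

#' Hypergeometric overlap of transcriptional clusters with pathway sets
#'
#' Tests every (cluster, gene set) pair with the hypergeometric upper tail:
#' population `N` (the universe, by default the union of all collection
#' members), successes `K = |set|`, draws `n = |cluster|`, observed
#' `k = |overlap|`. Benjamini-Hochberg correction is applied once, jointly
#' across the full cluster-by-set grid. Pairs are reported when the
#' adjusted p is below `alpha_adj` and the overlap covers at least
#' `min_fraction` of the cluster. Cluster symbols outside the universe
#' (e.g. kinases absent from the pathway annotation) are dropped with a
#' message before testing.
#'
#' @param clusters Named list of clusters (character vectors), e.g. from
#'   [transcriptional_cluster()].
#' @param collection A [gene_set_collection].
#' @param alpha_adj Adjusted-p threshold (default 0.01).
#' @param min_fraction Minimum overlap as a fraction of the cluster
#'   (default 0.05).
#' @param universe Optional universe override.
#' @return Data frame of class `overlap_result`, sorted by adjusted p:
#'   `cluster_id`, `set_name`, `cluster_size`, `set_size`, `overlap`,
#'   `overlap_fraction`, `p_nominal`, `p_adjusted`.
#' @export
overlap_analysis <- function(clusters, collection, alpha_adj = 0.01,
                             min_fraction = 0.05, universe = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!length(collection$sets)) stop("empty gene-set collection")
  if (is.null(names(clusters)) || any(!nzchar(names(clusters))))
    stop("clusters must be named")
  if (is.null(universe)) universe <- sort(unique(unlist(collection$sets)))
  N <- length(universe)
  sets <- lapply(collection$sets, intersect, universe)
  rows <- list()
  for (cid in names(clusters)) {
    cl <- unique(clusters[[cid]])
    cu <- intersect(cl, universe)
    if (length(cu) < length(cl))
      message(length(cl) - length(cu), " symbol(s) of cluster ", cid,
              " outside the universe dropped")
    if (!length(cu)) stop("cluster ", cid, " empty after universe restriction")
    n <- length(cu)
    for (sname in names(sets)) {
      K <- length(sets[[sname]])
      k <- length(intersect(cu, sets[[sname]]))
      p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = cid, set_name = sname, cluster_size = n, set_size = K,
        overlap = k, overlap_fraction = k / n, p_nominal = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_nominal, method = "BH")
  keep <- out$p_adjusted < alpha_adj &
    out$overlap >= min_fraction * out$cluster_size & out$overlap > 0
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$p_adjusted, out$p_nominal, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "universe_size") <- N
  class(out) <- c("overlap_result", "data.frame")
  out
}

#' Bipartite cluster-to-pathway enrichment network
#'
#' Nodes are the transcriptional clusters and their significantly
#' overlapping gene sets; an edge's weight is the overlap count. Gene-set
#' nodes carry their size and (if present) collection score. An empty
#' result yields an empty graph, not an error.
#'
#' @param results An `overlap_result` data frame.
#' @param collection The [gene_set_collection] the results came from.
#' @return An igraph object with vertex attributes `kind`
#'   (`cluster`/`gene_set`), `size`, `score`, and edge attribute `weight`.
#' @export
enrichment_network <- function(results, collection) {
  if (!nrow(results)) return(igraph::make_empty_graph(directed = FALSE))
  cl_ids <- unique(results$cluster_id)
  set_ids <- unique(results$set_name)
  score <- collection$score
  nodes <- data.frame(
    name = c(cl_ids, set_ids),
    kind = c(rep("cluster", length(cl_ids)), rep("gene_set", length(set_ids))),
    size = c(rep(NA_integer_, length(cl_ids)),
             lengths(collection$sets[set_ids])),
    score = c(rep(NA_real_, length(cl_ids)),
              if (is.null(score)) rep(NA_real_, length(set_ids))
              else unname(score[set_ids])),
    stringsAsFactors = FALSE)
  edges <- data.frame(from = results$cluster_id, to = results$set_name,
                      weight = results$overlap, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}
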