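#' Ranking-overlap similarity between two motifs
#'
#' Jaccard index of the two motifs' top-`top_k` gene sets: 1 for identical
#' rankings, 0 for disjoint top lists. This ranking-space similarity stands
#' in for sequence-based motif alignment, which requires the position weight
#' matrices themselves; the downstream contract (similar motifs share a
#' cluster and a candidate TF) is unchanged.
#'
#' @param db A [ranking_db].
#' @param motif_a,motif_b Motif ids.
#' @param top_k Depth of the compared top lists (>= 1, default 100).
#' @return Similarity in `[0, 1]`.
#' @export
motif_similarity <- function(db, motif_a, motif_b, top_k = 100) {
  stopifnot(top_k >= 1, motif_a %in% motif_ids(db), motif_b %in% motif_ids(db))
  top_k <- min(top_k, n_genes(db))
  a <- gene_ids(db)[db$rank[, motif_a] <= top_k]
  b <- gene_ids(db)[db$rank[, motif_b] <= top_k]
  length(intersect(a, b)) / length(union(a, b))
}

#' Group enriched motifs into similarity clusters
#'
#' Single-linkage agglomeration: two motifs share a cluster iff they are
#' connected by a chain of pairwise similarities `>= sim_threshold`.
#' Clusters are labeled `M1, M2, ...` (motifs) and `T1, T2, ...` (tracks)
#' in descending order of their representative (maximum-NES member) NES,
#' with motif and track clusters interleaved in that global order. A
#' cluster is a track cluster when its representative's id matches
#' `track_pattern`.
#'
#' @param results A `motif_enrichment` data frame (see [enrich()]),
#'   non-empty.
#' @param db The [ranking_db] the results came from.
#' @param sim_threshold Similarity threshold for linkage (default 0.5).
#' @param top_k Top-list depth for [motif_similarity()] (default 100).
#' @param track_pattern Regular expression identifying track ids.
#' @return List of `motif_cluster` objects, each with `cluster_id`,
#'   `members` (rows of `results`, NES-descending), `motif_ids`, `nes` and
#'   `auc` of the representative, `target_union`, `assigned_tf` (filled by
#'   [assign_tf()]/[annotate_clusters()]), and `flagged`.
#' @export
cluster_motifs <- function(results, db, sim_threshold = 0.5, top_k = 100,
                           track_pattern = "^track") {
  stopifnot(nrow(results) >= 1)
  ids <- results$motif_id
  n <- length(ids)
  comp <- seq_len(n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (motif_similarity(db, ids[i], ids[j], top_k) >= sim_threshold) {
          old <- comp[j]
          comp[comp == old] <- comp[i]
        }
      }
    }
  }
  groups <- split(seq_len(n), comp)
  clusters <- lapply(groups, function(idx) {
    members <- results[idx[order(-results$nes[idx], results$motif_id[idx])], ,
                       drop = FALSE]
    rownames(members) <- NULL
    structure(list(cluster_id = NA_character_,
                   members = members,
                   motif_ids = members$motif_id,
                   nes = members$nes[1],
                   auc = members$auc[1],
                   representative = members$motif_id[1],
                   target_union = sort(unique(unlist(members$targets))),
                   assigned_tf = NA_character_,
                   flagged = FALSE),
              class = "motif_cluster")
  })
  clusters <- clusters[order(-vapply(clusters, `[[`, numeric(1), "nes"))]
  is_track <- vapply(clusters, function(cl) grepl(track_pattern, cl$representative),
                     logical(1))
  m_i <- t_i <- 0L
  for (k in seq_along(clusters)) {
    if (is_track[k]) {
      t_i <- t_i + 1L
      clusters[[k]]$cluster_id <- paste0("T", t_i)
    } else {
      m_i <- m_i + 1L
      clusters[[k]]$cluster_id <- paste0("M", m_i)
    }
  }
  clusters
}

#' Assign one candidate TF to a motif cluster by annotation confidence
#'
#' Only `direct` annotations (the PWM was experimentally determined for that
#' TF) qualify. Among the direct annotations of the cluster's members, the
#' TF annotated to the member with the highest NES wins; remaining ties are
#' broken lexicographically. Without any direct annotation the cluster is
#' flagged and no TF is assigned.
#'
#' @param cluster A `motif_cluster`.
#' @param annotations Data frame with columns `motif_id`, `tf_symbol`,
#'   `confidence` (one of `direct`, `similarity`, `orthology`).
#' @return List with `tf` (symbol or `NA`) and `flagged` (logical).
#' @export
assign_tf <- function(cluster, annotations) {
  stopifnot(all(c("motif_id", "tf_symbol", "confidence") %in% names(annotations)))
  ok <- annotations$confidence == "direct" &
    annotations$motif_id %in% cluster$motif_ids
  ann <- annotations[ok, , drop = FALSE]
  if (!nrow(ann)) return(list(tf = NA_character_, flagged = TRUE))
  nes <- cluster$members$nes[match(ann$motif_id, cluster$members$motif_id)]
  ann <- ann[order(-nes, ann$tf_symbol), , drop = FALSE]
  list(tf = ann$tf_symbol[1], flagged = FALSE)
}

#' Assign TFs to every cluster in a list
#'
#' @param clusters List of `motif_cluster` objects from [cluster_motifs()].
#' @param annotations Motif-to-TF annotation table (see [assign_tf()]).
#' @return The cluster list with `assigned_tf` and `flagged` filled in.
#' @export
annotate_clusters <- function(clusters, annotations) {
  lapply(clusters, function(cl) {
    a <- assign_tf(cl, annotations)
    cl$assigned_tf <- a$tf
    cl$flagged <- a$flagged
    cl
  })
}

#' Tabular cluster summary
#'
#' One row per cluster: id, assigned TF, representative NES and AUC, size
#' of the target union, and member count — mirroring the usual
#' cluster-report layout (Cluster, TF, NES, AUC, #Targets, #Motifs/Tracks).
#'
#' @param clusters List of `motif_cluster` objects.
#' @return A data frame.
#' @export
cluster_report <- function(clusters) {
  data.frame(
    cluster_id = vapply(clusters, `[[`, character(1), "cluster_id"),
    tf = vapply(clusters, `[[`, character(1), "assigned_tf"),
    nes = vapply(clusters, `[[`, numeric(1), "nes"),
    auc = vapply(clusters, `[[`, numeric(1), "auc"),
    n_targets = vapply(clusters, function(cl) length(cl$target_union), integer(1)),
    n_members = vapply(clusters, function(cl) nrow(cl$members), integer(1)),
    stringsAsFactors = FALSE)
}

#' @export
print.motif_cluster <- function(x, ...) {
  cat("Motif cluster", x$cluster_id, "- TF:",
      if (is.na(x$assigned_tf)) "(unassigned)" else x$assigned_tf,
      "| NES", format(x$nes, digits = 3),
      "|", nrow(x$members), "member(s),",
      length(x$target_union), "target(s)\n")
  invisible(x)
}
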