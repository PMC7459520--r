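#' Enrichment parameters
#'
#' Bundles the tunable thresholds of the rank-and-recovery enrichment step.
#' `motif_similarity_fdr` and `min_orthology_identity` parameterize the
#' construction of the ranking databases (upstream of this package) and are
#' carried as provenance metadata only.
#'
#' @param roc_fraction Top fraction of the ranking over which the recovery
#'   AUC is computed (default 0.03).
#' @param rank_threshold Maximum rank considered for target prediction
#'   (default 5000, clipped to the database size).
#' @param nes_threshold Minimum normalized enrichment score (default 3.0;
#'   a stricter post-hoc choice is 3.5).
#' @param auc_threshold Minimum recovery AUC (default 0.06; filter is strict
#'   `>`).
#' @param motif_similarity_fdr,min_orthology_identity Pass-through metadata.
#' @return An object of class `enrichment_params`.
#' @export
enrichment_params <- function(roc_fraction = 0.03, rank_threshold = 5000L,
                              nes_threshold = 3.0, auc_threshold = 0.06,
                              motif_similarity_fdr = 0.001,
                              min_orthology_identity = 0) {
  stopifnot(roc_fraction > 0, roc_fraction < 1, rank_threshold >= 1,
            nes_threshold >= 0, auc_threshold >= 0)
  structure(list(roc_fraction = roc_fraction,
                 rank_threshold = as.integer(rank_threshold),
                 nes_threshold = nes_threshold,
                 auc_threshold = auc_threshold,
                 motif_similarity_fdr = motif_similarity_fdr,
                 min_orthology_identity = min_orthology_identity),
            class = "enrichment_params")
}

# Seed genes absent from the database are dropped with a warning (the seed
# list is mapped onto the database's gene annotation, and losses are
# tolerated); an empty effective seed set is an error.
effective_seed <- function(db, seed_set, warn = TRUE) {
  seed_set <- unique(seed_set)
  present <- intersect(seed_set, gene_ids(db))
  n_lost <- length(seed_set) - length(present)
  if (n_lost > 0 && warn)
    warning(n_lost, " seed gene(s) absent from the ranking database were dropped")
  if (!length(present)) stop("no scoreable genes")
  present
}

# cumulative recovery counts rec(1..r_max) for the ranks of the seed genes
recovery_from_ranks <- function(r, r_max) {
  cumsum(tabulate(r[r <= r_max], nbins = r_max))
}

#' Cumulative recovery curve of a seed gene set along one motif ranking
#'
#' `rec(r)` counts how many seed genes have rank `<= r` in the motif's
#' ranking; the curve is non-decreasing and bounded by the seed-set size.
#'
#' @param db A [ranking_db].
#' @param motif_id Motif column to score.
#' @param seed_set Seed gene symbols; genes absent from the database are
#'   dropped with a warning.
#' @param r_max Curve length, `1 <= r_max <= n_genes(db)`.
#' @return Integer vector of length `r_max`.
#' @export
recovery_curve <- function(db, motif_id, seed_set, r_max) {
  stopifnot(motif_id %in% motif_ids(db), r_max >= 1, r_max <= n_genes(db))
  seed <- effective_seed(db, seed_set)
  recovery_from_ranks(db$rank[seed, motif_id], as.integer(r_max))
}

#' Recovery AUC in the top of the ranking
#'
#' The area under the cumulative recovery curve restricted to the top
#' `r_max` ranks, normalized to `[0, 1]`:
#' `AUC = sum(rec) / (r_max * n_seed)`.
#'
#' @param rec Recovery curve of length `r_max`.
#' @param r_max Number of top ranks (must be >= 1; a zero value after
#'   flooring the ROC fraction is an error).
#' @param n_seed Number of scoreable seed genes.
#' @return AUC in `[0, 1]`.
#' @export
recovery_auc <- function(rec, r_max, n_seed) {
  if (r_max < 1) stop("ranking too short for the requested ROC fraction")
  stopifnot(length(rec) == r_max, n_seed >= 1)
  sum(rec) / (r_max * n_seed)
}

#' Normalized enrichment scores
#'
#' Standardizes the AUC of each motif against the mean and population
#' standard deviation of the AUCs of the whole collection; the output has
#' mean 0 and population sd 1.
#'
#' @param aucs Named numeric vector of per-motif AUCs (>= 2 motifs).
#' @return Named numeric vector of NES values.
#' @export
nes_scores <- function(aucs) {
  x <- unlist(aucs)
  if (length(x) < 2) stop("need at least two motifs to standardize")
  mu <- mean(x)
  sdp <- sqrt(mean((x - mu)^2))
  if (sdp == 0) stop("degenerate AUC distribution")
  (x - mu) / sdp
}

#' Average recovery curve over all motifs of the collection
#'
#' @param db A [ranking_db].
#' @param seed_set Seed gene symbols.
#' @param r_max Curve length.
#' @return Numeric vector of length `r_max`.
#' @export
mean_recovery_curve <- function(db, seed_set, r_max) {
  seed <- effective_seed(db, seed_set)
  R <- db$rank[seed, , drop = FALSE]
  curves <- apply(R, 2, recovery_from_ranks, r_max = as.integer(r_max))
  rowMeans(curves)
}

#' Leading-edge target prediction for one motif
#'
#' The leading-edge rank `r*` maximizes the deviation of the motif's
#' recovery curve above the collection-average curve within the rank
#' threshold (smallest rank on ties); predicted targets are the seed genes
#' ranked at or above `r*`.
#'
#' @param db A [ranking_db].
#' @param motif_id Motif to score.
#' @param seed_set Seed gene symbols.
#' @param mean_curve Collection-average recovery curve, of length
#'   `min(rank_threshold, n_genes)` (see [mean_recovery_curve()]).
#' @param params An [enrichment_params] (unused beyond validation; the
#'   curve length carries the rank threshold).
#' @return List with `targets` (character) and `leading_edge_rank` (integer).
#' @export
predict_targets <- function(db, motif_id, seed_set, mean_curve,
                            params = enrichment_params()) {
  L <- length(mean_curve)
  stopifnot(L >= 1, L <= n_genes(db))
  seed <- effective_seed(db, seed_set)
  rec <- recovery_from_ranks(db$rank[seed, motif_id], L)
  rstar <- which.max(rec - mean_curve)
  list(targets = seed[db$rank[seed, motif_id] <= rstar],
       leading_edge_rank = as.integer(rstar))
}

#' Rank-and-recovery motif enrichment over a full collection
#'
#' Computes the recovery AUC of the seed set in the top
#' `floor(roc_fraction * G)` ranks of every motif, standardizes AUCs into
#' NES over the whole collection, predicts leading-edge targets against the
#' collection-average recovery curve, and (by default) filters to motifs
#' with `NES >= nes_threshold` and `AUC > auc_threshold`, sorted by NES
#' descending.
#'
#' @param db A [ranking_db].
#' @param seed_set Seed gene symbols.
#' @param params An [enrichment_params].
#' @param filter If `FALSE`, return all motifs unfiltered (still sorted).
#' @return A data frame of class `motif_enrichment` with columns
#'   `motif_id`, `auc`, `nes`, `leading_edge_rank`, `n_targets`, and a list
#'   column `targets`.
#' @export
enrich <- function(db, seed_set, params = enrichment_params(), filter = TRUE) {
  G <- n_genes(db)
  seed <- effective_seed(db, seed_set)
  n_seed <- length(seed)
  r_max <- max(1L, as.integer(floor(params$roc_fraction * G)))
  L <- min(params$rank_threshold, G)
  R <- db$rank[seed, , drop = FALSE]
  curves <- apply(R, 2, recovery_from_ranks, r_max = L)
  if (is.null(dim(curves))) curves <- matrix(curves, nrow = L)
  aucs <- colSums(curves[seq_len(r_max), , drop = FALSE]) / (r_max * n_seed)
  names(aucs) <- motif_ids(db)
  nes <- nes_scores(aucs)
  mean_curve <- rowMeans(curves)
  dev <- curves - mean_curve
  rstar <- apply(dev, 2, which.max)
  targets <- lapply(seq_along(rstar), function(j) seed[R[, j] <= rstar[j]])
  out <- data.frame(motif_id = motif_ids(db),
                    auc = aucs,
                    nes = nes,
                    leading_edge_rank = as.integer(rstar),
                    n_targets = lengths(targets),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$targets <- targets
  if (filter)
    out <- out[out$nes >= params$nes_threshold & out$auc > params$auc_threshold, ]
  out <- out[order(-out$nes, out$motif_id), ]
  rownames(out) <- NULL
  class(out) <- c("motif_enrichment", "data.frame")
  out
}
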