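#' Planted regulon ground truth
#'
#' Describes one planted regulator for the synthetic-data generator: a TF, the
#' motif ids annotated to it, its target genes, and the probability that each
#' target is placed inside the top window of the motif ranking.
#'
#' @param tf_symbol Regulator symbol.
#' @param motif_ids One or more motif ids mapped to this TF.
#' @param target_genes Target gene symbols (a subset of the seed gene list).
#' @param signal_strength Probability in `[0, 1]` that a target is up-ranked
#'   into the top window.
#' @return An object of class `planted_regulon`.
#' @export
planted_regulon <- function(tf_symbol, motif_ids, target_genes, signal_strength) {
  stopifnot(length(tf_symbol) == 1, length(motif_ids) >= 1,
            length(target_genes) >= 1,
            signal_strength >= 0, signal_strength <= 1)
  structure(list(tf_symbol = tf_symbol, motif_ids = motif_ids,
                 target_genes = unique(target_genes),
                 signal_strength = signal_strength),
            class = "planted_regulon")
}

#' Generate a synthetic ranking database with planted regulons
#'
#' Every motif column is a permutation of `1..n_genes`. For a planted motif,
#' each target gene is placed uniformly at random within the top window
#' (ranks `1..floor(window_fraction * n_genes)`) with probability
#' `signal_strength`, otherwise it is ranked like any other gene; non-planted
#' (decoy) motifs are uniform random permutations, the null model against
#' which enrichment is standardized. Annotations link each planted motif to
#' its TF with `direct` confidence (plus a decoy `similarity` annotation, so
#' that the direct-annotation-wins rule is exercised non-trivially) and each
#' decoy motif to a decoy TF with `similarity` or `orthology` confidence.
#'
#' @param n_genes Number of genes (>= 10).
#' @param n_motifs Total number of motifs including planted ones (>= 2).
#' @param planted A `planted_regulon` or list of them.
#' @param rng_seed Integer seed; the generator is a pure function of it.
#' @param window_fraction Top-window fraction for planted targets (default
#'   0.03, matching the recovery AUC fraction).
#' @param gene_ids Optional gene symbols (default `g0001..`); planted targets
#'   must be among them.
#' @return A list with elements `db` (a [ranking_db]) and `annotations`
#'   (data frame with columns `motif_id`, `tf_symbol`, `confidence`).
#' @export
gen_ranking_db <- function(n_genes, n_motifs, planted = list(), rng_seed = 1L,
                           window_fraction = 0.03, gene_ids = NULL) {
  stopifnot(n_genes >= 10, n_motifs >= 2)
  if (inherits(planted, "planted_regulon")) planted <- list(planted)
  planted_motifs <- unlist(lapply(planted, `[[`, "motif_ids"))
  if (anyDuplicated(planted_motifs)) stop("duplicate motif ids among planted regulons")
  if (length(planted_motifs) > n_motifs)
    stop("more planted motifs than n_motifs")
  if (is.null(gene_ids)) gene_ids <- sprintf("g%04d", seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes)
  w <- floor(window_fraction * n_genes)
  for (pr in planted) {
    if (!all(pr$target_genes %in% gene_ids))
      stop("planted target genes absent from the gene universe")
    if (w < length(pr$target_genes))
      stop("infeasible signal: top window of ", w,
           " ranks cannot hold ", length(pr$target_genes), " targets")
  }
  set.seed(rng_seed)
  n_decoys <- n_motifs - length(planted_motifs)
  decoy_motifs <- if (n_decoys > 0) sprintf("mot_dec_%03d", seq_len(n_decoys)) else character()
  all_motifs <- c(planted_motifs, decoy_motifs)
  rank <- matrix(0L, n_genes, n_motifs, dimnames = list(gene_ids, all_motifs))

  ann <- list()
  n_decoy_tfs <- max(2L, ceiling(n_motifs / 5))
  decoy_tfs <- sprintf("TFdec%03d", seq_len(n_decoy_tfs))

  for (pr in planted) {
    tg_idx <- match(pr$target_genes, gene_ids)
    for (m in pr$motif_ids) {
      keep <- tg_idx[stats::runif(length(tg_idx)) < pr$signal_strength]
      win_ranks <- sample.int(w, length(keep))
      ranks <- integer(n_genes)
      ranks[keep] <- win_ranks
      rest_genes <- setdiff(seq_len(n_genes), keep)
      rest_ranks <- setdiff(seq_len(n_genes), win_ranks)
      ranks[rest_genes] <- rest_ranks[sample.int(length(rest_ranks))]
      rank[, m] <- ranks
      ann[[length(ann) + 1L]] <- data.frame(
        motif_id = m,
        tf_symbol = c(pr$tf_symbol, decoy_tfs[1 + (length(ann) %% n_decoy_tfs)]),
        confidence = c("direct", "similarity"),
        stringsAsFactors = FALSE)
    }
  }
  for (m in decoy_motifs) {
    rank[, m] <- sample.int(n_genes)
    ann[[length(ann) + 1L]] <- data.frame(
      motif_id = m,
      tf_symbol = sample(decoy_tfs, 1),
      confidence = sample(c("similarity", "orthology"), 1),
      stringsAsFactors = FALSE)
  }
  annotations <- do.call(rbind, ann)
  annotations <- annotations[!duplicated(annotations[c("motif_id", "tf_symbol")]), ]
  rownames(annotations) <- NULL
  list(db = ranking_db(rank), annotations = annotations)
}

#' Protein-protein interaction table
#'
#' @param rows Data frame with columns `source`, `target`,
#'   `evidence_count` (integer >= 1). Self-interactions are rejected.
#' @return An object of class `interaction_table`.
#' @export
interaction_table <- function(rows) {
  stopifnot(all(c("source", "target", "evidence_count") %in% names(rows)))
  if (any(rows$source == rows$target)) stop("self-interactions are not allowed")
  if (any(rows$evidence_count < 1)) stop("evidence_count must be >= 1")
  rows <- unique(rows[c("source", "target", "evidence_count")])
  rownames(rows) <- NULL
  structure(list(rows = rows), class = "interaction_table")
}

#' Kinase-substrate table
#'
#' @param substrates Named list mapping each kinase to its substrate set
#'   (non-empty character vectors).
#' @param universe Background universe; default all proteins appearing as
#'   substrates in the table.
#' @return An object of class `kinase_substrate_table`.
#' @export
kinase_substrate_table <- function(substrates,
                                   universe = sort(unique(unlist(substrates)))) {
  stopifnot(length(substrates) >= 1, !is.null(names(substrates)))
  if (any(!nzchar(names(substrates)))) stop("kinases must be named")
  if (any(lengths(substrates) == 0)) stop("substrate sets must be non-empty")
  substrates <- lapply(substrates, unique)
  structure(list(substrates = substrates, universe = universe),
            class = "kinase_substrate_table")
}

#' Generate a hub-structured synthetic interactome and kinase table
#'
#' Each hub TF receives `neighbors_per_hub` direct protein neighbors with
#' both edge orientations represented; additional background edges connect
#' random protein pairs. The first kinase is planted: its substrate set is
#' exactly the expansion set (the hubs plus all their direct neighbors), so
#' that a hypergeometric kinase enrichment over the expansion set must rank
#' it first. Remaining kinases draw substrates from the whole proteome with
#' a mild preference for hub-adjacent proteins.
#'
#' @param hub_tfs Hub TF symbols.
#' @param n_proteins Number of background proteins (>= `length(hub_tfs)`).
#' @param n_kinases Number of kinases (>= 1); the first is planted.
#' @param rng_seed Integer seed.
#' @param neighbors_per_hub Direct PPI neighbors per hub (<= `n_proteins`).
#' @param extra_edges Background protein-protein edges.
#' @param complex_edges Additional edges drawn among the expansion set,
#'   emulating the dense wiring of transcriptional complexes (real
#'   hub-centered PPI neighborhoods are far denser than random background).
#' @param max_evidence Evidence counts are drawn from `1..max_evidence`.
#' @param hub_bias Probability that a decoy-kinase substrate is hub-adjacent.
#' @return A list with `ppi` ([interaction_table]), `kinase_db`
#'   ([kinase_substrate_table]), `planted_kinase` (symbol) and
#'   `expansion_set` (hubs plus direct neighbors).
#' @export
gen_interactome <- function(hub_tfs, n_proteins = 60, n_kinases = 10,
                            rng_seed = 1L, neighbors_per_hub = 8,
                            extra_edges = 40, complex_edges = 15 * neighbors_per_hub,
                            max_evidence = 5, hub_bias = 0.3) {
  stopifnot(length(hub_tfs) >= 1, n_kinases >= 1,
            n_proteins >= length(hub_tfs))
  if (neighbors_per_hub > n_proteins)
    stop("requested more neighbors per hub than available proteins")
  set.seed(rng_seed)
  proteins <- sprintf("P%03d", seq_len(n_proteins))
  rows <- list()
  nbr_of <- list()
  for (h in hub_tfs) {
    nb <- sample(proteins, neighbors_per_hub)
    nbr_of[[h]] <- nb
    half <- ceiling(length(nb) / 2)
    out_nb <- nb[seq_len(half)]
    in_nb <- nb[setdiff(seq_along(nb), seq_len(half))]
    rows[[length(rows) + 1L]] <- data.frame(
      source = c(rep(h, length(out_nb)), in_nb),
      target = c(out_nb, rep(h, length(in_nb))),
      stringsAsFactors = FALSE)
  }
  expansion_pool <- unique(c(hub_tfs, unlist(nbr_of)))
  if (complex_edges > 0 && length(expansion_pool) >= 2) {
    src <- sample(expansion_pool, complex_edges, replace = TRUE)
    tgt <- sample(expansion_pool, complex_edges, replace = TRUE)
    ok <- src != tgt
    rows[[length(rows) + 1L]] <- data.frame(source = src[ok], target = tgt[ok],
                                            stringsAsFactors = FALSE)
  }
  if (extra_edges > 0 && n_proteins >= 2) {
    src <- sample(proteins, extra_edges, replace = TRUE)
    tgt <- sample(proteins, extra_edges, replace = TRUE)
    ok <- src != tgt
    rows[[length(rows) + 1L]] <- data.frame(source = src[ok], target = tgt[ok],
                                            stringsAsFactors = FALSE)
  }
  tab <- unique(do.call(rbind, rows))
  tab$evidence_count <- sample.int(max_evidence, nrow(tab), replace = TRUE)

  expansion_set <- unique(c(hub_tfs, unlist(nbr_of)))
  kinases <- sprintf("K%02d", seq_len(n_kinases))
  subs <- list()
  subs[[kinases[1]]] <- expansion_set
  if (n_kinases > 1) {
    for (k in kinases[-1]) {
      s <- sample(5:15, 1)
      n_hubby <- stats::rbinom(1, s, hub_bias)
      members <- unique(c(
        sample(expansion_set, min(n_hubby, length(expansion_set))),
        sample(proteins, s - min(n_hubby, length(expansion_set)))))
      if (!length(members)) members <- sample(proteins, 1)
      subs[[k]] <- members
    }
  }
  list(ppi = interaction_table(tab),
       kinase_db = kinase_substrate_table(subs),
       planted_kinase = kinases[1],
       expansion_set = expansion_set)
}

#' Generate a synthetic gene-set collection with planted pathway sets
#'
#' Emits GMT-conformant named sets over `universe`. For every planted cluster
#' one set contains `planted_coverage` (default 80%, hence at least half) of
#' that cluster's members, guaranteeing a significant hypergeometric overlap
#' at typical sizes; the other sets are random draws. Each set carries a
#' score emulating a gene-set-enrichment NES.
#'
#' @param universe Gene/protein symbol universe (non-empty).
#' @param n_sets Total number of sets (>= 1), planted ones included.
#' @param planted_clusters A character vector or list of them; one planted
#'   set is emitted per cluster.
#' @param rng_seed Integer seed.
#' @param planted_coverage Fraction of each planted cluster covered.
#' @param size_range Size range of the random sets.
#' @return A [gene_set_collection].
#' @export
gen_genesets <- function(universe, n_sets, planted_clusters = list(),
                         rng_seed = 1L, planted_coverage = 0.8,
                         size_range = c(15, 60)) {
  if (!length(universe)) stop("empty universe")
  stopifnot(n_sets >= 1)
  if (is.character(planted_clusters)) planted_clusters <- list(planted_clusters)
  if (length(planted_clusters) > n_sets)
    stop("more planted clusters than sets")
  set.seed(rng_seed)
  sets <- list()
  for (i in seq_along(planted_clusters)) {
    cl <- intersect(planted_clusters[[i]], universe)
    if (!length(cl)) stop("planted cluster ", i, " is disjoint from the universe")
    sets[[sprintf("planted_pathway_%02d", i)]] <-
      sample(cl, ceiling(planted_coverage * length(cl)))
  }
  n_rand <- n_sets - length(planted_clusters)
  if (n_rand > 0) {
    sizes <- sample(size_range[1]:size_range[2], n_rand, replace = TRUE)
    sizes <- pmin(sizes, length(universe))
    for (i in seq_len(n_rand))
      sets[[sprintf("random_pathway_%02d", i)]] <- sample(universe, sizes[i])
  }
  score <- round(stats::runif(length(sets), 1.5, 3), 2) *
    sample(c(-1, 1), length(sets), replace = TRUE)
  names(score) <- names(sets)
  gene_set_collection(sets, score = score)
}

#' Generate a complete synthetic world with planted ground truth
#'
#' Bundles all pipeline inputs with the statistical structure the analysis
#' assumes: a seed gene list, a motif ranking database with planted regulons
#' whose targets are up-ranked, motif-to-TF annotations, a hub-structured
#' interactome, a kinase-substrate table with a planted kinase covering the
#' expansion set, and a pathway collection with one planted set per hub.
#' Defaults are the package's reference simulation conditions: 172 seed
#' genes among 2000, 50 motifs of which 3 are planted regulons with 30
#' disjoint targets each at full signal strength, 10 kinases.
#'
#' @param n_genes,n_motifs Ranking-database dimensions.
#' @param n_seed_genes Size of the seed (co-expressed) gene list.
#' @param n_regulons Number of planted regulons (one motif and one TF each).
#' @param targets_per_regulon Disjoint targets per regulon
#'   (`n_regulons * targets_per_regulon <= n_seed_genes`).
#' @param signal_strength Probability a planted target lands in the top window.
#' @param n_proteins,n_kinases,neighbors_per_hub Interactome sizes.
#' @param n_gene_sets Pathway collection size.
#' @param rng_seed Integer seed; all randomness flows from it.
#' @return An object of class `synthetic_world`: a list with `seed_genes`,
#'   `db`, `annotations`, `interactome`, `kinase_db`, `gene_sets`, `truth`
#'   (list of [planted_regulon]), `planted_kinase`, and `rng_seed`.
#' @export
gen_world <- function(n_genes = 2000, n_motifs = 50, n_seed_genes = 172,
                      n_regulons = 3, targets_per_regulon = 30,
                      signal_strength = 1.0, n_proteins = 60, n_kinases = 10,
                      neighbors_per_hub = 8, n_gene_sets = 25, rng_seed = 1L) {
  stopifnot(n_regulons * targets_per_regulon <= n_seed_genes)
  set.seed(rng_seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 3)
  genes <- sprintf("g%04d", seq_len(n_genes))
  seed_genes <- sort(sample(genes, n_seed_genes))
  target_pool <- sample(seed_genes, n_regulons * targets_per_regulon)
  tfs <- sprintf("TF%02d", seq_len(n_regulons))
  truth <- lapply(seq_len(n_regulons), function(i) {
    planted_regulon(
      tf_symbol = tfs[i],
      motif_ids = sprintf("mot_%s", tolower(tfs[i])),
      target_genes = target_pool[((i - 1) * targets_per_regulon + 1):(i * targets_per_regulon)],
      signal_strength = signal_strength)
  })
  rdb <- gen_ranking_db(n_genes, n_motifs, truth, rng_seed = sub_seeds[1],
                        gene_ids = genes)
  inter <- gen_interactome(tfs, n_proteins = n_proteins, n_kinases = n_kinases,
                           rng_seed = sub_seeds[2],
                           neighbors_per_hub = neighbors_per_hub)
  ppi_nodes <- unique(c(inter$ppi$rows$source, inter$ppi$rows$target))
  universe <- unique(c(seed_genes, ppi_nodes, names(inter$kinase_db$substrates)))
  planted_clusters <- lapply(truth, function(pr) {
    nb <- unique(c(
      inter$ppi$rows$target[inter$ppi$rows$source == pr$tf_symbol],
      inter$ppi$rows$source[inter$ppi$rows$target == pr$tf_symbol]))
    unique(c(pr$tf_symbol, pr$target_genes, nb, inter$planted_kinase))
  })
  gs <- gen_genesets(universe, n_gene_sets, planted_clusters,
                     rng_seed = sub_seeds[3])
  structure(list(seed_genes = seed_genes,
                 db = rdb$db,
                 annotations = rdb$annotations,
                 interactome = inter$ppi,
                 kinase_db = inter$kinase_db,
                 gene_sets = gs,
                 truth = truth,
                 planted_kinase = inter$planted_kinase,
                 expansion_set = inter$expansion_set,
                 rng_seed = rng_seed),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic world:", length(x$seed_genes), "seed genes,",
      ncol(x$db$rank), "motifs (", length(x$truth), "planted regulons ),",
      length(x$kinase_db$substrates), "kinases, seed", x$rng_seed, "\n")
  invisible(x)
}
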