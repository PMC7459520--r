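# Published reference tables of a master-regulator analysis, used as fixed
# inputs: per-cluster representative enrichment scores and the candidate-TF
# centrality triples of a reconstructed TF-gene regulatory network.

table1_clusters <- function() {
  data.frame(
    cluster = c("M1", "M2", "T1", "M3", "M4", "M5", "M6", "M7", "M8"),
    tf = c("TBP", "NFKB1", "CHD1", "SPIB", "SRF", "BCL6", "PAX3", "ATF2", "CEBPE"),
    nes = c(6.20, 5.91, 5.23, 5.12, 4.66, 4.14, 4.07, 3.58, 3.53),
    auc = c(0.098, 0.095, 0.130, 0.085, 0.080, 0.074, 0.073, 0.068, 0.067),
    n_targets = c(74, 91, 29, 104, 53, 55, 48, 46, 50),
    stringsAsFactors = FALSE)
}

table2_centralities <- function() {
  data.frame(
    id = c("SPIB", "NFKB1", "TBP", "BCL6", "SRF", "CEBPE", "PAX3", "ATF2", "CHD1"),
    kind = "tf",
    degree = c(104, 91, 74, 55, 53, 50, 48, 46, 29),
    betweenness = c(0.36, 0.22, 0.14, 0.08, 0.08, 0.08, 0.05, 0.06, 0.04),
    radiality = c(3.41, 3.24, 3.02, 2.77, 2.75, 2.71, 2.68, 2.65, 2.43),
    stringsAsFactors = FALSE)
}

# a fast, structurally complete world for pipeline-level tests
tiny_world <- function(seed = 1L) {
  gen_world(n_genes = 400, n_motifs = 10, n_seed_genes = 40, n_regulons = 2,
            targets_per_regulon = 10, signal_strength = 0.95,
            n_proteins = 20, n_kinases = 5, neighbors_per_hub = 4,
            n_gene_sets = 8, rng_seed = seed)
}

tiny_params <- function() enrichment_params(nes_threshold = 1.5)

# random directed edge list over n nodes (no self loops, no duplicates)
random_edges <- function(n, p = 0.3) {
  grid <- expand.grid(from = seq_len(n), to = seq_len(n))
  grid <- grid[grid$from != grid$to, ]
  grid <- grid[stats::runif(nrow(grid)) < p, , drop = FALSE]
  nodes <- paste0("n", seq_len(n))
  data.frame(from = nodes[grid$from], to = nodes[grid$to],
             stringsAsFactors = FALSE)
}

graph_from_edges <- function(edges, n) {
  nodes <- paste0("n", seq_len(n))
  vert <- data.frame(name = nodes, kind = "protein", stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vert)
}
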