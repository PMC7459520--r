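write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  listcols <- vapply(df, is.list, logical(1))
  for (cn in names(df)[listcols])
    df[[cn]] <- vapply(df[[cn]], paste, character(1), collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Export a network as node/edge TSV tables and GraphML
#'
#' @param net An igraph object.
#' @param prefix Output path prefix; writes `<prefix>_nodes.tsv`,
#'   `<prefix>_edges.tsv`, `<prefix>.graphml`.
#' @return The three paths, invisibly.
#' @export
write_network_tables <- function(net, prefix) {
  nodes <- igraph::as_data_frame(net, what = "vertices")
  edges <- igraph::as_data_frame(net, what = "edges")
  paths <- c(paste0(prefix, "_nodes.tsv"), paste0(prefix, "_edges.tsv"),
             paste0(prefix, ".graphml"))
  write_tsv(nodes, paths[1])
  write_tsv(edges, paths[2])
  igraph::write_graph(net, paths[3], format = "graphml")
  invisible(paths)
}

#' Run the full master-regulator inference pipeline
#'
#' Composes the analysis end to end on a synthetic (or equivalently
#' structured) world: motif enrichment on the seed genes, similarity
#' clustering with TF assignment, TF-gene network construction with
#' undirected centrality analysis and tertile hub selection, one-hop PPI
#' expansion of the hubs, hypergeometric kinase enrichment with
#' combined-score selection, directed centrality z-scores of the extended
#' (hub + interactor + kinase) network, hub-centered transcriptional
#' clusters, and hypergeometric cluster-to-pathway overlap with its
#' bipartite enrichment network. The pipeline itself draws no random
#' numbers: identical inputs and configuration give byte-identical outputs.
#'
#' @param world A `synthetic_world` (see [gen_world()]), or any list with
#'   the same named inputs.
#' @param params An [enrichment_params].
#' @param sim_threshold,top_k Motif clustering controls
#'   (see [cluster_motifs()]).
#' @param min_evidence PPI evidence threshold (see [expand_ppi()]).
#' @param kinase_alpha Adjusted-p threshold for kinase selection.
#' @param overlap_alpha,min_fraction Overlap significance controls
#'   (see [overlap_analysis()]).
#' @param universe Optional pathway universe override.
#' @param outdir Optional directory; when given, every intermediate is
#'   written as TSV (plus GraphML for networks) together with a JSON run
#'   manifest echoing the configuration, seed, and collected warnings.
#' @return A list of class `regmaster_pipeline` with elements `enrichment`,
#'   `clusters`, `cluster_table`, `grn`, `grn_report`, `hubs`, `expansion`,
#'   `kinases`, `kinases_selected`, `extended_report`, `network`,
#'   `tclusters`, `overlaps`, `enrichment_net`, `config`, `warnings`.
#' @export
run_pipeline <- function(world, params = enrichment_params(),
                         sim_threshold = 0.5, top_k = 100, min_evidence = 1,
                         kinase_alpha = 0.01, overlap_alpha = 0.01,
                         min_fraction = 0.05, universe = NULL, outdir = NULL) {
  warn_log <- character()
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warn_log <<- c(warn_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  stage <- function(name, expr) {
    tryCatch(collect(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  enr <- stage("enrich", enrich(world$db, world$seed_genes, params))
  if (!nrow(enr)) stop("no enriched motifs at the configured thresholds")
  clusters <- stage("cluster_motifs",
                    cluster_motifs(enr, world$db, sim_threshold, top_k))
  clusters <- stage("assign_tf", annotate_clusters(clusters, world$annotations))
  grn <- stage("build_grn", build_grn(clusters))
  grn_report <- stage("topology", centralities(grn, treat_directed = FALSE))
  hubs <- stage("select_hubs", select_hubs(grn_report))
  if (!length(hubs)) stop("empty hub set after topological selection")
  expansion <- stage("expand_ppi",
                     expand_ppi(hubs, world$interactome, min_evidence))
  query <- igraph::V(expansion)$name
  kin <- stage("kinase_enrichment",
               suppressMessages(kinase_enrichment(query, world$kinase_db,
                                                  kinase_alpha)))
  kin_sel <- stage("select_kinases", select_kinases(kin, kinase_alpha))
  ext_net <- stage("extended_network",
                   combined_network(expansion = expansion,
                                    kinases = kin_sel$kinase,
                                    kdb = world$kinase_db))
  ext_report <- stage("extended_topology",
                      zscores(centralities(ext_net, treat_directed = TRUE)))
  full_net <- stage("combined_network",
                    combined_network(grn, expansion, kin_sel$kinase,
                                     world$kinase_db))
  tclusters <- stage("transcriptional_clusters",
                     stats::setNames(
                       lapply(hubs, transcriptional_cluster, net = full_net),
                       hubs))
  overlaps <- stage("overlap_analysis",
                    suppressMessages(
                      overlap_analysis(tclusters, world$gene_sets,
                                       overlap_alpha, min_fraction, universe)))
  enet <- stage("enrichment_network",
                enrichment_network(overlaps, world$gene_sets))

  config <- list(roc_fraction = params$roc_fraction,
                 rank_threshold = params$rank_threshold,
                 nes_threshold = params$nes_threshold,
                 auc_threshold = params$auc_threshold,
                 sim_threshold = sim_threshold, top_k = top_k,
                 min_evidence = min_evidence, kinase_alpha = kinase_alpha,
                 overlap_alpha = overlap_alpha, min_fraction = min_fraction,
                 rng_seed = world$rng_seed)
  result <- structure(list(enrichment = enr,
                           clusters = clusters,
                           cluster_table = cluster_report(clusters),
                           grn = grn, grn_report = grn_report, hubs = hubs,
                           expansion = expansion, kinases = kin,
                           kinases_selected = kin_sel,
                           extended_report = ext_report,
                           network = full_net, tclusters = tclusters,
                           overlaps = overlaps, enrichment_net = enet,
                           config = config, warnings = warn_log),
                      class = "regmaster_pipeline")
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  result
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_tsv(result$enrichment, p("motif_enrichment.tsv"))
  write_tsv(result$cluster_table, p("motif_clusters.tsv"))
  write_tsv(result$grn_report$nodes, p("grn_centralities.tsv"))
  write_tsv(result$grn_report$edges, p("grn_edge_betweenness.tsv"))
  write_network_tables(result$grn, p("grn"))
  write_tsv(result$kinases, p("kinase_enrichment.tsv"))
  write_tsv(result$kinases_selected, p("kinases_selected.tsv"))
  write_tsv(result$extended_report$nodes, p("extended_centralities.tsv"))
  write_network_tables(result$network, p("combined_network"))
  tc <- data.frame(hub = rep(names(result$tclusters),
                             lengths(result$tclusters)),
                   member = unlist(result$tclusters, use.names = FALSE),
                   stringsAsFactors = FALSE)
  write_tsv(tc, p("transcriptional_clusters.tsv"))
  write_tsv(result$overlaps, p("pathway_overlaps.tsv"))
  if (igraph::vcount(result$enrichment_net) > 0)
    write_network_tables(result$enrichment_net, p("enrichment_network"))
  manifest <- list(package = "regmaster",
                   version = as.character(utils::packageVersion("regmaster")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   config = result$config,
                   hubs = result$hubs,
                   n_clusters = length(result$clusters),
                   n_kinases_selected = nrow(result$kinases_selected),
                   n_significant_overlaps = nrow(result$overlaps),
                   warnings = result$warnings)
  jsonlite::write_json(manifest, p("run_manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.regmaster_pipeline <- function(x, ...) {
  cat("regmaster pipeline run\n")
  cat("  enriched motifs/tracks:", nrow(x$enrichment), "in",
      length(x$clusters), "cluster(s)\n")
  cat("  hub TFs:", paste(x$hubs, collapse = ", "), "\n")
  cat("  kinases selected:", paste(x$kinases_selected$kinase, collapse = ", "),
      "\n")
  cat("  significant pathway overlaps:", nrow(x$overlaps), "\n")
  invisible(x)
}
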