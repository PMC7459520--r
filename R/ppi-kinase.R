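#' Expand hub TFs to their direct PPI interactors
#'
#' One-hop expansion: the node set is the hubs plus every protein with a
#' direct interaction (either orientation, evidence count at least
#' `min_evidence`) with at least one hub; the edges are all table rows with
#' both endpoints in that node set, kept with their recorded direction.
#' Hubs absent from the table are retained as isolated nodes with a warning.
#'
#' @param hubs Hub TF symbols (non-empty).
#' @param ppi An [interaction_table].
#' @param min_evidence Minimum evidence count for a row to qualify.
#' @return An igraph object with vertex attribute `kind` (`tf` for hubs,
#'   `protein` otherwise) and edge attributes `provenance = "ppi"` and
#'   `evidence_count`.
#' @export
expand_ppi <- function(hubs, ppi, min_evidence = 1) {
  stopifnot(length(hubs) >= 1, inherits(ppi, "interaction_table"))
  tab <- ppi$rows[ppi$rows$evidence_count >= min_evidence, , drop = FALSE]
  touching <- tab$source %in% hubs | tab$target %in% hubs
  nbrs <- setdiff(unique(c(tab$source[touching], tab$target[touching])), hubs)
  nodes <- c(hubs, nbrs)
  absent <- setdiff(hubs, c(ppi$rows$source, ppi$rows$target))
  if (length(absent))
    warning("hub(s) absent from the interaction table kept as isolated nodes: ",
            paste(absent, collapse = ", "))
  edges <- tab[tab$source %in% nodes & tab$target %in% nodes, , drop = FALSE]
  edges <- data.frame(from = edges$source, to = edges$target,
                      provenance = "ppi",
                      evidence_count = edges$evidence_count,
                      stringsAsFactors = FALSE)
  vert <- data.frame(name = nodes,
                     kind = ifelse(nodes %in% hubs, "tf", "protein"),
                     stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vert)
}

#' Hypergeometric kinase enrichment over a query protein set
#'
#' For each kinase with substrate set `K` in a background universe `U` (all
#' proteins appearing as substrates), the overlap `k = |K intersect query|`
#' is scored with the hypergeometric upper tail `P(X >= k)` (equivalently a
#' one-sided Fisher exact test), adjusted by Benjamini-Hochberg across all
#' tested kinases. The standardized overlap
#' `z = (k - E[X]) / sqrt(Var[X])` under the same hypergeometric yields a
#' combined score `-log(p) * z`, monotone in both evidence strength and
#' effect size; results are sorted by it.
#'
#' @param query Query protein symbols; symbols outside the universe are
#'   dropped with a message, an empty effective query is an error.
#' @param kdb A [kinase_substrate_table].
#' @param alpha Nominal significance level used for the `significant`
#'   marker column (default 0.01).
#' @return A data frame of class `kinase_enrichment` with columns `kinase`,
#'   `n_substrates`, `overlap`, `p_nominal`, `p_adjusted`, `z`,
#'   `combined_score`, `significant`.
#' @export
kinase_enrichment <- function(query, kdb, alpha = 0.01) {
  stopifnot(inherits(kdb, "kinase_substrate_table"))
  query <- unique(query)
  U <- kdb$universe
  q <- intersect(query, U)
  dropped <- length(query) - length(q)
  if (dropped > 0)
    message(dropped, " query symbol(s) outside the kinase background universe dropped")
  if (!length(q)) stop("empty query after restriction to the kinase universe")
  N <- length(U)
  nq <- length(q)
  res <- lapply(names(kdb$substrates), function(kin) {
    K <- intersect(kdb$substrates[[kin]], U)
    k <- length(intersect(K, q))
    Kn <- length(K)
    lp <- stats::phyper(k - 1, Kn, N - Kn, nq, lower.tail = FALSE, log.p = TRUE)
    ex <- nq * Kn / N
    vr <- nq * (Kn / N) * (1 - Kn / N) * (N - nq) / max(N - 1, 1)
    z <- if (vr > 0) (k - ex) / sqrt(vr) else 0
    data.frame(kinase = kin, n_substrates = Kn, overlap = k,
               p_nominal = exp(lp), z = z, combined_score = -lp * z,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p_nominal, method = "BH")
  out$significant <- out$p_nominal < alpha
  out <- out[order(-out$combined_score, out$kinase),
             c("kinase", "n_substrates", "overlap", "p_nominal", "p_adjusted",
               "z", "combined_score", "significant")]
  rownames(out) <- NULL
  class(out) <- c("kinase_enrichment", "data.frame")
  out
}

#' Select the most significant kinases
#'
#' Keeps kinases with BH-adjusted p below `alpha_adj`, then returns the
#' upper tertile (top `ceiling(n/3)` positions, combined-score ties at the
#' boundary included) of that significant set ranked by combined score.
#'
#' @param results A `kinase_enrichment` data frame.
#' @param alpha_adj Adjusted-p threshold (default 0.01).
#' @return The selected rows (possibly empty, with a warning), with a
#'   `boundary_tied` attribute flagging whether ties enlarged the tertile.
#' @export
select_kinases <- function(results, alpha_adj = 0.01) {
  sig <- results[results$p_adjusted < alpha_adj, , drop = FALSE]
  if (!nrow(sig)) {
    warning("no kinase significant at adjusted p < ", alpha_adj)
    return(sig)
  }
  sig <- sig[order(-sig$combined_score, sig$kinase), , drop = FALSE]
  t_size <- ceiling(nrow(sig) / 3)
  cut <- sig$combined_score[t_size]
  out <- sig[sig$combined_score >= cut, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "boundary_tied") <- nrow(out) > t_size
  out
}
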