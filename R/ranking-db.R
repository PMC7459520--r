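#' Motif ranking database
#'
#' A ranking database stores, for every motif (or ChIP-seq track treated as a
#' motif), a total ranking of all genes: rank 1 is the gene most likely to be
#' a genomic target of that motif. It is the substrate of the rank-and-recovery
#' enrichment procedure.
#'
#' @param rank Integer matrix, genes in rows and motifs in columns; cell
#'   `[g, m]` is the rank of gene `g` in motif `m`'s ranking. Every column
#'   must be a permutation of `1..nrow(rank)`.
#' @param gene_ids,motif_ids Row/column identifiers; default taken from
#'   `dimnames(rank)`.
#' @return An object of class `ranking_db`.
#' @export
ranking_db <- function(rank, gene_ids = rownames(rank), motif_ids = colnames(rank)) {
  rank <- as.matrix(rank)
  storage.mode(rank) <- "integer"
  G <- nrow(rank)
  if (is.null(gene_ids) || is.null(motif_ids))
    stop("ranking_db requires gene and motif identifiers")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in ranking database")
  if (anyDuplicated(motif_ids)) stop("duplicate motif ids in ranking database")
  if (length(gene_ids) != G || length(motif_ids) != ncol(rank))
    stop("identifier lengths do not match the rank matrix")
  ok <- vapply(seq_len(ncol(rank)),
               function(j) all(tabulate(rank[, j], nbins = G) == 1L),
               logical(1))
  if (!all(ok))
    stop("column(s) ", paste(motif_ids[!ok], collapse = ", "),
         " are not permutations of 1..", G)
  dimnames(rank) <- list(gene_ids, motif_ids)
  structure(list(rank = rank), class = "ranking_db")
}

#' @export
print.ranking_db <- function(x, ...) {
  cat("Ranking database:", nrow(x$rank), "genes x", ncol(x$rank), "motifs/tracks\n")
  invisible(x)
}

#' Number of genes / motif and gene identifiers of a ranking database
#' @param db A `ranking_db`.
#' @return `n_genes()`: integer; `gene_ids()`/`motif_ids()`: character vectors.
#' @export
n_genes <- function(db) nrow(db$rank)

#' @rdname n_genes
#' @export
gene_ids <- function(db) rownames(db$rank)

#' @rdname n_genes
#' @export
motif_ids <- function(db) colnames(db$rank)

#' Read/write a ranking database as a tab-delimited matrix
#'
#' The on-disk dialect is a TSV with a header row: first column `gene_id`,
#' remaining columns one per motif, cells holding integer ranks.
#'
#' @param db A `ranking_db`.
#' @param path File path.
#' @return `read_ranking_db()` returns a `ranking_db`; `write_ranking_db()`
#'   returns `path` invisibly.
#' @export
write_ranking_db <- function(db, path) {
  out <- data.frame(gene_id = rownames(db$rank), db$rank,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking_db
#' @export
read_ranking_db <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(tab)) stop("missing 'gene_id' column in ", path)
  m <- as.matrix(tab[, setdiff(names(tab), "gene_id"), drop = FALSE])
  rownames(m) <- tab$gene_id
  ranking_db(m)
}
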