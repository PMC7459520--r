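#' Gene-set collection
#'
#' Named, non-empty gene sets with an optional per-set score (emulating a
#' gene-set-enrichment NES) and description.
#'
#' @param sets Named list of character vectors; names unique, sets
#'   non-empty.
#' @param score Optional named numeric vector of per-set scores.
#' @param description Optional named character vector of descriptions.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, score = NULL, description = NULL) {
  stopifnot(length(sets) >= 1, !is.null(names(sets)))
  if (anyDuplicated(names(sets))) stop("duplicate set names")
  if (any(!nzchar(names(sets)))) stop("set names must be non-empty")
  if (any(lengths(sets) == 0)) stop("sets must be non-empty")
  sets <- lapply(sets, function(x) unique(as.character(x)))
  if (!is.null(score)) score <- score[names(sets)]
  if (!is.null(description)) description <- description[names(sets)]
  structure(list(sets = sets, score = score, description = description),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene-set collection:", length(x$sets), "sets,",
      length(unique(unlist(x$sets))), "distinct members\n")
  invisible(x)
}

#' Read a Gene Matrix Transposed (GMT) file
#'
#' Each line holds at least three tab-separated fields: set name,
#' description, then member symbols. A numeric description is interpreted
#' as the set's score. Duplicate members within a set are de-duplicated
#' with a warning; duplicate set names and lines with fewer than three
#' fields are errors reporting the offending line numbers.
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_collection].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short))
    stop("malformed GMT line(s) with fewer than 3 fields: line ",
         paste(lineno[short], collapse = ", "))
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    d <- nm[duplicated(nm)][1]
    stop("duplicate set name '", d, "' at lines ",
         paste(lineno[nm == d], collapse = " and "))
  }
  desc <- vapply(fields, `[[`, character(1), 2)
  members <- lapply(fields, function(f) f[-(1:2)])
  n_dup <- sum(vapply(members, function(m) sum(duplicated(m)), integer(1)))
  if (n_dup > 0)
    warning(n_dup, " duplicate member symbol(s) within sets de-duplicated")
  members <- lapply(members, unique)
  names(members) <- nm
  score <- suppressWarnings(as.numeric(desc))
  names(score) <- nm
  names(desc) <- nm
  gene_set_collection(members,
                      score = if (all(is.na(score))) NULL else score,
                      description = desc)
}

#' Write a gene-set collection as a GMT file
#'
#' The description field carries the set score when one is present,
#' otherwise the stored description (or `.`); write-then-read reproduces
#' the sets and scores exactly.
#'
#' @param collection A [gene_set_collection].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  nm <- names(collection$sets)
  desc <- vapply(nm, function(s) {
    sc <- collection$score[s]
    if (!is.null(collection$score) && length(sc) && !is.na(sc))
      as.character(sc)
    else if (!is.null(collection$description) && !is.na(collection$description[s]))
      collection$description[s]
    else "."
  }, character(1))
  lines <- vapply(seq_along(nm), function(i) {
    paste(c(nm[i], desc[i], collection$sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
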