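# Independent brute-force oracles. These deliberately avoid igraph and the
# package's own code paths: shortest paths are found by enumerating all
# simple paths, hypergeometric tails by enumerating all draws, and
# enrichment scores by direct counting over the raw rank matrix.

# all shortest s -> t paths by depth-first enumeration of simple paths
enumerate_shortest <- function(adj, s, t) {
  best <- Inf
  found <- list()
  rec <- function(v, path) {
    if (v == t) {
      len <- length(path) - 1
      if (len < best) {
        best <<- len
        found <<- list(path)
      } else if (len == best) {
        found[[length(found) + 1]] <<- path
      }
      return()
    }
    if (length(path) - 1 >= best) return()
    for (w in adj[[v]]) if (!(w %in% path)) rec(w, c(path, w))
  }
  rec(s, s)
  list(dist = best, paths = found)
}

# full centrality battery from first principles (no igraph)
oracle_centralities <- function(nodes, edges, directed) {
  n <- length(nodes)
  ei <- data.frame(from = match(edges$from, nodes),
                   to = match(edges$to, nodes))
  # orientation used for distances / path counts
  und_pairs <- unique(data.frame(
    a = pmin(ei$from, ei$to), b = pmax(ei$from, ei$to)))
  dist_edges <- if (directed) ei else
    data.frame(from = c(und_pairs$a, und_pairs$b),
               to = c(und_pairs$b, und_pairs$a))
  adj <- lapply(seq_len(n), function(v) dist_edges$to[dist_edges$from == v])

  d <- matrix(Inf, n, n)
  diag(d) <- 0
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  stress <- numeric(n)
  btw_raw <- numeric(n)
  edge_keys <- if (directed) paste(ei$from, ei$to) else
    paste(und_pairs$a, und_pairs$b)
  eb <- stats::setNames(numeric(length(edge_keys)), edge_keys)

  pair_rows <- if (directed) {
    expand.grid(s = seq_len(n), t = seq_len(n))
  } else {
    do.call(rbind, lapply(seq_len(n), function(s)
      if (s < n) data.frame(s = s, t = (s + 1):n) else NULL))
  }
  pair_rows <- pair_rows[pair_rows$s != pair_rows$t, , drop = FALSE]

  for (r in seq_len(nrow(pair_rows))) {
    s <- pair_rows$s[r]; t <- pair_rows$t[r]
    res <- enumerate_shortest(adj, s, t)
    if (!is.finite(res$dist)) next
    d[s, t] <- res$dist
    if (!directed) d[t, s] <- res$dist
    sg <- length(res$paths)
    sigma[s, t] <- sg
    if (!directed) sigma[t, s] <- sg
    v_cnt <- numeric(n)
    for (p in res$paths) {
      if (length(p) > 2)
        for (v in p[-c(1, length(p))]) v_cnt[v] <- v_cnt[v] + 1
      for (i in seq_len(length(p) - 1)) {
        key <- if (directed) paste(p[i], p[i + 1]) else
          paste(min(p[i], p[i + 1]), max(p[i], p[i + 1]))
        eb[key] <- eb[key] + 1 / sg
      }
    }
    stress <- stress + v_cnt
    btw_raw <- btw_raw + v_cnt / sg
  }

  in_deg <- tabulate(ei$to, n)
  out_deg <- tabulate(ei$from, n)
  deg_g <- if (directed) in_deg + out_deg else
    tabulate(c(und_pairs$a, und_pairs$b), n)

  finite_pos <- d[is.finite(d) & d > 0]
  diam <- if (length(finite_pos)) max(finite_pos) else 0
  radiality <- closeness <- eccentricity <- numeric(n)
  for (v in seq_len(n)) {
    dv <- d[v, ]
    dv <- dv[is.finite(dv) & dv > 0]
    if (length(dv) && n >= 2) {
      radiality[v] <- sum(diam + 1 - dv) / (n - 1)
      closeness[v] <- 1 / sum(dv)
      eccentricity[v] <- 1 / max(dv)
    }
  }
  centroid <- numeric(n)
  if (n >= 2) {
    gam <- function(v, w) sum(d[, v] < d[, w])
    for (v in seq_len(n))
      centroid[v] <- min(vapply(setdiff(seq_len(n), v),
                                function(w) gam(v, w) - gam(w, v), numeric(1)))
  }
  denom <- if (directed) (n - 1) * (n - 2) else (n - 1) * (n - 2) / 2
  btw <- if (n >= 3) btw_raw / denom else numeric(n)
  bridging <- numeric(n)
  for (v in seq_len(n)) {
    if (deg_g[v] == 0) next
    nb <- if (directed) unique(c(ei$to[ei$from == v], ei$from[ei$to == v])) else
      unique(c(und_pairs$b[und_pairs$a == v], und_pairs$a[und_pairs$b == v]))
    bridging[v] <- btw_raw[v] * (1 / deg_g[v]) / sum(1 / deg_g[nb])
  }
  list(nodes = data.frame(
         id = nodes, degree = in_deg + out_deg, in_degree = in_deg,
         out_degree = out_deg, betweenness = btw, radiality = radiality,
         stress = stress, bridging = bridging, centroid = centroid,
         closeness = closeness, eccentricity = eccentricity,
         stringsAsFactors = FALSE),
       edge_betweenness = eb, diameter = diam)
}

# hypergeometric upper tail P(X >= k) by enumerating all size-n draws from
# a population of N with K successes
oracle_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# rank-and-recovery statistics by direct counting over the raw rank matrix
oracle_enrichment <- function(rank_mat, seed_genes, params) {
  G <- nrow(rank_mat)
  r_max <- max(1, floor(params$roc_fraction * G))
  L <- min(params$rank_threshold, G)
  seed <- intersect(seed_genes, rownames(rank_mat))
  recs <- lapply(colnames(rank_mat), function(m) {
    vapply(seq_len(L), function(r) sum(rank_mat[seed, m] <= r), numeric(1))
  })
  names(recs) <- colnames(rank_mat)
  aucs <- vapply(recs, function(rec) sum(rec[seq_len(r_max)]) /
                   (r_max * length(seed)), numeric(1))
  mu <- mean(aucs)
  sdp <- sqrt(mean((aucs - mu)^2))
  nes <- (aucs - mu) / sdp
  mean_curve <- Reduce(`+`, recs) / length(recs)
  rstar <- vapply(recs, function(rec) which.max(rec - mean_curve), integer(1))
  targets <- lapply(colnames(rank_mat), function(m)
    seed[rank_mat[seed, m] <= rstar[m]])
  names(targets) <- colnames(rank_mat)
  list(auc = aucs, nes = nes, leading_edge_rank = rstar, targets = targets)
}
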