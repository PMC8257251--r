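# Independent brute-force oracles used across the suite. These are written
# as plain loops on purpose: they must not share code paths with the package.

# tiny expression tibble from a matrix
tiny_expr <- function(m, genes = NULL) {
  genes <- genes %||% sprintf("g%03d", seq_len(nrow(m)))
  colnames(m) <- colnames(m) %||% paste0("s", seq_len(ncol(m)))
  out <- tibble::tibble(gene = genes)
  dplyr::bind_cols(out, tibble::as_tibble(m, .name_repair = "minimal"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# connected components via union-find over an explicit edge list
uf_components <- function(nodes, edges_a, edges_b) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (k in seq_along(edges_a)) {
    ra <- find(edges_a[k]); rb <- find(edges_b[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  split(nodes, roots)
}

# all-pairs shortest path costs by Floyd-Warshall on a dense matrix
floyd_warshall <- function(nodes, ea, eb, cost) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (k in seq_along(ea)) {
    i <- ea[k]; j <- eb[k]
    d[i, j] <- min(d[i, j], cost[k])
    d[j, i] <- min(d[j, i], cost[k])
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# unweighted BFS distances from one source
bfs_dist <- function(nodes, ea, eb, src) {
  d <- stats::setNames(rep(Inf, length(nodes)), nodes)
  d[src] <- 0
  frontier <- src
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (u in frontier) {
      nbs <- c(eb[ea == u], ea[eb == u])
      for (v in nbs) if (!is.finite(d[v])) {
        d[v] <- d[u] + 1
        nxt <- c(nxt, v)
      }
    }
    frontier <- unique(nxt)
  }
  d
}

# two-sided KS statistic between hit ranks and miss ranks: max absolute
# difference of the two empirical CDFs evaluated along the ranked list
ks_stat_hits <- function(hit_pos, L) {
  hits <- rep(0, L); hits[hit_pos] <- 1
  k <- sum(hits)
  cdf_h <- cumsum(hits) / k
  cdf_m <- cumsum(1 - hits) / (L - k)
  max(abs(cdf_h - cdf_m))
}

# naive running-sum enrichment score: literal walk over every rank
naive_es <- function(scores, is_hit, weight_exp) {
  L <- length(scores)
  w <- abs(scores)^weight_exp
  denom <- sum(w[is_hit])
  run <- numeric(L)
  cur <- 0
  miss_step <- 1 / (L - sum(is_hit))
  for (i in seq_len(L)) {
    cur <- if (is_hit[i]) cur + w[i] / denom else cur - miss_step
    run[i] <- cur
  }
  if (max(run) > -min(run)) max(run) else min(run)
}

# exact hypergeometric upper tail by enumerating all draws of size n
enum_hyper_tail <- function(universe, term, query) {
  n <- length(query)
  draws <- combn(universe, n)
  obs <- length(intersect(term, query))
  hits <- apply(draws, 2, function(dr) length(intersect(dr, term)) >= obs)
  mean(hits)
}

small_ppi <- function(ea, eb, conf, channel = "experiments") {
  tibble::tibble(gene_a = ea, gene_b = eb, confidence = conf,
                 channel = channel)
}
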