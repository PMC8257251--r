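#' Rank genes for gene set enrichment analysis
#'
#' Signal-to-noise ratio (mu1 - mu2) / (sd1 + sd2) on log2-transformed
#' normalized expression, with the conventional standard-deviation floor
#' (each group's sd is raised to at least 0.2 * |mean|, minimum 0.2) so that
#' near-constant genes do not dominate. Ties are broken by gene ID for
#' determinism.
#'
#' @param x normalized, floored expression tibble.
#' @param design sample/group design tibble.
#' @param comparison a [comparison_spec()].
#' @param metric `"s2n"` (signal-to-noise) or `"diff"` (difference of log2
#'   means).
#' @return tibble (gene, score) in descending score order.
#' @export
rank_genes <- function(x, design, comparison, metric = c("s2n", "diff")) {
  metric <- match.arg(metric)
  stopifnot(inherits(comparison, "comparison_spec"))
  m <- log2(as_expr_matrix(x))
  check_design(x, design)
  pick <- function(g) {
    ss <- intersect(design$sample[design$group == g], colnames(m))
    if (length(ss) < 2) abort(paste0("need >= 2 replicates in group ", g))
    m[, ss, drop = FALSE]
  }
  a <- pick(comparison$numerator)
  b <- pick(comparison$denominator)
  mu1 <- rowMeans(a); mu2 <- rowMeans(b)
  score <- if (metric == "diff") {
    mu1 - mu2
  } else {
    s1 <- fix_sd(apply(a, 1, sd), mu1)
    s2 <- fix_sd(apply(b, 1, sd), mu2)
    (mu1 - mu2) / (s1 + s2)
  }
  out <- tibble(gene = rownames(m), score = unname(score))
  out[order(-out$score, out$gene), ]
}

fix_sd <- function(s, mu) {
  lo <- 0.2 * abs(mu)
  lo[lo == 0] <- 0.2
  pmax(s, lo)
}

# Running-sum extremum evaluated only at hit positions: at the i-th hit
# (rank pos[i]) the sum is cumw[i]/denom - (pos[i] - i)/(L - k) just after
# the hit and cumw[i-1]/denom - (pos[i] - i)/(L - k) just before it.
es_core <- function(absw, positions, L) {
  k <- length(positions)
  if (k == 0) abort("gene set has no members in the ranked list")
  if (k >= L) abort("gene set covers the whole ranked list (no misses)")
  o <- order(positions)
  pos <- positions[o]
  w <- absw[o]
  denom <- sum(w)
  if (denom == 0) w[] <- 1 / k else w <- w / denom
  cw <- cumsum(w)
  miss <- (pos - seq_len(k)) / (L - k)
  after <- cw - miss
  before <- c(0, cw[-k]) - miss
  max_p <- max(after)
  min_p <- min(c(before, 0))
  if (max_p > -min_p) {
    i_star <- which.max(after)
    list(es = max_p, extremum_rank = pos[i_star],
         leading_idx = o[seq_len(i_star)])
  } else {
    i_star <- which.min(before)
    list(es = min_p, extremum_rank = pos[i_star],
         leading_idx = o[seq(i_star, k)])
  }
}

#' Enrichment score of a gene set along a ranked list
#'
#' Classic weighted Kolmogorov-Smirnov-like running sum: walking down the
#' ranked list, the sum increases by |score|^weight_exp (normalized over
#' hits) at each gene-set member and decreases by 1/(misses) otherwise; the
#' enrichment score is the signed maximum deviation from zero.
#'
#' @param ranked tibble (gene, score) from [rank_genes()], descending.
#' @param gene_set character vector of gene IDs.
#' @param weight_exp weighting exponent (0 = unweighted KS; 1 = classic).
#' @return list: `es`, `running` (tibble rank/value over the whole list),
#'   `leading_edge` (genes up to the extremum), `hit_ranks`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exp = 1) {
  L <- nrow(ranked)
  positions <- which(ranked$gene %in% gene_set)
  core <- es_core(abs(ranked$score[positions])^weight_exp, positions, L)
  k <- length(positions)
  w <- abs(ranked$score[positions])^weight_exp
  if (sum(w) == 0) w[] <- 1 / k else w <- w / sum(w)
  steps <- rep(-1 / (L - k), L)
  steps[positions] <- w
  running <- cumsum(steps)
  list(es = core$es,
       running = tibble(rank = seq_len(L), value = running),
       leading_edge = ranked$gene[sort(positions[core$leading_idx])],
       hit_ranks = sort(positions))
}

#' Run gene set enrichment analysis with gene-set permutation
#'
#' For every set within the size window, computes the enrichment score on
#' the ranked list and a null distribution of scores from random same-size
#' gene sets. NES is the score normalized by the mean magnitude of
#' same-signed null scores; the nominal p-value is the same-signed null
#' tail; FDR is the canonical sign-stratified ratio-of-tails estimate over
#' the pooled normalized null. Gene-set (not phenotype) permutation is the
#' appropriate null for 3-4 replicates per group.
#'
#' @param x normalized expression tibble.
#' @param design sample/group design tibble.
#' @param comparison a [comparison_spec()].
#' @param db a [gene_set_db()] (or plain tibble with term/genes).
#' @param n_perm number of random gene sets per term.
#' @param min_size,max_size set-size window after intersecting the universe.
#' @param weight_exp running-sum weight exponent.
#' @param seed integer seed for the permutation draws.
#' @return tibble of class `gsea_results`: term, size, es, nes, p, fdr,
#'   leading_edge (list-col), n_perm.
#' @export
run_gsea <- function(x, design, comparison, db, n_perm = 1000,
                     min_size = 5, max_size = 500, weight_exp = 1,
                     seed = 1L) {
  ranked <- rank_genes(x, design, comparison)
  gsea_ranked(ranked, db, n_perm = n_perm, min_size = min_size,
              max_size = max_size, weight_exp = weight_exp, seed = seed,
              comparison = comparison$name)
}

#' @rdname run_gsea
#' @param ranked a pre-computed ranked tibble (gene, score), descending.
#' @param comparison label attached to the results.
#' @export
gsea_ranked <- function(ranked, db, n_perm = 1000, min_size = 5,
                        max_size = 500, weight_exp = 1, seed = 1L,
                        comparison = NA_character_) {
  set.seed(seed)
  L <- nrow(ranked)
  absw_all <- abs(ranked$score)^weight_exp
  universe <- ranked$gene
  sets <- lapply(db$genes, intersect, y = universe)
  sz <- lengths(sets)
  keep <- sz >= min_size & sz <= max_size & sz < L
  if (!any(keep)) abort("no gene sets survive the size filter")
  sets <- sets[keep]
  terms <- db$term[keep]
  sz <- sz[keep]

  n_sets <- length(sets)
  es_obs <- numeric(n_sets)
  leading <- vector("list", n_sets)
  null_nes <- vector("list", n_sets)
  nes <- p_nom <- numeric(n_sets)
  for (i in seq_len(n_sets)) {
    pos <- which(universe %in% sets[[i]])
    core <- es_core(absw_all[pos], pos, L)
    es_obs[i] <- core$es
    leading[[i]] <- universe[sort(pos[core$leading_idx])]
    k <- sz[i]
    null_es <- vapply(seq_len(n_perm), function(b) {
      rp <- sample.int(L, k)
      es_core(absw_all[rp], rp, L)$es
    }, numeric(1))
    pos_null <- null_es[null_es >= 0]
    neg_null <- null_es[null_es < 0]
    mean_pos <- if (length(pos_null)) mean(pos_null) else NA_real_
    mean_neg <- if (length(neg_null)) mean(abs(neg_null)) else NA_real_
    if (es_obs[i] >= 0) {
      nes[i] <- es_obs[i] / mean_pos
      p_nom[i] <- if (length(pos_null)) mean(pos_null >= es_obs[i]) else NA_real_
      null_nes[[i]] <- c(pos_null / mean_pos,
                         if (length(neg_null) && !is.na(mean_neg)) neg_null / mean_neg)
    } else {
      nes[i] <- es_obs[i] / mean_neg
      p_nom[i] <- if (length(neg_null)) mean(neg_null <= es_obs[i]) else NA_real_
      null_nes[[i]] <- c(if (length(pos_null) && !is.na(mean_pos)) pos_null / mean_pos,
                         neg_null / mean_neg)
    }
  }

  pooled <- unlist(null_nes)
  pooled_pos <- pooled[pooled >= 0]
  pooled_neg <- pooled[pooled < 0]
  obs_pos <- nes[nes >= 0 & !is.na(nes)]
  obs_neg <- nes[nes < 0 & !is.na(nes)]
  fdr <- vapply(nes, function(v) {
    if (is.na(v)) return(NA_real_)
    if (v >= 0) {
      num <- if (length(pooled_pos)) mean(pooled_pos >= v) else 0
      den <- if (length(obs_pos)) mean(obs_pos >= v) else 1
    } else {
      num <- if (length(pooled_neg)) mean(pooled_neg <= v) else 0
      den <- if (length(obs_neg)) mean(obs_neg <= v) else 1
    }
    if (den == 0) return(1)
    min(1, num / den)
  }, numeric(1))

  out <- tibble(term = terms, database = db_name(db),
                comparison = comparison, size = as.integer(sz),
                es = es_obs, nes = nes, p = p_nom, fdr = fdr,
                leading_edge = leading, n_perm = as.integer(n_perm))
  out <- out[order(-abs(out$nes)), ]
  class(out) <- c("gsea_results", class(out))
  out
}

#' Select significant hallmark-style results
#'
#' @param results a `gsea_results` tibble.
#' @param fdr_max FDR threshold (exclusive).
#' @param nes_min magnitude threshold on NES (exclusive).
#' @return the significant subset.
#' @export
select_hallmarks <- function(results, fdr_max = 0.05, nes_min = 2) {
  keep <- !is.na(results$nes) & abs(results$nes) > nes_min &
    results$fdr < fdr_max
  results[keep, , drop = FALSE]
}
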