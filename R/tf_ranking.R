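#' Count direct PPI connections between a TF and a signature
#'
#' Number of distinct signature genes sharing an edge with the TF above the
#' confidence threshold; all evidence channels are admitted at this stage.
#'
#' @param tf TF identifier.
#' @param signature character vector of signature gene IDs.
#' @param ppi PPI edge tibble (gene_a, gene_b, confidence, channel).
#' @param min_conf minimum confidence (exclusive).
#' @return integer count.
#' @export
ppi_direct_connections <- function(tf, signature, ppi, min_conf = 0.2) {
  present <- tf %in% c(ppi$gene_a, ppi$gene_b)
  if (!present) {
    warn(paste0("TF absent from PPI network: ", tf))
    return(0L)
  }
  ed <- ppi[ppi$confidence > min_conf, , drop = FALSE]
  nb <- c(ed$gene_b[ed$gene_a == tf], ed$gene_a[ed$gene_b == tf])
  length(intersect(unique(nb), signature))
}

# undirected igraph over confidence-filtered edges, duplicate edges
# collapsed to the maximum confidence, cost = -ln(confidence)
conf_graph <- function(ppi, min_conf) {
  ed <- ppi[ppi$confidence > min_conf, , drop = FALSE]
  a <- pmin(ed$gene_a, ed$gene_b)
  b <- pmax(ed$gene_a, ed$gene_b)
  ed <- tibble(gene_a = a, gene_b = b, confidence = ed$confidence) |>
    group_by(.data$gene_a, .data$gene_b) |>
    summarise(confidence = max(.data$confidence), .groups = "drop")
  g <- igraph::graph_from_data_frame(ed[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  igraph::E(g)$confidence <- ed$confidence
  igraph::E(g)$cost <- -log(ed$confidence)
  g
}

#' Infer an anchored TF-to-signature subnetwork
#'
#' For each (anchor, target) pair, the minimum-cost path with edge cost
#' -ln(confidence) — i.e. the most probable chain of interactions — is
#' computed on the confidence-filtered PPI; the subnetwork is the union of
#' all such path edges. Among equal-cost paths the lexicographically
#' smallest node sequence is chosen, making inference deterministic.
#'
#' @param anchors character vector of anchor (TF) IDs.
#' @param targets character vector of target gene IDs.
#' @param ppi PPI edge tibble.
#' @param min_conf minimum edge confidence (exclusive).
#' @return list: `edges` (tibble from/to/confidence), `nodes`,
#'   `unreachable` targets, `path_costs` (tibble anchor/target/cost).
#' @export
infer_anchored_subnetwork <- function(anchors, targets, ppi, min_conf = 0.2) {
  ctx <- ppi_context(ppi, min_conf)
  if (!any(anchors %in% ctx$vnames)) abort("no anchor present in the network")
  anchors_in <- intersect(anchors, ctx$vnames)
  targets_in <- intersect(unique(targets), ctx$vnames)
  unreachable <- setdiff(unique(targets), targets_in)
  d_t_all <- if (length(targets_in) > 0) {
    igraph::distances(ctx$g, v = targets_in, weights = igraph::E(ctx$g)$cost)
  } else NULL
  res <- anchored_core(ctx, anchors_in, targets_in, d_t_all)
  assemble_subnetwork(ctx, anchors_in, res,
                      union(unreachable, res$unreachable))
}

# shared per-network context: confidence-filtered graph plus neighbor
# lists ordered by neighbor name (for lexicographic path tie-breaks)
ppi_context <- function(ppi, min_conf) {
  g <- conf_graph(ppi, min_conf)
  vnames <- igraph::V(g)$name
  ed_df <- igraph::as_data_frame(g, what = "edges")
  src <- c(ed_df$from, ed_df$to)
  dst <- c(ed_df$to, ed_df$from)
  dcost <- c(ed_df$cost, ed_df$cost)
  o <- order(src, dst)
  src <- src[o]; dst <- dst[o]; dcost <- dcost[o]
  idx <- split(seq_along(src), src)
  list(g = g, vnames = vnames,
       nb_names = lapply(idx, function(i) dst[i]),
       nb_costs = lapply(idx, function(i) dcost[i]))
}

# minimum-cost paths from each anchor to every reachable target;
# among ties the lexicographically smallest node sequence is rebuilt by a
# greedy walk constrained to stay on shortest paths
anchored_core <- function(ctx, anchors_in, targets_in, d_t_all) {
  edge_keys <- character(0)
  cost_anchor <- cost_target <- character(0)
  cost_val <- numeric(0)
  unreachable <- character(0)
  tol <- 1e-9
  n_v <- igraph::vcount(ctx$g)
  for (a in anchors_in) {
    if (length(targets_in) == 0) break
    d_a <- igraph::distances(ctx$g, v = a,
                             weights = igraph::E(ctx$g)$cost)[1, ]
    reach <- targets_in[is.finite(d_a[targets_in])]
    unreachable <- union(unreachable, setdiff(targets_in, reach))
    for (t in setdiff(reach, a)) {
      total <- d_a[[t]]
      d_t <- d_t_all[t, ]
      cur <- a; acc <- 0; steps <- 0L
      path <- a
      while (cur != t && steps <= n_v) {
        nbs <- ctx$nb_names[[cur]]
        ncs <- ctx$nb_costs[[cur]]
        ok <- which(abs(acc + ncs + d_t[nbs] - total) <= tol * (1 + total))
        ok <- ok[!nbs[ok] %in% path]           # guard zero-cost cycles
        if (length(ok) == 0) break
        nxt <- ok[1]
        acc <- acc + ncs[nxt]
        cur <- nbs[nxt]
        path <- c(path, cur)
        steps <- steps + 1L
      }
      if (cur != t) next
      u <- pmin(path[-length(path)], path[-1])
      v <- pmax(path[-length(path)], path[-1])
      edge_keys <- c(edge_keys, paste(u, v, sep = "\r"))
      cost_anchor <- c(cost_anchor, a)
      cost_target <- c(cost_target, t)
      cost_val <- c(cost_val, total)
    }
  }
  list(edge_keys = unique(edge_keys),
       path_costs = tibble(anchor = cost_anchor, target = cost_target,
                           cost = cost_val),
       unreachable = unreachable)
}

assemble_subnetwork <- function(ctx, anchors_in, res, unreachable) {
  if (length(res$edge_keys) > 0) {
    parts <- do.call(rbind, strsplit(res$edge_keys, "\r", fixed = TRUE))
    eids <- igraph::get_edge_ids(ctx$g, rbind(parts[, 1], parts[, 2]))
    edges <- tibble(from = parts[, 1], to = parts[, 2],
                    confidence = igraph::E(ctx$g)$confidence[eids])
  } else {
    edges <- tibble(from = character(), to = character(),
                    confidence = numeric())
  }
  list(edges = edges,
       nodes = unique(c(anchors_in, edges$from, edges$to)),
       unreachable = unreachable,
       path_costs = res$path_costs)
}

#' Topological metrics of an anchored subnetwork
#'
#' Three parameters of the TF-centred interaction subnetwork: the number of
#' target genes directly adjacent to the TF (1st neighbors), the
#' characteristic path length (mean unweighted shortest-path length from
#' the TF to every other reachable subnetwork node), and the Freeman degree
#' centralization of the subnetwork (1 for a star, 0 for a regular graph).
#'
#' @param subnet result of [infer_anchored_subnetwork()] with `tf` as the
#'   sole anchor.
#' @param tf the anchor TF.
#' @param targets the target gene IDs.
#' @return list: `anat_direct` (integer), `anat_cpl` (NA if nothing
#'   reachable), `anat_centralization` (NA if under 3 nodes).
#' @export
subnetwork_metrics <- function(subnet, tf, targets) {
  edges <- subnet$edges
  nodes <- unique(c(tf, edges$from, edges$to))
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  nb <- igraph::V(g)$name[
    as.integer(igraph::neighbors(g, tf))]
  anat_direct <- length(intersect(unique(nb), targets))
  d <- igraph::distances(g, v = tf, weights = NA)[1, ]
  d <- d[names(d) != tf & is.finite(d)]
  anat_cpl <- if (length(d) > 0) mean(d) else NA_real_
  n <- length(nodes)
  anat_centralization <- if (n >= 3) {
    deg <- igraph::degree(g)
    sum(max(deg) - deg) / ((n - 1) * (n - 2))
  } else NA_real_
  list(anat_direct = as.integer(anat_direct), anat_cpl = anat_cpl,
       anat_centralization = anat_centralization)
}

#' Count registered regulon targets within a signature
#'
#' @param tf TF identifier.
#' @param signature character vector of gene IDs.
#' @param regulon directed edge tibble (tf, target).
#' @return integer count of signature genes registered as targets of `tf`.
#' @export
regulon_target_count <- function(tf, signature, regulon) {
  length(intersect(unique(regulon$target[regulon$tf == tf]), signature))
}

#' Summarize gene-TF relatedness scores over a signature
#'
#' Restricted to signature genes: the number of directly related genes, the
#' mean score of direct rows and the mean score of indirect rows. An empty
#' class yields a zero mean with a message (imputed for ranking).
#'
#' @param tf TF identifier.
#' @param signature character vector of gene IDs.
#' @param relatedness tibble (gene, tf, score, flag in direct/indirect).
#' @return list: `var_n_direct`, `var_mean_direct`, `var_mean_indirect`.
#' @export
relatedness_summary <- function(tf, signature, relatedness) {
  rel <- relatedness[relatedness$tf == tf & relatedness$gene %in% signature, ,
                     drop = FALSE]
  direct <- rel$score[rel$flag == "direct"]
  indirect <- rel$score[rel$flag == "indirect"]
  if (length(direct) == 0) inform(paste0("no direct relatedness rows for ", tf))
  if (length(indirect) == 0) inform(paste0("no indirect relatedness rows for ", tf))
  list(var_n_direct = length(direct),
       var_mean_direct = if (length(direct)) mean(direct) else 0,
       var_mean_indirect = if (length(indirect)) mean(indirect) else 0)
}

#' Compute the full per-TF evidence parameter table
#'
#' Eight parameters per TF and comparison: direct PPI connection count,
#' anchored-subnetwork 1st-neighbor count, characteristic path length and
#' centralization, regulon target count, and the three relatedness
#' summaries.
#'
#' @param tfs character vector of candidate TFs.
#' @param signatures named list (comparison -> gene-ID vector).
#' @param networks list with `ppi`, `regulon`, `relatedness` tibbles.
#' @param min_conf confidence threshold for the PPI-based parameters.
#' @return tibble: tf, comparison, and the eight parameter columns.
#' @export
compute_tf_metrics <- function(tfs, signatures, networks, min_conf = 0.2) {
  rows <- list()
  ctx <- ppi_context(networks$ppi, min_conf)
  for (cmp in names(signatures)) {
    sig <- signatures[[cmp]]
    targets_in <- intersect(unique(sig), ctx$vnames)
    d_t_all <- if (length(targets_in) > 0) {
      igraph::distances(ctx$g, v = targets_in, weights = igraph::E(ctx$g)$cost)
    } else NULL
    for (tf in tfs) {
      sub <- if (tf %in% ctx$vnames) {
        res <- anchored_core(ctx, tf, targets_in, d_t_all)
        assemble_subnetwork(ctx, tf, res,
                            union(setdiff(unique(sig), targets_in),
                                  res$unreachable))
      } else NULL
      sm <- if (is.null(sub)) {
        list(anat_direct = 0L, anat_cpl = NA_real_,
             anat_centralization = NA_real_)
      } else {
        subnetwork_metrics(sub, tf, sig)
      }
      rs <- suppressMessages(relatedness_summary(tf, sig, networks$relatedness))
      rows[[paste(cmp, tf)]] <- tibble(
        tf = tf, comparison = cmp,
        string_degree = suppressWarnings(
          ppi_direct_connections(tf, sig, networks$ppi, min_conf)),
        anat_direct = sm$anat_direct,
        anat_cpl = sm$anat_cpl,
        anat_centralization = sm$anat_centralization,
        regnet_targets = regulon_target_count(tf, sig, networks$regulon),
        var_n_direct = rs$var_n_direct,
        var_mean_direct = rs$var_mean_direct,
        var_mean_indirect = rs$var_mean_indirect
      )
    }
  }
  bind_rows(rows)
}

tf_parameters <- c("string_degree", "anat_direct", "anat_cpl",
                   "anat_centralization", "regnet_targets", "var_n_direct",
                   "var_mean_direct", "var_mean_indirect")

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' @param values numeric vector of observations.
#' @param groups factor/character vector of group labels, same length.
#' @return list: `f`, `p`, `tukey` tibble (group1, group2, diff, p_adj).
#' @export
anova_tukey <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) abort("need at least 2 groups")
  if (any(table(groups) < 2)) abort("need at least 2 observations per group")
  dat <- data.frame(y = values, g = groups)
  if (var(values) == 0) {
    # all observations identical: no between- or within-group variation
    pairs <- t(combn(levels(groups), 2))
    return(list(f = 0, p = 1,
                tukey = tibble(group1 = pairs[, 2], group2 = pairs[, 1],
                               diff = 0, p_adj = 1)))
  }
  fit <- aov(y ~ g, data = dat)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  list(f = an[["F value"]][1], p = an[["Pr(>F)"]][1],
       tukey = tibble(group1 = vapply(nm, `[`, "", 1),
                      group2 = vapply(nm, `[`, "", 2),
                      diff = tk[, "diff"], p_adj = tk[, "p adj"]))
}

#' Consolidate multi-evidence TF parameters into a ranking
#'
#' Characteristic path length is first inverted (shorter paths mean tighter
#' wiring, so its reciprocal makes every parameter point the same way),
#' missing values are imputed (path length reciprocal 0, centralization 0),
#' then every parameter is Z-scored across the candidate TFs within each
#' comparison (population sd; constant parameters yield all-zero scores
#' with a warning). Each TF's parameter Z-scores are pooled into a mean Z,
#' and a one-way ANOVA with Tukey HSD across TFs — the parameter Z-scores
#' as observations — tests whether the leading TF stands out.
#'
#' Separation is tested twice: per comparison (8 observations per TF) and
#' pooled over all comparisons (`anova_overall`/`tukey_overall`, all
#' parameter Z-scores per TF as observations) — the pooled test carries
#' the better power and backs the overall ranking.
#'
#' @param metrics tibble from [compute_tf_metrics()].
#' @return object of class `tf_ranking`: list with `z_scores` (long
#'   tibble), `summary` (tf, comparison, mean_z, rank), `overall` (tf,
#'   mean_z, rank across comparisons), `anova` (per comparison), `tukey`
#'   (per comparison), `anova_overall`, `tukey_overall` (pooled).
#' @export
consolidate_ranking <- function(metrics) {
  stopifnot(all(c("tf", "comparison", tf_parameters) %in% names(metrics)))
  if (length(unique(metrics$tf)) < 3) abort("need at least 3 candidate TFs")
  long <- list(); anv <- list(); tuk <- list()
  for (cmp in unique(metrics$comparison)) {
    sub <- metrics[metrics$comparison == cmp, , drop = FALSE]
    vals <- as.matrix(sub[, tf_parameters])
    rownames(vals) <- sub$tf
    # reciprocal transform: short characteristic path length is good
    cpl <- vals[, "anat_cpl"]
    vals[, "anat_cpl"] <- ifelse(is.na(cpl) | cpl == 0, 0, 1 / cpl)
    vals[is.na(vals)] <- 0
    z <- apply(vals, 2, zscore_pop)
    if (any(apply(vals, 2, function(v) length(unique(v)) == 1))) {
      warn(paste0("constant parameter(s) in comparison ", cmp,
                  ": Z-scores set to 0"))
    }
    zl <- as_tibble(z) |>
      mutate(tf = sub$tf, comparison = cmp) |>
      tidyr::pivot_longer(all_of(tf_parameters), names_to = "parameter",
                          values_to = "z")
    long[[cmp]] <- zl
    at <- anova_tukey(zl$z, zl$tf)
    anv[[cmp]] <- tibble(comparison = cmp, f = at$f, p = at$p)
    tuk[[cmp]] <- mutate(at$tukey, comparison = cmp)
  }
  z_scores <- bind_rows(long)
  summary_tbl <- z_scores |>
    group_by(.data$comparison, .data$tf) |>
    summarise(mean_z = mean(.data$z), .groups = "drop") |>
    group_by(.data$comparison) |>
    arrange(desc(.data$mean_z), .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup()
  overall <- summary_tbl |>
    group_by(.data$tf) |>
    summarise(mean_z = mean(.data$mean_z), .groups = "drop") |>
    arrange(desc(.data$mean_z)) |>
    mutate(rank = row_number())
  at_all <- anova_tukey(z_scores$z, z_scores$tf)
  structure(list(z_scores = z_scores, summary = summary_tbl,
                 overall = overall, anova = bind_rows(anv),
                 tukey = bind_rows(tuk),
                 anova_overall = tibble(f = at_all$f, p = at_all$p),
                 tukey_overall = at_all$tukey, metrics = metrics),
            class = "tf_ranking")
}

#' @export
print.tf_ranking <- function(x, ...) {
  cat("Multi-evidence TF ranking\n")
  cat("Comparisons:", paste(unique(x$summary$comparison), collapse = ", "), "\n")
  cat("Overall order:", paste(x$overall$tf, collapse = " > "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a TF ranking
#'
#' One row per TF and comparison: mean Z, rank, ANOVA p of the comparison
#' and the smallest Tukey-adjusted p of that TF against any other TF.
#'
#' @param x a `tf_ranking`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.tf_ranking <- function(x, ...) {
  min_tukey <- x$tukey |>
    tidyr::pivot_longer(c("group1", "group2"), values_to = "tf") |>
    group_by(.data$comparison, .data$tf) |>
    summarise(min_tukey_p = min(.data$p_adj), .groups = "drop")
  x$summary |>
    left_join(x$anova, by = "comparison") |>
    left_join(min_tukey, by = c("comparison", "tf")) |>
    rename(anova_f = "f", anova_p = "p")
}

#' Glance at a TF ranking
#'
#' @param x a `tf_ranking`.
#' @param ... unused.
#' @return one-row tibble: number of TFs and comparisons, the top TF
#'   overall and the largest ANOVA p across comparisons.
#' @export
glance.tf_ranking <- function(x, ...) {
  tibble(n_tfs = length(unique(x$summary$tf)),
         n_comparisons = length(unique(x$summary$comparison)),
         top_tf = x$overall$tf[1],
         top_mean_z = x$overall$mean_z[1],
         max_anova_p = max(x$anova$p))
}
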