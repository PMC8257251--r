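test_that("direct-connection counts respect threshold and deduplication", {
  ppi <- small_ppi(c("tf", "tf", "tf", "tf"),
                   c("g1", "g2", "g3", "g1"),
                   conf = c(0.5, 0.5, 0.1, 0.9))
  expect_equal(ppi_direct_connections("tf", c("g1", "g2", "g3"), ppi), 2)
  expect_equal(ppi_direct_connections("tf", c("g1"), ppi), 1)
  expect_warning(n <- ppi_direct_connections("ghost", "g1", ppi), "absent")
  expect_equal(n, 0L)
})

test_that("anchored paths choose the most probable chain (hand -ln arithmetic)", {
  # direct conf 0.9 (cost 0.105) beats 0.8*0.8 two-hop (cost 0.446)
  ppi <- small_ppi(c("A", "A", "M"), c("T", "M", "T"), c(0.9, 0.8, 0.8))
  sub <- infer_anchored_subnetwork("A", "T", ppi)
  expect_equal(nrow(sub$edges), 1)
  expect_equal(sub$path_costs$cost, -log(0.9), tolerance = 1e-12)
  # flip: direct conf 0.5 (cost 0.693) loses to 0.9*0.9 (cost 0.211)
  ppi2 <- small_ppi(c("A", "A", "M"), c("T", "M", "T"), c(0.5, 0.9, 0.9))
  sub2 <- infer_anchored_subnetwork("A", "T", ppi2)
  expect_equal(sub2$path_costs$cost, -2 * log(0.9), tolerance = 1e-12)
  expect_setequal(paste(sub2$edges$from, sub2$edges$to),
                  c("A M", "M T"))
  expect_error(infer_anchored_subnetwork("nope", "T", ppi), "no anchor")
})

test_that("all-adjacent targets give a star subnetwork with closed-form metrics", {
  targets <- paste0("t", 1:6)
  ppi <- small_ppi(rep("TF", 6), targets, conf = 0.9)
  sub <- infer_anchored_subnetwork("TF", targets, ppi)
  expect_equal(nrow(sub$edges), 6)
  m <- subnetwork_metrics(sub, "TF", targets)
  expect_equal(m$anat_direct, 6L)
  expect_equal(m$anat_cpl, 1.0)
  expect_equal(m$anat_centralization, 1.0)
})

test_that("cycle graphs have zero centralization; tiny nets report missing", {
  nodes <- paste0("c", 1:6)
  edges <- tibble::tibble(from = nodes, to = nodes[c(2:6, 1)],
                          confidence = 0.9)
  sub <- list(edges = edges)
  m <- subnetwork_metrics(sub, "c1", nodes[-1])
  expect_equal(m$anat_centralization, 0)
  expect_equal(m$anat_cpl, mean(c(1, 2, 3, 2, 1)))
  m2 <- subnetwork_metrics(list(edges = edges[1, ]), "c1", "c2")
  expect_true(is.na(m2$anat_centralization))
})

test_that("path costs, CPL and centralization match brute-force oracles", {
  set.seed(40)
  for (rep in 1:25) {
    n <- sample(8:15, 1)
    nodes <- sprintf("v%02d", 1:n)
    n_edge <- sample((n - 1):(2 * n), 1)
    ea <- sample(nodes, n_edge, replace = TRUE)
    eb <- sample(nodes, n_edge, replace = TRUE)
    ok <- ea != eb
    ea <- ea[ok]; eb <- eb[ok]
    if (length(ea) == 0) next
    conf <- runif(length(ea), 0.25, 0.95)
    ppi <- small_ppi(ea, eb, conf)
    anchor <- nodes[1]
    targets <- nodes[-1]
    sub <- tryCatch(infer_anchored_subnetwork(anchor, targets, ppi, 0.2),
                    error = function(e) NULL)
    if (is.null(sub)) next
    # oracle: Floyd-Warshall on max-confidence collapsed edges
    key <- paste(pmin(ea, eb), pmax(ea, eb))
    agg <- tapply(conf, key, max)
    uv <- do.call(rbind, strsplit(names(agg), " "))
    d <- floyd_warshall(nodes, uv[, 1], uv[, 2], -log(as.numeric(agg)))
    if (nrow(sub$path_costs) > 0) {
      for (i in seq_len(nrow(sub$path_costs))) {
        expect_equal(sub$path_costs$cost[i],
                     d[anchor, sub$path_costs$target[i]], tolerance = 1e-9)
      }
    }
    expect_setequal(sub$unreachable,
                    targets[!is.finite(d[anchor, targets])])

    # CPL and centralization of the inferred subnetwork vs BFS/degree oracle
    if (nrow(sub$edges) > 0) {
      met <- subnetwork_metrics(sub, anchor, targets)
      bd <- bfs_dist(sub$nodes, sub$edges$from, sub$edges$to, anchor)
      bd <- bd[names(bd) != anchor & is.finite(bd)]
      expect_equal(met$anat_cpl, mean(bd), tolerance = 1e-12)
      deg <- stats::setNames(rep(0, length(sub$nodes)), sub$nodes)
      for (i in seq_len(nrow(sub$edges))) {
        deg[sub$edges$from[i]] <- deg[sub$edges$from[i]] + 1
        deg[sub$edges$to[i]] <- deg[sub$edges$to[i]] + 1
      }
      nn <- length(sub$nodes)
      if (nn >= 3) {
        expect_equal(met$anat_centralization,
                     sum(max(deg) - deg) / ((nn - 1) * (nn - 2)),
                     tolerance = 1e-12)
      }
      # union subnetwork contains every per-pair optimal path cost
      for (i in seq_len(nrow(sub$path_costs))) {
        dsub <- floyd_warshall(sub$nodes, sub$edges$from, sub$edges$to,
                               -log(sub$edges$confidence))
        expect_equal(dsub[anchor, sub$path_costs$target[i]],
                     sub$path_costs$cost[i], tolerance = 1e-9)
      }
    }
  }
})

test_that("regulon and relatedness summaries match simple group-by oracles", {
  reg <- tibble::tibble(tf = c("tf", "tf", "other"),
                        target = c("g1", "g9", "g2"))
  expect_equal(regulon_target_count("tf", c("g1", "g2"), reg), 1)
  expect_equal(regulon_target_count("tf", "g5",
                                    tibble::tibble(tf = character(),
                                                   target = character())), 0)

  rel <- tibble::tibble(gene = c("g1", "g2", "g3", "g4"),
                        tf = "tf",
                        score = c(10, 20, 3, 2),
                        flag = c("direct", "direct", "indirect", "indirect"))
  rs <- suppressMessages(relatedness_summary("tf", c("g1", "g2", "g3"), rel))
  expect_equal(rs$var_n_direct, 2)
  expect_equal(rs$var_mean_direct, 15)
  expect_equal(rs$var_mean_indirect, 3)
  rs2 <- suppressMessages(relatedness_summary("tf", "g1", rel))
  expect_equal(rs2$var_mean_indirect, 0)  # imputed when class empty

  set.seed(41)
  big <- tibble::tibble(gene = sample(sprintf("g%02d", 1:30), 60, TRUE),
                        tf = sample(c("a", "b"), 60, TRUE),
                        score = runif(60, 0, 30),
                        flag = sample(c("direct", "indirect"), 60, TRUE))
  big <- big[!duplicated(paste(big$gene, big$tf)), ]
  sig <- sprintf("g%02d", 1:15)
  rs3 <- suppressMessages(relatedness_summary("a", sig, big))
  sub <- big[big$tf == "a" & big$gene %in% sig, ]
  expect_equal(rs3$var_n_direct, sum(sub$flag == "direct"))
  if (any(sub$flag == "direct")) {
    expect_equal(rs3$var_mean_direct, mean(sub$score[sub$flag == "direct"]))
  }
})

test_that("ANOVA with Tukey reproduces hand-computed mean squares", {
  g <- rep(c("a", "b", "c"), each = 3)
  y <- c(1, 2, 3, 2, 3, 4, 10, 11, 12)
  out <- anova_tukey(y, g)
  # hand computation: group means 2,3,11; grand mean 16/3
  ssb <- 3 * sum((c(2, 3, 11) - 16 / 3)^2)
  ssw <- sum((y - rep(c(2, 3, 11), each = 3))^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(out$f, f_hand, tolerance = 1e-10)
  expect_lt(out$p, 0.001)
  expect_equal(nrow(out$tukey), 3)
  # a-b not significant, both differ from c
  expect_gt(out$tukey$p_adj[out$tukey$group1 == "b" &
                              out$tukey$group2 == "a"], 0.05)
  expect_lt(max(out$tukey$p_adj[out$tukey$group1 == "c" |
                                  out$tukey$group2 == "c"]), 0.001)
  # identical groups: F = 0, all pairwise p = 1
  same <- anova_tukey(rep(5, 9), g)
  expect_equal(same$f, 0)
  expect_true(all(same$tukey$p_adj == 1))
  expect_error(anova_tukey(1:3, c("a", "a", "b")), "2 observations")
})

test_that("Z-score consolidation is standardized and orientation-correct", {
  mk <- function(tf, cmp, vals) {
    tibble::tibble(tf = tf, comparison = cmp,
                   string_degree = vals[1], anat_direct = vals[2],
                   anat_cpl = vals[3], anat_centralization = vals[4],
                   regnet_targets = vals[5], var_n_direct = vals[6],
                   var_mean_direct = vals[7], var_mean_indirect = vals[8])
  }
  set.seed(42)
  metrics <- dplyr::bind_rows(lapply(paste0("TF", 1:4), function(tf) {
    mk(tf, "c1", runif(8, 1, 10))
  }))
  rk <- suppressWarnings(consolidate_ranking(metrics))
  z <- rk$z_scores
  for (p in unique(z$parameter)) {
    v <- z$z[z$parameter == p]
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-9)
  }
  # two TFs, one parameter varying -> Z = +1 / -1
  m2 <- dplyr::bind_rows(mk("A", "c1", c(5, rep(1, 7))),
                         mk("B", "c1", c(3, rep(1, 7))),
                         mk("C", "c1", c(4, rep(1, 7))))
  z2 <- suppressWarnings(consolidate_ranking(m2))$z_scores
  sd_col <- z2$z[z2$parameter == "string_degree"]
  expect_equal(sort(sd_col), c(-sqrt(1.5), 0, sqrt(1.5)), tolerance = 1e-9)

  # shorter characteristic path length never lowers the transformed score
  m3 <- dplyr::bind_rows(mk("A", "c1", c(1, 1, 1.2, 1, 1, 1, 1, 1)),
                         mk("B", "c1", c(1, 1, 2.5, 1, 1, 1, 1, 1)),
                         mk("C", "c1", c(1, 1, 4.0, 1, 1, 1, 1, 1)))
  z3 <- suppressWarnings(consolidate_ranking(m3))$z_scores
  cpl_z <- z3$z[z3$parameter == "anat_cpl"]
  names(cpl_z) <- z3$tf[z3$parameter == "anat_cpl"]
  expect_true(cpl_z[["A"]] > cpl_z[["B"]], cpl_z[["B"]] > cpl_z[["C"]])

  # all TFs identical -> all Z zero, ANOVA F = 0
  m4 <- dplyr::bind_rows(mk("A", "c1", rep(2, 8)), mk("B", "c1", rep(2, 8)),
                         mk("C", "c1", rep(2, 8)))
  rk4 <- suppressWarnings(consolidate_ranking(m4))
  expect_true(all(rk4$z_scores$z == 0))
  expect_equal(rk4$anova$f, 0)

  # tidy/glance surface
  td <- generics::tidy(rk)
  expect_true(all(c("tf", "comparison", "mean_z", "rank", "anova_p",
                    "min_tukey_p") %in% names(td)))
  gl <- generics::glance(rk)
  expect_equal(gl$n_tfs, 4)
})

test_that("the planted central TF wins the consolidated ranking", {
  spec <- synthetic_spec(n_genes = 800, seed = 50)
  sim <- simulate_counts(spec)
  net <- simulate_knowledge(spec, sim$truth)
  sigs <- lapply(names(sim$truth$planted_up), function(nm) {
    union(sim$truth$planted_up[[nm]], sim$truth$planted_down[[nm]])
  })
  names(sigs) <- names(sim$truth$planted_up)
  rk <- suppressWarnings(suppressMessages(
    consolidate_ranking(compute_tf_metrics(sim$truth$tfs, sigs, net))))
  expect_true(all(rk$summary$tf[rk$summary$rank == 1] == "TF1"))
  expect_equal(rk$overall$tf[1], "TF1")
})
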