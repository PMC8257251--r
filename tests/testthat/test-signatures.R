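make_two_group <- function(mA, mB) {
  m <- cbind(matrix(rep(mA, 3), ncol = 3), matrix(rep(mB, 3), ncol = 3))
  colnames(m) <- c(paste0("a", 1:3), paste0("b", 1:3))
  list(x = tiny_expr(m),
       design = tibble::tibble(sample = colnames(m),
                               group = rep(c("A", "B"), each = 3)))
}

test_that("group fold change is the ratio of group means", {
  tg <- make_two_group(c(100, 20, 50), c(25, 40, 50))
  cmp <- comparison_spec("A_vs_B", "A", "B")
  fc <- group_fold_change(tg$x, tg$design, cmp)
  expect_equal(fc$fc, c(4, 0.5, 1))
  expect_error(group_fold_change(tg$x, tg$design,
                                 comparison_spec("A_vs_C", "A", "C")),
               "group absent")
})

test_that("signature selection honours cutoffs and boundary convention", {
  fc_tbl <- tibble::tibble(gene = c("a", "b", "c", "d"),
                           fc = c(2.0, 1.6, 0.5, 1.0))
  cmp2 <- comparison_spec("x", "A", "B", fc_cutoff = 2)
  sig2 <- select_signature(fc_tbl, cmp2)
  expect_setequal(signature_genes(sig2, "up"), "a")     # inclusive boundary
  expect_setequal(signature_genes(sig2, "down"), "c")
  strict <- select_signature(fc_tbl, cmp2, inclusive = FALSE)
  expect_length(signature_genes(strict, "up"), 0)
  cmp15 <- comparison_spec("y", "A", "B", fc_cutoff = 1.5)
  sig15 <- select_signature(fc_tbl, cmp15)
  expect_setequal(signature_genes(sig15, "up"), c("a", "b"))
  expect_error(comparison_spec("z", "A", "A"), "differ")
  expect_error(comparison_spec("z", "A", "B", fc_cutoff = 0.5), "exceed")
})

test_that("reversing a comparison swaps up and down exactly", {
  set.seed(10)
  m <- matrix(rlnorm(200 * 6, 5, 0.7) + 20, 200, 6)
  x <- tiny_expr(m)
  design <- tibble::tibble(sample = paste0("s", 1:6),
                           group = rep(c("A", "B"), each = 3))
  fwd <- select_signature(group_fold_change(x, design,
                                            comparison_spec("f", "A", "B")),
                          comparison_spec("f", "A", "B"))
  rev <- select_signature(group_fold_change(x, design,
                                            comparison_spec("r", "B", "A")),
                          comparison_spec("r", "B", "A"))
  expect_setequal(signature_genes(fwd, "up"), signature_genes(rev, "down"))
  expect_setequal(signature_genes(fwd, "down"), signature_genes(rev, "up"))
})

test_that("raising the cutoff never adds signature genes", {
  set.seed(11)
  fc_tbl <- tibble::tibble(gene = sprintf("g%03d", 1:300),
                           fc = exp(rnorm(300, 0, 0.8)))
  sizes <- sapply(c(1.2, 1.5, 2, 3), function(ct) {
    nrow(select_signature(fc_tbl, comparison_spec("c", "A", "B", ct)))
  })
  expect_true(all(diff(sizes) <= 0))
  lo <- select_signature(fc_tbl, comparison_spec("c", "A", "B", 1.5))
  hi <- select_signature(fc_tbl, comparison_spec("c", "A", "B", 2))
  expect_true(all(hi$gene %in% lo$gene))
})

test_that("planted genes are recovered at the fold-change stage", {
  spec <- synthetic_spec(n_genes = 1000, nb_dispersion = 0.05, seed = 12)
  sim <- simulate_counts(spec)
  norm <- suppressMessages(preprocess_counts(sim$counts, sim$design))
  cmp <- sim$truth$comparisons[[1]]  # MAF_vs_NLF at cutoff 2
  sig <- select_signature(group_fold_change(norm, sim$design, cmp), cmp)
  up_truth <- intersect(sim$truth$planted_up[[cmp$name]], norm$gene)
  recall <- mean(up_truth %in% signature_genes(sig, "up"))
  expect_gte(recall, 0.9)
})

test_that("venn partition enumerates disjoint regions", {
  sets <- list(A = c("a", "b", "c"), B = c("b", "c", "d"), C = c("c", "e"))
  vp <- venn_partition(sets)
  expect_equal(sum(vp$n_genes), 5)
  expect_setequal(vp$genes[[which(vp$region == "A&B&C")]], "c")
  expect_setequal(vp$genes[[which(vp$region == "A&B")]], "b")
  # identical sets: only the full intersection is non-empty
  vp2 <- venn_partition(list(X = c("a", "b"), Y = c("a", "b")))
  expect_equal(vp2$region, "X&Y")
  # disjoint sets: only singleton regions
  vp3 <- venn_partition(list(X = "a", Y = "b"))
  expect_setequal(vp3$region, c("X", "Y"))
})

test_that("connectivity pruning drops small components and excluded channels", {
  # components of size 5, 3, 1
  ppi <- small_ppi(c("a1", "a2", "a3", "a4", "b1", "b2"),
                   c("a2", "a3", "a4", "a5", "b2", "b3"),
                   conf = 0.9)
  genes <- c(paste0("a", 1:5), paste0("b", 1:3), "lone")
  out <- suppressMessages(prune_by_connectivity(genes, ppi))
  expect_setequal(out, paste0("a", 1:5))

  # a textmining bridge between two sub-threshold pieces removes everything
  ppi2 <- small_ppi(c("x1", "x2", "y1", "y2", "x3"),
                    c("x2", "x3", "y2", "y3", "y1"),
                    conf = 0.9,
                    channel = c("db", "db", "db", "db", "textmining"))
  out2 <- suppressMessages(prune_by_connectivity(
    c(paste0("x", 1:3), paste0("y", 1:3)), ppi2))
  expect_length(out2, 0)

  expect_error(prune_by_connectivity("a", small_ppi("a", "b", 1.3)),
               "confidences")
})

test_that("pruning equals a union-find oracle and is conservative", {
  set.seed(13)
  genes <- sprintf("n%02d", 1:50)
  ea <- sample(genes, 120, replace = TRUE)
  eb <- sample(genes, 120, replace = TRUE)
  keep <- ea != eb
  ppi <- small_ppi(ea[keep], eb[keep], conf = runif(sum(keep), 0.05, 1),
                   channel = sample(c("db", "textmining"), sum(keep), TRUE))
  out <- suppressMessages(prune_by_connectivity(genes, ppi, min_conf = 0.3,
                                                min_component = 4))
  ok <- ppi$confidence > 0.3 & ppi$channel != "textmining"
  comps <- uf_components(genes, ppi$gene_a[ok], ppi$gene_b[ok])
  brute <- unlist(comps[lengths(comps) >= 4], use.names = FALSE)
  expect_setequal(out, brute)
  expect_true(all(out %in% genes))
  # identity settings keep every gene present in the network
  all_kept <- suppressMessages(prune_by_connectivity(genes, ppi,
                                                     min_conf = 0,
                                                     excluded_channels = character(0),
                                                     min_component = 1))
  expect_setequal(all_kept, genes)
})
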