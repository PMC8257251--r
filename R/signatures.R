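#' Define a two-group comparison with its fold-change cutoff
#'
#' @param name comparison label, e.g. `"MAF_vs_NLF"`.
#' @param numerator,denominator group names; fold change is
#'   mean(numerator) / mean(denominator).
#' @param fc_cutoff linear fold-change cutoff (> 1). Conventional defaults
#'   for the three stage comparisons are 2.0 (late vs normal), 1.5 (early vs
#'   normal) and 2.0 (late vs early).
#' @return a `comparison_spec` list.
#' @export
comparison_spec <- function(name, numerator, denominator, fc_cutoff = 2) {
  if (identical(numerator, denominator)) abort("numerator must differ from denominator")
  if (fc_cutoff <= 1) abort("fc_cutoff must exceed 1")
  structure(list(name = name, numerator = numerator,
                 denominator = denominator, fc_cutoff = fc_cutoff),
            class = "comparison_spec")
}

group_means <- function(x, design, groups) {
  m <- as_expr_matrix(x)
  check_design(x, design)
  lapply(groups, function(g) {
    ss <- design$sample[design$group == g]
    ss <- intersect(ss, colnames(m))
    if (length(ss) == 0) abort(paste0("group absent from design/matrix: ", g))
    rowMeans(m[, ss, drop = FALSE])
  })
}

#' Per-gene group fold change
#'
#' Ratio of group means on the linear normalized-and-floored scale; flooring
#' guarantees finite ratios and damps fold-change inflation from lowly
#' expressed genes.
#'
#' @param x normalized, floored expression tibble.
#' @param design sample/group design tibble.
#' @param comparison a [comparison_spec()].
#' @return tibble (gene, fc).
#' @export
group_fold_change <- function(x, design, comparison) {
  stopifnot(inherits(comparison, "comparison_spec"))
  mm <- group_means(x, design, c(comparison$numerator, comparison$denominator))
  tibble(gene = x$gene, fc = unname(mm[[1]] / mm[[2]]))
}

#' Select a directional gene signature by fold-change cutoff
#'
#' Up = genes with FC at or above the cutoff; down = genes with FC at or
#' below its reciprocal. Boundary handling is inclusive by default
#' (boundary genes are measure-zero on real data).
#'
#' @param fc_tbl tibble (gene, fc) from [group_fold_change()].
#' @param comparison a [comparison_spec()].
#' @param inclusive include genes exactly at the cutoff.
#' @return signature tibble (gene, comparison, direction, fc) of class
#'   `gene_signature`.
#' @export
select_signature <- function(fc_tbl, comparison, inclusive = TRUE) {
  stopifnot(inherits(comparison, "comparison_spec"))
  fc <- fc_tbl$fc
  if (any(!is.finite(fc)) || any(fc <= 0)) abort("fold changes must be finite and positive")
  cut <- comparison$fc_cutoff
  up <- if (inclusive) fc >= cut else fc > cut
  dn <- if (inclusive) fc <= 1 / cut else fc < 1 / cut
  out <- bind_rows(
    tibble(gene = fc_tbl$gene[up], direction = "up", fc = fc[up]),
    tibble(gene = fc_tbl$gene[dn], direction = "down", fc = fc[dn])
  )
  out <- tibble(gene = out$gene, comparison = comparison$name,
                direction = out$direction, fc = out$fc)
  class(out) <- c("gene_signature", class(out))
  out
}

#' Gene IDs of a signature
#'
#' @param sig a `gene_signature` tibble.
#' @param direction `"up"`, `"down"` or `"both"`.
#' @return character vector of gene IDs.
#' @export
signature_genes <- function(sig, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  if (direction == "both") return(unique(sig$gene))
  unique(sig$gene[sig$direction == direction])
}

#' Partition gene sets into disjoint Venn regions
#'
#' @param sets a named list of character vectors, or a list of
#'   `gene_signature` tibbles (their up-and-down unions are used, named by
#'   comparison).
#' @return tibble (region, n_genes, genes list-column); regions are named by
#'   the `&`-joined set names they belong to, region sizes sum to the size
#'   of the overall union.
#' @export
venn_partition <- function(sets) {
  if (length(sets) < 2) abort("need at least 2 sets")
  if (is.data.frame(sets[[1]])) {
    nm <- vapply(sets, function(s) s$comparison[1], character(1))
    sets <- lapply(sets, signature_genes)
    names(sets) <- nm
  }
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  all_genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_genes %in% s, logical(length(all_genes)))
  if (length(all_genes) == 1) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "&"))
  split_genes <- split(all_genes, key)
  tibble(region = names(split_genes),
         n_genes = lengths(split_genes),
         genes = unname(split_genes))
}

ppi_graph <- function(ppi, min_conf, excluded_channels) {
  stopifnot(all(c("gene_a", "gene_b", "confidence") %in% names(ppi)))
  keep <- ppi$confidence > min_conf
  if ("channel" %in% names(ppi) && length(excluded_channels) > 0) {
    keep <- keep & !(ppi$channel %in% excluded_channels)
  }
  ppi[keep, , drop = FALSE]
}

#' Prune a gene set to its interconnected core
#'
#' Keeps only genes lying in sufficiently large connected components of the
#' PPI subgraph induced on the set, after discarding low-confidence edges and
#' excluded evidence channels (text-mining by default). Genes absent from
#' the network count as isolated singletons and are dropped.
#'
#' @param genes character vector of gene IDs.
#' @param ppi PPI edge tibble (gene_a, gene_b, confidence, channel).
#' @param min_conf minimum edge confidence (exclusive).
#' @param excluded_channels evidence channels to discard.
#' @param min_component minimum connected-component size to survive.
#' @return character vector of surviving gene IDs.
#' @export
prune_by_connectivity <- function(genes, ppi, min_conf = 0.3,
                                  excluded_channels = "textmining",
                                  min_component = 4) {
  if (any(ppi$confidence <= 0 | ppi$confidence > 1)) {
    abort("PPI confidences must lie in (0, 1]")
  }
  genes <- unique(genes)
  ed <- ppi_graph(ppi, min_conf, excluded_channels)
  ed <- ed[ed$gene_a %in% genes & ed$gene_b %in% genes, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    ed[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = genes)
  )
  comp <- igraph::components(g)
  big <- which(comp$csize >= min_component)
  survivors <- names(comp$membership)[comp$membership %in% big]
  n_missing <- sum(!genes %in% c(ppi$gene_a, ppi$gene_b))
  inform(paste0("connectivity pruning: ", length(genes), " -> ",
                length(survivors), " genes (", n_missing,
                " absent from network)"))
  survivors
}
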