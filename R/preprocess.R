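#' Filter genes by a minimum-count rule
#'
#' Keeps genes with at least `min_count` counts in at least `min_samples`
#' samples (across the whole matrix), the standard low-expression filter for
#' bulk RNA-seq with 3-4 replicates per group.
#'
#' @param counts expression tibble (`gene` column + one numeric column per
#'   sample) of raw integer counts.
#' @param min_count minimum count per sample.
#' @param min_samples minimum number of samples reaching `min_count`.
#' @return filtered tibble, original gene order preserved.
#' @export
filter_min_counts <- function(counts, min_count = 20, min_samples = 3) {
  m <- as_expr_matrix(counts)
  if (any(m < 0) || any(m != floor(m))) abort("counts must be non-negative integers")
  keep <- rowSums(m >= min_count) >= min_samples
  if (!any(keep)) warn("no genes pass the minimum-count filter")
  out <- counts[keep, , drop = FALSE]
  attr(out, "provenance") <- attr(counts, "provenance")
  stamp_provenance(out, "min_count_filter", min_count = min_count,
                   min_samples = min_samples, removed = sum(!keep))
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample onto the same distribution: each column's values are
#' replaced by the mean of the column-wise order statistics at their rank;
#' ties receive the average of the tied target values. After normalization
#' the sorted value multiset is identical across columns.
#'
#' @param counts expression tibble.
#' @return normalized tibble.
#' @export
quantile_normalize <- function(counts) {
  m <- as_expr_matrix(counts)
  if (ncol(m) < 2) {
    warn("single-sample matrix: quantile normalization is the identity")
    return(stamp_provenance(counts, "quantile_normalize", columns = ncol(m)))
  }
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(qn) <- dimnames(m)
  stamp_provenance(expr_tbl(qn, counts), "quantile_normalize", columns = ncol(m))
}

#' Floor expression values
#'
#' Sets every entry below `floor` to `floor`, damping fold-change inflation
#' from lowly expressed genes.
#'
#' @param x expression tibble.
#' @param floor floor value.
#' @return floored tibble.
#' @export
floor_values <- function(x, floor = 20) {
  m <- as_expr_matrix(x)
  m[m < floor] <- floor
  stamp_provenance(expr_tbl(m, x), "floor", floor = floor)
}

#' Restrict to protein-coding genes
#'
#' @param x expression tibble.
#' @param coding_ids character vector of protein-coding gene IDs.
#' @return tibble restricted to `coding_ids`, original order preserved.
#' @export
subset_protein_coding <- function(x, coding_ids) {
  if (length(coding_ids) == 0) abort("coding_ids must be non-empty")
  keep <- x$gene %in% coding_ids
  if (!any(keep)) {
    abort("no overlap between matrix genes and coding_ids: ID-space mismatch?")
  }
  out <- x[keep, , drop = FALSE]
  attr(out, "provenance") <- attr(x, "provenance")
  stamp_provenance(out, "coding_subset", removed = sum(!keep))
}

per_group_cv <- function(m, design) {
  groups <- split(design$sample, design$group)
  vapply(groups, function(ss) {
    sub <- m[, ss, drop = FALSE]
    mu <- rowMeans(sub)
    if (any(mu == 0)) abort("zero group mean encountered; apply floor_values first")
    apply(sub, 1, sd) / mu
  }, numeric(nrow(m)))
}

#' Exclude the most in-group variable genes
#'
#' Computes, per group, the coefficient of variation (sd/mean over that
#' group's replicates) of each gene and removes the union, across groups, of
#' the top `ceiling(top_frac * n_genes)` CVs per group. Noisy genes dominated
#' by within-group technical variation are thereby excluded.
#'
#' @param x floored normalized expression tibble.
#' @param design tibble with `sample` and `group` columns.
#' @param top_frac fraction of genes removed per group (default top 1%).
#' @return filtered tibble.
#' @export
cv_filter <- function(x, design, top_frac = 0.01) {
  m <- as_expr_matrix(x)
  check_design(x, design)
  design <- design[design$sample %in% colnames(m), ]
  tab <- table(design$group)
  if (any(tab < 2)) abort("cv_filter needs >= 2 replicates per group")
  cvs <- per_group_cv(m, design)
  k <- ceiling(top_frac * nrow(m))
  drop <- unique(unlist(lapply(seq_len(ncol(cvs)), function(j) {
    order(cvs[, j], decreasing = TRUE)[seq_len(k)]
  })))
  out <- x[-drop, , drop = FALSE]
  attr(out, "provenance") <- attr(x, "provenance")
  stamp_provenance(out, "cv_filter", top_frac = top_frac,
                   per_group_k = k, removed = length(drop))
}

#' Z-score each gene across samples
#'
#' Centers and scales every row to mean 0 and population standard deviation
#' 1. Constant rows map to all zeros (with a message) so downstream
#' clustering stays total.
#'
#' @param x expression tibble.
#' @return tibble of per-gene Z-scores.
#' @export
zscore_rows <- function(x) {
  m <- as_expr_matrix(x)
  mu <- rowMeans(m)
  s <- sqrt(rowMeans((m - mu)^2))
  const <- s == 0
  if (any(const)) {
    inform(paste0(sum(const), " constant gene(s) set to zero Z-scores"))
    s[const] <- 1
  }
  z <- (m - mu) / s
  expr_tbl(z, x)
}

#' Hierarchical clustering of genes or samples
#'
#' Agglomerative clustering with Euclidean distance and average linkage, the
#' conventional choice for expression heat maps.
#'
#' @param x expression tibble (typically Z-scored).
#' @param axis cluster `"genes"` (rows) or `"samples"` (columns).
#' @return an object of class `hclust`.
#' @export
hcluster <- function(x, axis = c("genes", "samples")) {
  axis <- match.arg(axis)
  m <- as_expr_matrix(x)
  if (axis == "samples") m <- t(m)
  if (nrow(m) < 2) abort("need at least 2 items to cluster")
  hclust(dist(m, method = "euclidean"), method = "average")
}

#' Principal component analysis of samples
#'
#' Genes are centered internally; samples are projected onto the principal
#' axes of expression variation.
#'
#' @param x expression tibble.
#' @param n_components number of components to keep (default all).
#' @return list of class `cafnet_pca`: `scores` tibble (sample + PCs),
#'   `loadings` matrix (genes x PCs), `var_frac` variance fractions.
#' @export
pca_project <- function(x, n_components = NULL) {
  m <- as_expr_matrix(x)
  if (ncol(m) < 2) abort("need at least 2 samples")
  max_k <- min(ncol(m), nrow(m))
  if (is.null(n_components)) n_components <- min(ncol(m) - 1, max_k)
  if (n_components > max_k) abort("n_components exceeds matrix rank bound")
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as_tibble(pc$x[, seq_len(k), drop = FALSE])
  scores <- dplyr::bind_cols(tibble(sample = colnames(m)), scores)
  structure(list(scores = scores,
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 var_frac = var_frac,
                 center = pc$center),
            class = "cafnet_pca")
}

#' Run the full count-preprocessing chain
#'
#' Fixed order: minimum-count filter, quantile normalization, flooring,
#' optional protein-coding subset, CV exclusion.
#'
#' @param counts raw count tibble.
#' @param design sample/group design tibble.
#' @param coding_ids optional protein-coding gene list.
#' @param min_count,min_samples,floor,top_cv stage thresholds.
#' @return preprocessed expression tibble with full provenance.
#' @export
preprocess_counts <- function(counts, design, coding_ids = NULL,
                              min_count = 20, min_samples = 3,
                              floor = 20, top_cv = 0.01) {
  x <- filter_min_counts(counts, min_count, min_samples)
  x <- quantile_normalize(x)
  x <- floor_values(x, floor)
  if (!is.null(coding_ids)) x <- subset_protein_coding(x, coding_ids)
  cv_filter(x, design, top_cv)
}
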