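#' @importFrom rlang abort warn inform .data %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows across all_of desc n row_number rename pull distinct
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_int map_chr map2 imap keep
#' @importFrom stats phyper p.adjust sd aov TukeyHSD prcomp hclust dist
#'   rnbinom rlnorm runif rpois setNames complete.cases pf var
#' @importFrom utils head combn
NULL

# expression tables are tibbles with a `gene` character column followed by one
# numeric column per sample; these helpers move between that shape and the
# matrix form used internally

as_expr_matrix <- function(x) {
  stopifnot(is.data.frame(x), "gene" %in% names(x))
  genes <- as.character(x$gene)
  if (anyDuplicated(genes)) {
    abort("duplicate gene IDs in expression table")
  }
  m <- as.matrix(x[setdiff(names(x), "gene")])
  if (!is.numeric(m)) abort("sample columns must be numeric")
  rownames(m) <- genes
  m
}

expr_tbl <- function(m, template = NULL) {
  out <- tibble(gene = rownames(m))
  out <- dplyr::bind_cols(out, as_tibble(m, .name_repair = "minimal"))
  if (!is.null(template)) {
    attr(out, "provenance") <- attr(template, "provenance")
  }
  out
}

sample_cols <- function(x) setdiff(names(x), "gene")

check_design <- function(x, design) {
  stopifnot(is.data.frame(design), all(c("sample", "group") %in% names(design)))
  missing <- setdiff(sample_cols(x), design$sample)
  if (length(missing) > 0) {
    abort(paste0("samples absent from design: ", paste(missing, collapse = ", ")))
  }
  invisible(design)
}

groups_of <- function(x, design) {
  design <- check_design(x, design)
  split(design$sample[design$sample %in% sample_cols(x)],
        design$group[design$sample %in% sample_cols(x)])
}

# population (n-denominator) z-score; constant vectors map to zero
zscore_pop <- function(v) {
  mu <- mean(v)
  s <- sqrt(mean((v - mu)^2))
  if (s == 0) return(rep(0, length(v)))
  (v - mu) / s
}

stamp_provenance <- function(x, step, ...) {
  prov <- attr(x, "provenance") %||% list()
  prov[[step]] <- c(list(at = length(prov) + 1L), list(...))
  attr(x, "provenance") <- prov
  x
}

#' Retrieve the provenance record of an expression table
#'
#' Each preprocessing step stamps the returned table with what it did
#' (thresholds, number of genes removed). Useful for audit trails; dplyr
#' verbs may drop the attribute, so query it right after a pipeline step.
#'
#' @param x an expression tibble produced by the preprocessing functions
#' @return a named list, one entry per applied step
#' @export
provenance <- function(x) attr(x, "provenance") %||% list()
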