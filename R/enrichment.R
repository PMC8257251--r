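#' Construct a gene-set database
#'
#' @param x tibble with columns `term`, `description`, `genes` (list-column
#'   of character vectors).
#' @param database database label (e.g. "GO_BP", "KEGG", "Reactome").
#' @return the tibble with class `gene_set_db` and a `database` attribute.
#' @export
gene_set_db <- function(x, database) {
  stopifnot(all(c("term", "genes") %in% names(x)))
  if (!"description" %in% names(x)) x$description <- x$term
  if (anyDuplicated(x$term)) abort("term IDs must be unique within a database")
  if (any(lengths(x$genes) == 0)) abort("gene sets must be non-empty")
  x <- as_tibble(x[, c("term", "description", "genes")])
  attr(x, "database") <- database
  class(x) <- c("gene_set_db", class(x))
  x
}

db_name <- function(db) attr(db, "database") %||% "db"

#' Hypergeometric over-representation analysis
#'
#' For every term (intersected with the universe and capped at
#' `max_term_size`), tests whether the query list overlaps it more than
#' expected under uniform sampling: the upper-tail hypergeometric p-value
#' P(X >= overlap). q-values are Benjamini-Hochberg across all tested terms
#' of this database run; coverage is overlap / term size within the universe.
#'
#' @param query character vector of genes, a subset of `universe`.
#' @param universe character vector: all genes that survived preprocessing.
#' @param db a [gene_set_db()].
#' @param max_term_size terms larger than this (within the universe) are
#'   excluded.
#' @param comparison,direction labels attached to the records (direction is
#'   `"up"` or `"down"`; it signs the consolidated group scores later).
#' @return tibble of enrichment records (term, database, comparison,
#'   direction, n_term, n_overlap, coverage, p, q, overlap_genes list-col).
#' @export
ora_test <- function(query, universe, db, max_term_size = 500,
                     comparison = NA_character_, direction = NA_character_) {
  query <- unique(query)
  universe <- unique(universe)
  if (!all(query %in% universe)) {
    abort("query must be a subset of the universe (p-values would be inflated)")
  }
  sets <- lapply(db$genes, intersect, y = universe)
  keep <- lengths(sets) > 0 & lengths(sets) <= max_term_size
  if (!any(keep)) {
    return(tibble(term = character(), database = character(),
                  comparison = character(), direction = character(),
                  n_term = integer(), n_overlap = integer(),
                  coverage = numeric(), p = numeric(), q = numeric(),
                  overlap_genes = list()))
  }
  sets <- sets[keep]
  terms <- db$term[keep]
  n_u <- length(universe)
  n_q <- length(query)
  ov <- lapply(sets, intersect, y = query)
  k <- lengths(ov)
  K <- lengths(sets)
  # P(X >= k) for X ~ Hypergeometric(N = n_u, K, n_q)
  p <- phyper(k - 1, K, n_u - K, n_q, lower.tail = FALSE)
  out <- tibble(term = terms, database = db_name(db),
                comparison = comparison, direction = direction,
                n_term = as.integer(K), n_overlap = as.integer(k),
                coverage = k / K, p = p,
                q = p.adjust(p, method = "BH"),
                overlap_genes = ov)
  arrange(out, .data$p)
}

#' Filter enrichment records on significance and coverage
#'
#' @param records tibble from [ora_test()].
#' @param p_max maximum nominal p-value (exclusive).
#' @param q_max maximum BH q-value (exclusive).
#' @param coverage_min minimum coverage fraction (exclusive).
#' @return the records passing all three thresholds.
#' @export
filter_records <- function(records, p_max = 0.01, q_max = 0.05,
                           coverage_min = 0.03) {
  keep <- records$p < p_max & records$q < q_max & records$coverage > coverage_min
  inform(paste0("enrichment filter: ", nrow(records), " -> ", sum(keep), " terms"))
  records[keep, , drop = FALSE]
}

#' Consolidate enriched terms across databases into annotation groups
#'
#' Builds a term-similarity graph: two terms from different databases are
#' connected when their overlap gene sets share at least `min_shared` genes
#' and their overlap coefficient (or Jaccard index) exceeds `min_overlap`.
#' Connected components form annotation groups; components smaller than
#' `min_group` terms or drawn from a single database are discarded. This
#' retains only functions supported by independent annotation sources.
#'
#' @param records filtered enrichment records from at least two databases;
#'   all of one comparison/direction.
#' @param min_overlap minimum relative overlap (exclusive).
#' @param min_shared minimum number of shared genes between overlap sets.
#' @param min_group minimum terms per surviving group.
#' @param method `"overlap"` (|A∩B| / min(|A|,|B|)) or `"jaccard"`.
#' @param same_db_edges also allow edges within one database.
#' @return tibble: group, term, database, p, q, direction, comparison.
#' @export
consolidate_terms <- function(records, min_overlap = 0.2, min_shared = 2,
                              min_group = 3,
                              method = c("overlap", "jaccard"),
                              same_db_edges = FALSE) {
  method <- match.arg(method)
  n <- nrow(records)
  if (n == 0) return(tibble(group = character(), term = character(),
                            database = character(), p = numeric(),
                            q = numeric(), direction = character(),
                            comparison = character()))
  # canonical order so grouping is invariant to input permutation
  ord <- order(records$database, records$term)
  records <- records[ord, , drop = FALSE]
  sets <- records$overlap_genes
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (!same_db_edges && records$database[i] == records$database[j]) next
      shared <- length(intersect(sets[[i]], sets[[j]]))
      if (shared < min_shared) next
      denom <- switch(method,
        overlap = min(length(sets[[i]]), length(sets[[j]])),
        jaccard = length(union(sets[[i]], sets[[j]])))
      if (denom == 0) next
      if (shared / denom > min_overlap) pairs[[length(pairs) + 1]] <- c(i, j)
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(pairs) > 0) {
    g <- igraph::add_edges(g, unlist(pairs))
  }
  comp <- igraph::components(g)
  records$.comp <- comp$membership
  kept <- records |>
    group_by(.data$.comp) |>
    filter(n() >= min_group, dplyr::n_distinct(.data$database) >= 2) |>
    ungroup()
  if (nrow(kept) == 0) return(tibble(group = character(), term = character(),
                                     database = character(), p = numeric(),
                                     q = numeric(), direction = character(),
                                     comparison = character()))
  # label each group by its most significant member term's description
  labels <- kept |>
    group_by(.data$.comp) |>
    summarise(label = .data$term[which.min(.data$q)][1], .groups = "drop")
  kept <- left_join(kept, labels, by = ".comp")
  tibble(group = kept$label, term = kept$term, database = kept$database,
         p = kept$p, q = kept$q, direction = kept$direction,
         comparison = kept$comparison)
}

#' Summarize annotation groups for bubble plots
#'
#' Per group: number of member terms and the signed mean of -log10(q);
#' groups derived from a downregulated gene list get a negative sign.
#'
#' @param groups tibble from [consolidate_terms()].
#' @param q_floor q-values are floored here before taking logs.
#' @return tibble (comparison, direction, group, n_terms, signed_score).
#' @export
summarize_groups <- function(groups, q_floor = 1e-300) {
  if (nrow(groups) == 0) {
    return(tibble(comparison = character(), direction = character(),
                  group = character(), n_terms = integer(),
                  signed_score = numeric()))
  }
  groups |>
    group_by(.data$comparison, .data$direction, .data$group) |>
    summarise(n_terms = n(),
              signed_score = mean(-log10(pmax(.data$q, q_floor))),
              .groups = "drop") |>
    mutate(signed_score = ifelse(.data$direction == "down",
                                 -.data$signed_score, .data$signed_score))
}
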