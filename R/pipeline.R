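#' Pipeline configuration with the study defaults
#'
#' Collects every threshold of the analysis chain in one declarative
#' object. Defaults: count filter (>= 20 counts in >= 3 samples), floor 20,
#' top-1% CV exclusion, fold-change cutoffs 2.0 / 1.5 / 2.0 for the
#' late-vs-normal, early-vs-normal and late-vs-early comparisons, pruning
#' confidence > 0.3 with text-mining excluded and components < 4 dropped,
#' ORA thresholds p < 0.01, q < 0.05, coverage > 3%, term consolidation
#' (overlap > 0.2, >= 2 shared genes, groups >= 3), GSEA with 1000 gene-set
#' permutations, set sizes 5-500, FDR < 0.05, |NES| > 2, and TF-stage
#' confidence > 0.2.
#'
#' @param counts,design expression and design tibbles (or paths handled by
#'   the caller).
#' @param comparisons list of [comparison_spec()]; default derived from the
#'   group order in `design`.
#' @param gene_set_dbs named list of [gene_set_db()] used for ORA.
#' @param hallmark_db a [gene_set_db()] used for GSEA (defaults to the
#'   first of `gene_set_dbs`).
#' @param networks list with `ppi`, `regulon`, `relatedness` tibbles.
#' @param tfs candidate TF IDs for the ranking stage.
#' @param coding_ids optional protein-coding gene list.
#' @param out_dir output directory (created if missing); NULL disables
#'   writing.
#' @param seed integer seed funnelled to every stochastic stage.
#' @param min_count,min_samples,floor,top_cv preprocessing thresholds.
#' @param prune_conf,prune_channels,min_component pruning thresholds.
#' @param ora_p,ora_q,ora_coverage,max_term_size ORA thresholds.
#' @param term_overlap,term_shared,term_group consolidation thresholds.
#' @param gsea_n_perm,gsea_min_size,gsea_max_size,gsea_fdr,gsea_nes GSEA
#'   settings.
#' @param tf_conf confidence threshold of the TF-ranking stage.
#' @param prune_signatures use the pruned gene lists for enrichment and TF
#'   ranking (the connectivity-filtered signatures).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(counts, design, comparisons = NULL,
                            gene_set_dbs = NULL, hallmark_db = NULL,
                            networks = NULL, tfs = NULL, coding_ids = NULL,
                            out_dir = NULL, seed = 1L,
                            min_count = 20, min_samples = 3, floor = 20,
                            top_cv = 0.01,
                            prune_conf = 0.3, prune_channels = "textmining",
                            min_component = 4,
                            ora_p = 0.01, ora_q = 0.05, ora_coverage = 0.03,
                            max_term_size = 500,
                            term_overlap = 0.2, term_shared = 2,
                            term_group = 3,
                            gsea_n_perm = 1000, gsea_min_size = 5,
                            gsea_max_size = 500, gsea_fdr = 0.05,
                            gsea_nes = 2,
                            tf_conf = 0.2,
                            prune_signatures = TRUE) {
  if (min_count < 0 || min_samples < 1) abort("invalid count-filter thresholds")
  if (floor <= 0) abort("floor must be positive")
  if (top_cv < 0 || top_cv >= 1) abort("top_cv must lie in [0, 1)")
  if (prune_conf < 0 || prune_conf >= 1) abort("prune_conf must lie in [0, 1)")
  if (tf_conf < 0 || tf_conf >= 1) abort("tf_conf must lie in [0, 1)")
  if (any(c(ora_p, ora_q) <= 0) || any(c(ora_p, ora_q) > 1)) {
    abort("ORA p/q thresholds must lie in (0, 1]")
  }
  if (gsea_n_perm < 1) abort("gsea_n_perm must be positive")
  if (is.null(comparisons)) {
    grp <- unique(design$group)
    reps <- table(design$group)[grp]
    comparisons <- default_comparisons(setNames(as.integer(reps), grp))
  }
  for (cmp in comparisons) {
    if (!inherits(cmp, "comparison_spec")) abort("comparisons must be comparison_spec objects")
  }
  cfg <- list(counts = counts, design = design, comparisons = comparisons,
              gene_set_dbs = gene_set_dbs,
              hallmark_db = hallmark_db %||% gene_set_dbs[[1]],
              networks = networks, tfs = tfs, coding_ids = coding_ids,
              out_dir = out_dir, seed = as.integer(seed),
              min_count = min_count, min_samples = min_samples,
              floor = floor, top_cv = top_cv,
              prune_conf = prune_conf, prune_channels = prune_channels,
              min_component = min_component,
              ora_p = ora_p, ora_q = ora_q, ora_coverage = ora_coverage,
              max_term_size = max_term_size,
              term_overlap = term_overlap, term_shared = term_shared,
              term_group = term_group,
              gsea_n_perm = gsea_n_perm, gsea_min_size = gsea_min_size,
              gsea_max_size = gsea_max_size, gsea_fdr = gsea_fdr,
              gsea_nes = gsea_nes, tf_conf = tf_conf,
              prune_signatures = prune_signatures)
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  thresholds <- cfg[!names(cfg) %in%
                      c("counts", "design", "gene_set_dbs", "hallmark_db",
                        "networks", "out_dir")]
  rlang::hash(thresholds)
}

#' Run the full analysis chain
#'
#' Preprocessing, fold-change signatures per comparison, connectivity
#' pruning, over-representation analysis with cross-database consolidation,
#' GSEA, and the multi-evidence TF ranking, in that fixed order. All
#' intermediates are returned (and written as TSV plus a JSON provenance
#' manifest when `out_dir` is set); given the same config and seed the
#' output is byte-identical across runs.
#'
#' @param cfg a [pipeline_config()].
#' @return list: `normalized`, `signatures`, `pruned`, `enrichment`
#'   (records, groups, bubble), `gsea`, `ranking`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  counts <- cfg$counts
  design <- cfg$design
  manifest <- list(seed = cfg$seed, config_hash = config_hash(cfg),
                   thresholds = list(
                     min_count = cfg$min_count, min_samples = cfg$min_samples,
                     floor = cfg$floor, top_cv = cfg$top_cv,
                     prune_conf = cfg$prune_conf,
                     min_component = cfg$min_component,
                     ora = c(cfg$ora_p, cfg$ora_q, cfg$ora_coverage),
                     term = c(cfg$term_overlap, cfg$term_shared, cfg$term_group),
                     gsea = c(cfg$gsea_n_perm, cfg$gsea_min_size,
                              cfg$gsea_max_size, cfg$gsea_fdr, cfg$gsea_nes),
                     tf_conf = cfg$tf_conf),
                   stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage failed [", name, "]: ", conditionMessage(e)),
            class = paste0("cafnet_stage_", name))
    })
  }

  norm <- stage("preprocess", suppressMessages(preprocess_counts(
    counts, design, coding_ids = cfg$coding_ids,
    min_count = cfg$min_count, min_samples = cfg$min_samples,
    floor = cfg$floor, top_cv = cfg$top_cv)))
  manifest$stages$preprocess <- list(genes_in = nrow(counts),
                                     genes_out = nrow(norm))

  sigs <- stage("signatures", lapply(cfg$comparisons, function(cmp) {
    select_signature(group_fold_change(norm, design, cmp), cmp)
  }))
  names(sigs) <- vapply(cfg$comparisons, function(c) c$name, character(1))
  manifest$stages$signatures <- lapply(sigs, function(s)
    list(up = sum(s$direction == "up"), down = sum(s$direction == "down")))

  pruned <- NULL
  if (!is.null(cfg$networks)) {
    pruned <- stage("prune", lapply(sigs, function(s) {
      suppressMessages(prune_by_connectivity(
        signature_genes(s), cfg$networks$ppi, min_conf = cfg$prune_conf,
        excluded_channels = cfg$prune_channels,
        min_component = cfg$min_component))
    }))
    manifest$stages$prune <- lapply(pruned, length)
  }

  enrichment <- NULL
  if (!is.null(cfg$gene_set_dbs)) {
    universe <- norm$gene
    records <- stage("ora", {
      recs <- list()
      for (cmp_name in names(sigs)) {
        for (dir in c("up", "down")) {
          query <- signature_genes(sigs[[cmp_name]], dir)
          if (length(query) == 0) next
          for (db in cfg$gene_set_dbs) {
            r <- ora_test(query, universe, db,
                          max_term_size = cfg$max_term_size,
                          comparison = cmp_name, direction = dir)
            recs[[length(recs) + 1]] <- suppressMessages(
              filter_records(r, cfg$ora_p, cfg$ora_q, cfg$ora_coverage))
          }
        }
      }
      bind_rows(recs)
    })
    groups <- stage("consolidate", {
      gs <- list()
      if (nrow(records) > 0) {
        combos <- unique(records[, c("comparison", "direction")])
        for (i in seq_len(nrow(combos))) {
          sub <- records[records$comparison == combos$comparison[i] &
                           records$direction == combos$direction[i], ]
          gs[[i]] <- consolidate_terms(sub, min_overlap = cfg$term_overlap,
                                       min_shared = cfg$term_shared,
                                       min_group = cfg$term_group)
        }
      }
      bind_rows(gs)
    })
    bubble <- summarize_groups(groups)
    enrichment <- list(records = records, groups = groups, bubble = bubble)
    manifest$stages$enrichment <- list(records = nrow(records),
                                       grouped_terms = nrow(groups),
                                       groups = length(unique(groups$group)))
  }

  gsea_res <- NULL
  if (!is.null(cfg$hallmark_db)) {
    gsea_res <- stage("gsea", {
      res <- lapply(seq_along(cfg$comparisons), function(i) {
        run_gsea(norm, design, cfg$comparisons[[i]], cfg$hallmark_db,
                 n_perm = cfg$gsea_n_perm, min_size = cfg$gsea_min_size,
                 max_size = cfg$gsea_max_size,
                 seed = cfg$seed + i)
      })
      bind_rows(res)
    })
    manifest$stages$gsea <- list(
      tested = nrow(gsea_res),
      significant = nrow(select_hallmarks(gsea_res, cfg$gsea_fdr, cfg$gsea_nes)))
  }

  ranking <- NULL
  if (!is.null(cfg$networks) && !is.null(cfg$tfs)) {
    sig_lists <- if (cfg$prune_signatures && !is.null(pruned)) pruned
                 else lapply(sigs, signature_genes)
    ranking <- stage("rank_tfs", suppressWarnings(suppressMessages(
      consolidate_ranking(compute_tf_metrics(cfg$tfs, sig_lists,
                                             cfg$networks,
                                             min_conf = cfg$tf_conf)))))
    manifest$stages$rank_tfs <- list(
      n_tfs = length(cfg$tfs),
      top_tf = as.list(setNames(ranking$summary$tf[ranking$summary$rank == 1],
                                ranking$summary$comparison[ranking$summary$rank == 1])))
  }

  result <- list(normalized = norm, signatures = sigs, pruned = pruned,
                 enrichment = enrichment, gsea = gsea_res, ranking = ranking,
                 manifest = manifest)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(result, cfg)
  result
}

write_pipeline_outputs <- function(result, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(cfg$out_dir, f)
  guard <- p(paste0("manifest_", config_hash(cfg), ".json"))
  existing <- list.files(cfg$out_dir, pattern = "^manifest_.*\\.json$",
                         full.names = TRUE)
  if (length(existing) > 0 && !any(existing == guard)) {
    abort(paste0("output directory holds results from a different config: ",
                 cfg$out_dir, " (remove them or choose a new directory)"))
  }
  readr::write_tsv(result$normalized, p("normalized.tsv"))
  readr::write_tsv(bind_rows(result$signatures), p("signatures.tsv"))
  if (!is.null(result$pruned)) {
    pr <- bind_rows(imap(result$pruned, function(g, nm)
      tibble(comparison = nm, gene = g)))
    readr::write_tsv(pr, p("pruned_signatures.tsv"))
  }
  if (!is.null(result$enrichment)) {
    rec <- result$enrichment$records
    rec$overlap_genes <- vapply(rec$overlap_genes, paste, character(1),
                                collapse = ",")
    readr::write_tsv(rec, p("enrichment_records.tsv"))
    readr::write_tsv(result$enrichment$groups, p("term_groups.tsv"))
    readr::write_tsv(result$enrichment$bubble, p("bubble_table.tsv"))
  }
  if (!is.null(result$gsea)) {
    gr <- result$gsea
    gr$leading_edge <- vapply(gr$leading_edge, paste, character(1),
                              collapse = ",")
    readr::write_tsv(gr, p("gsea_results.tsv"))
  }
  if (!is.null(result$ranking)) {
    readr::write_tsv(result$ranking$z_scores, p("tf_z_scores.tsv"))
    readr::write_tsv(tidy(result$ranking), p("tf_ranking.tsv"))
  }
  jsonlite::write_json(result$manifest, guard, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(cfg$out_dir)
}
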