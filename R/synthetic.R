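#' Specification of a synthetic fibroblast-stage experiment
#'
#' Bundles every knob of the synthetic-data generator: a negative-binomial
#' count matrix over three stage groups (normal-lung, micrometastasis- and
#' macrometastasis-associated fibroblasts by default) with planted
#' stage-specific fold changes, plus knowledge networks (PPI, TF regulon,
#' gene-TF relatedness) in which one designated transcription factor is more
#' connected to the planted signature than decoy TFs.
#'
#' @param n_genes total number of genes simulated.
#' @param groups named integer vector of replicate counts per group, in stage
#'   order. Every group needs at least 3 replicates (the downstream min-count
#'   filter assumes 3).
#' @param n_stage_unique number of planted differential genes unique to each
#'   comparison (half up, half down).
#' @param n_shared number of genes planted as differential in all comparisons
#'   (progressively dysregulated along the stages).
#' @param effect_log2fc planted absolute log2 fold change.
#' @param nb_dispersion negative-binomial dispersion: var = mu + mu^2 * disp.
#'   Zero gives Poisson counts.
#' @param libsize_sigma log-normal sd of per-sample library-size factors
#'   (rescaled to geometric mean 1).
#' @param n_tfs number of candidate transcription factors (first one is the
#'   planted central regulator).
#' @param central_tf_edge_prob,decoy_tf_edge_prob probability that a planted
#'   signature gene is linked to the central TF (resp. each decoy) in each
#'   evidence channel (PPI edge, regulon edge, direct-relatedness row).
#' @param background_edge_prob density of random gene-gene PPI edges.
#' @param signature_edge_prob extra PPI density among planted genes of the
#'   same comparison; models the co-functional modules that make the
#'   connectivity-pruning stage meaningful.
#' @param fraction_textmining fraction of PPI edges labelled "textmining"
#'   (excluded by the pruning stage).
#' @param indirect_fraction fraction of unlinked gene-TF pairs that receive a
#'   low "indirect" relatedness row.
#' @param seed integer seed; all generator output is deterministic given it.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 2000,
                           groups = c(NLF = 4L, MIF = 3L, MAF = 4L),
                           n_stage_unique = 50,
                           n_shared = 20,
                           effect_log2fc = 2,
                           nb_dispersion = 0.1,
                           libsize_sigma = 0.15,
                           n_tfs = 5,
                           central_tf_edge_prob = 0.4,
                           decoy_tf_edge_prob = 0.1,
                           background_edge_prob = 0.002,
                           signature_edge_prob = 0.08,
                           fraction_textmining = 0.2,
                           indirect_fraction = 0.3,
                           seed = 1L) {
  if (is.null(names(groups)) || any(names(groups) == "")) {
    abort("groups must be a named vector of replicate counts")
  }
  if (length(groups) < 2) abort("need at least two groups")
  if (any(groups < 3)) {
    abort("every group needs at least 3 replicates (min-sample filter assumes 3)")
  }
  probs <- c(central_tf_edge_prob, decoy_tf_edge_prob, background_edge_prob,
             signature_edge_prob, fraction_textmining, indirect_fraction)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (central_tf_edge_prob <= decoy_tf_edge_prob) {
    abort("central_tf_edge_prob must exceed decoy_tf_edge_prob")
  }
  if (effect_log2fc < 0) abort("effect_log2fc must be >= 0")
  if (nb_dispersion < 0) abort("nb_dispersion must be >= 0")
  if (n_tfs < 2) abort("need at least 2 candidate TFs")
  structure(list(
    n_genes = as.integer(n_genes), groups = groups,
    n_stage_unique = as.integer(n_stage_unique),
    n_shared = as.integer(n_shared),
    effect_log2fc = effect_log2fc, nb_dispersion = nb_dispersion,
    libsize_sigma = libsize_sigma, n_tfs = as.integer(n_tfs),
    central_tf_edge_prob = central_tf_edge_prob,
    decoy_tf_edge_prob = decoy_tf_edge_prob,
    background_edge_prob = background_edge_prob,
    signature_edge_prob = signature_edge_prob,
    fraction_textmining = fraction_textmining,
    indirect_fraction = indirect_fraction,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

default_comparisons <- function(groups) {
  nm <- names(groups)
  # stage order: first = baseline, later = advanced stages
  if (length(nm) < 3) {
    return(list(comparison_spec(paste0(nm[2], "_vs_", nm[1]), nm[2], nm[1], 2)))
  }
  list(
    comparison_spec(paste0(nm[3], "_vs_", nm[1]), nm[3], nm[1], 2.0),
    comparison_spec(paste0(nm[2], "_vs_", nm[1]), nm[2], nm[1], 1.5),
    comparison_spec(paste0(nm[3], "_vs_", nm[2]), nm[3], nm[2], 2.0)
  )
}

#' Simulate a gene-by-sample count matrix with planted stage effects
#'
#' Baseline gene means are log-normal; planted genes have the relevant group
#' means scaled by `2^(+/- effect_log2fc)`; counts are negative-binomial with
#' per-sample library-size factors. Ground truth records, per comparison, the
#' genes whose planted group-mean ratio is up or down.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `counts` (tibble, `gene` + one column per sample),
#'   `design` (tibble sample/group), and `truth` (list: `planted_up`,
#'   `planted_down` per comparison, `central_tf`, `library_factors`,
#'   `comparisons`).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  genes <- sprintf("g%05d", seq_len(spec$n_genes))
  grp_names <- names(spec$groups)
  samples <- unlist(lapply(grp_names, function(g) {
    paste0(g, "_", seq_len(spec$groups[[g]]))
  }))
  design <- tibble(sample = samples,
                   group = rep(grp_names, times = spec$groups))

  comparisons <- default_comparisons(spec$groups)
  n_cmp <- length(comparisons)

  # per-gene per-group log2 multipliers
  mult <- matrix(0, nrow = spec$n_genes, ncol = length(grp_names),
                 dimnames = list(genes, grp_names))
  needed <- n_cmp * spec$n_stage_unique + spec$n_shared
  if (needed > spec$n_genes) abort("n_genes too small for requested planting")
  planted_ids <- sample(genes, needed)
  idx <- 0L
  planted_members <- list()
  for (k in seq_len(n_cmp)) {
    cmp <- comparisons[[k]]
    ids <- planted_ids[idx + seq_len(spec$n_stage_unique)]
    idx <- idx + spec$n_stage_unique
    half <- ceiling(length(ids) / 2)
    up <- ids[seq_len(half)]
    dn <- setdiff(ids, up)
    mult[up, cmp$numerator] <- mult[up, cmp$numerator] + spec$effect_log2fc
    mult[dn, cmp$numerator] <- mult[dn, cmp$numerator] - spec$effect_log2fc
    planted_members[[cmp$name]] <- ids
  }
  shared <- planted_ids[idx + seq_len(spec$n_shared)]
  if (spec$n_shared > 0 && length(grp_names) >= 3) {
    half <- ceiling(length(shared) / 2)
    s_up <- shared[seq_len(half)]
    s_dn <- setdiff(shared, s_up)
    # progressive dysregulation: mid stage one effect unit, late stage two
    mult[s_up, grp_names[2]] <- spec$effect_log2fc
    mult[s_up, grp_names[3]] <- 2 * spec$effect_log2fc
    mult[s_dn, grp_names[2]] <- -spec$effect_log2fc
    mult[s_dn, grp_names[3]] <- -2 * spec$effect_log2fc
  }

  base_mean <- rlnorm(spec$n_genes, meanlog = log(200), sdlog = 1)
  lib <- rlnorm(length(samples), meanlog = 0, sdlog = spec$libsize_sigma)
  lib <- lib / exp(mean(log(lib)))
  names(lib) <- samples

  mu <- matrix(0, spec$n_genes, length(samples), dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    g <- design$group[j]
    mu[, j] <- base_mean * 2^mult[, g] * lib[j]
  }
  counts <- if (spec$nb_dispersion > 0) {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / spec$nb_dispersion),
           nrow = spec$n_genes, dimnames = dimnames(mu))
  } else {
    matrix(rpois(length(mu), lambda = mu),
           nrow = spec$n_genes, dimnames = dimnames(mu))
  }

  planted_up <- planted_down <- list()
  for (cmp in comparisons) {
    ratio <- mult[, cmp$numerator] - mult[, cmp$denominator]
    planted_up[[cmp$name]] <- genes[ratio > 0]
    planted_down[[cmp$name]] <- genes[ratio < 0]
  }

  truth <- list(
    planted_up = planted_up,
    planted_down = planted_down,
    planted_members = planted_members,
    shared_genes = shared,
    central_tf = "TF1",
    tfs = paste0("TF", seq_len(spec$n_tfs)),
    library_factors = lib,
    comparisons = comparisons,
    base_mean = base_mean,
    multipliers = mult
  )
  list(counts = expr_tbl(counts), design = design, truth = truth)
}

sample_pairs <- function(n_items, prob) {
  # draw Binomial(M, prob) unordered pairs without replacement by index
  m <- n_items * (n_items - 1) / 2
  if (m < 1 || prob <= 0) return(cbind(integer(0), integer(0)))
  k <- stats::rbinom(1, size = m, prob = prob)
  if (k == 0) return(cbind(integer(0), integer(0)))
  id <- sample(m, k)
  # map linear index to (i, j), i < j, row-major over the upper triangle:
  # row i holds n_items - i pairs
  cum <- cumsum(seq(n_items - 1, 1))
  i <- findInterval(id - 0.5, c(0, cum))
  j <- id - c(0, cum)[i] + i
  cbind(as.integer(i), as.integer(j))
}

#' Simulate knowledge networks around a planted central TF
#'
#' Builds the three evidence sources consumed by the TF-ranking stage: a
#' weighted undirected PPI edge list with evidence-channel labels, a directed
#' TF-to-target regulon, and a gene-by-TF relatedness table with direct /
#' indirect flags. The central TF is linked to each planted signature gene
#' with `central_tf_edge_prob` in every channel, decoys with
#' `decoy_tf_edge_prob`; relatedness scores of linked (direct) rows are drawn
#' from Uniform(5, 30) versus Uniform(0, 5) for indirect rows.
#'
#' @param spec a [synthetic_spec()].
#' @param truth ground truth from [simulate_counts()] (same gene universe).
#' @return list with tibbles `ppi` (gene_a, gene_b, confidence, channel),
#'   `regulon` (tf, target), `relatedness` (gene, tf, score, flag).
#' @export
simulate_knowledge <- function(spec, truth) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1000L)
  genes <- sprintf("g%05d", seq_len(spec$n_genes))
  tfs <- truth$tfs
  sig_by_cmp <- lapply(names(truth$planted_up), function(nm) {
    union(truth$planted_up[[nm]], truth$planted_down[[nm]])
  })
  names(sig_by_cmp) <- names(truth$planted_up)
  sig_all <- unique(unlist(sig_by_cmp))

  # background gene-gene edges
  bg <- sample_pairs(spec$n_genes, spec$background_edge_prob)
  edges <- tibble(gene_a = genes[bg[, 1]], gene_b = genes[bg[, 2]])

  # co-functional modules: extra density inside each comparison's planted set
  for (ids in sig_by_cmp) {
    if (length(ids) < 2) next
    mp <- sample_pairs(length(ids), spec$signature_edge_prob)
    if (nrow(mp) > 0) {
      edges <- bind_rows(edges, tibble(gene_a = ids[mp[, 1]], gene_b = ids[mp[, 2]]))
    }
  }

  # TF links in the PPI channel
  link <- function(tf, p) {
    hit <- sig_all[runif(length(sig_all)) < p]
    if (length(hit) == 0) return(NULL)
    tibble(gene_a = tf, gene_b = hit)
  }
  tf_ppi <- bind_rows(c(
    list(link(truth$central_tf, spec$central_tf_edge_prob)),
    lapply(setdiff(tfs, truth$central_tf), link, p = spec$decoy_tf_edge_prob)
  ))
  edges <- bind_rows(edges, tf_ppi)
  edges <- dplyr::distinct(edges, .data$gene_a, .data$gene_b)
  channels <- c("experiments", "database", "coexpression")
  edges$confidence <- runif(nrow(edges), 0.15, 0.95)
  is_tm <- runif(nrow(edges)) < spec$fraction_textmining
  edges$channel <- ifelse(is_tm, "textmining",
                          sample(channels, nrow(edges), replace = TRUE))

  # regulon channel
  reg_link <- function(tf, p) {
    hit <- sig_all[runif(length(sig_all)) < p]
    if (length(hit) == 0) return(NULL)
    tibble(tf = tf, target = hit)
  }
  regulon <- bind_rows(c(
    list(reg_link(truth$central_tf, spec$central_tf_edge_prob)),
    lapply(setdiff(tfs, truth$central_tf), reg_link, p = spec$decoy_tf_edge_prob)
  ))
  if (nrow(regulon) == 0) regulon <- tibble(tf = character(), target = character())

  # relatedness channel: direct rows for linked pairs, indirect for a random
  # fraction of the remaining signature-gene x TF pairs
  rel <- list()
  for (tf in tfs) {
    p <- if (tf == truth$central_tf) spec$central_tf_edge_prob else spec$decoy_tf_edge_prob
    linked <- sig_all[runif(length(sig_all)) < p]
    unlinked <- setdiff(sig_all, linked)
    indirect <- unlinked[runif(length(unlinked)) < spec$indirect_fraction]
    rel[[tf]] <- bind_rows(
      if (length(linked)) tibble(gene = linked, tf = tf,
                                 score = runif(length(linked), 5, 30),
                                 flag = "direct"),
      if (length(indirect)) tibble(gene = indirect, tf = tf,
                                   score = runif(length(indirect), 0, 5),
                                   flag = "indirect")
    )
  }
  relatedness <- bind_rows(rel)
  if (nrow(relatedness) == 0) {
    relatedness <- tibble(gene = character(), tf = character(),
                          score = numeric(), flag = character())
  }

  list(ppi = edges, regulon = regulon, relatedness = relatedness)
}

#' Simulate gene-set databases with terms covering the planted signatures
#'
#' Builds `n_databases` synthetic annotation databases. Each planted
#' comparison contributes enriched terms (random subsets of its planted up or
#' down genes padded with background genes); the rest are random background
#' terms. Used to exercise the over-representation and consolidation stages
#' end to end.
#'
#' @param spec a [synthetic_spec()].
#' @param truth ground truth from [simulate_counts()].
#' @param n_databases number of databases.
#' @param n_background_terms random terms per database.
#' @param term_size size range of background terms.
#' @return named list of gene-set tibbles (term, description, genes list-col),
#'   one per database, each of class `gene_set_db`.
#' @export
simulate_gene_sets <- function(spec, truth, n_databases = 3,
                               n_background_terms = 40,
                               term_size = c(10, 80)) {
  set.seed(spec$seed + 2000L)
  genes <- sprintf("g%05d", seq_len(spec$n_genes))
  dbs <- list()
  for (d in seq_len(n_databases)) {
    db_name <- paste0("DB", d)
    terms <- list()
    # enriched terms share a planted core so cross-database consolidation
    # has something to fuse
    for (nm in names(truth$planted_up)) {
      for (dir in c("up", "down")) {
        planted <- if (dir == "up") truth$planted_up[[nm]] else truth$planted_down[[nm]]
        if (length(planted) < 4) next
        core <- sample(planted, max(4, round(length(planted) * 0.6)))
        pad <- sample(setdiff(genes, core), round(length(core) * 0.5))
        terms[[paste0(db_name, "_", nm, "_", dir)]] <- c(core, pad)
      }
    }
    for (b in seq_len(n_background_terms)) {
      sz <- sample(seq(term_size[1], term_size[2]), 1)
      terms[[paste0(db_name, "_bg", b)]] <- sample(genes, sz)
    }
    dbs[[db_name]] <- gene_set_db(
      tibble(term = names(terms),
             description = names(terms),
             genes = unname(terms)),
      database = db_name
    )
  }
  dbs
}

#' Write synthetic fixtures to disk
#'
#' Emits the full set of pipeline input files: counts and design TSVs, PPI /
#' regulon / relatedness TSVs, one GMT per gene-set database, a protein-coding
#' gene list, and the ground truth as JSON. Files round-trip through the
#' package readers.
#'
#' @param counts,design,truth output of [simulate_counts()].
#' @param networks output of [simulate_knowledge()].
#' @param out_dir existing writable directory.
#' @param gene_sets optional output of [simulate_gene_sets()].
#' @return named character vector of file paths.
#' @export
write_fixtures <- function(counts, design, truth, networks, out_dir,
                           gene_sets = NULL) {
  if (!dir.exists(out_dir)) {
    abort(paste0("output directory does not exist: ", out_dir))
  }
  p <- function(f) file.path(out_dir, f)
  paths <- c(counts = p("counts.tsv"), design = p("design.tsv"),
             ppi = p("ppi.tsv"), regulon = p("regulon.tsv"),
             relatedness = p("relatedness.tsv"),
             coding = p("coding_genes.txt"), truth = p("truth.json"))
  readr::write_tsv(counts, paths[["counts"]])
  readr::write_tsv(design, paths[["design"]])
  readr::write_tsv(networks$ppi, paths[["ppi"]])
  readr::write_tsv(networks$regulon, paths[["regulon"]])
  readr::write_tsv(networks$relatedness, paths[["relatedness"]])
  writeLines(counts$gene, paths[["coding"]])
  truth_json <- list(planted_up = truth$planted_up,
                     planted_down = truth$planted_down,
                     central_tf = truth$central_tf, tfs = truth$tfs,
                     library_factors = as.list(truth$library_factors))
  jsonlite::write_json(truth_json, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(gene_sets)) {
    for (nm in names(gene_sets)) {
      gp <- p(paste0(nm, ".gmt"))
      write_gmt(gene_sets[[nm]], gp)
      paths[[paste0("gmt_", nm)]] <- gp
    }
  }
  paths
}
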