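read_tsv_quiet <- function(path, ...) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

#' Read a gene-by-sample count matrix from TSV
#'
#' First column must be the gene ID (named `gene` or renamed to it),
#' remaining columns one per sample. Duplicate gene IDs are an error.
#'
#' @param path TSV file path.
#' @return expression tibble.
#' @export
read_counts <- function(path) {
  x <- read_tsv_quiet(path)
  names(x)[1] <- "gene"
  x$gene <- as.character(x$gene)
  if (anyDuplicated(x$gene)) {
    abort(paste0("duplicate gene ID in ", path, ": ",
                 x$gene[duplicated(x$gene)][1]))
  }
  if (!all(vapply(x[-1], is.numeric, logical(1)))) {
    abort(paste0("non-numeric sample column in ", path))
  }
  x
}

#' Read a sample design table from TSV
#'
#' @param path TSV with columns `sample` and `group`.
#' @return design tibble.
#' @export
read_design <- function(path) {
  x <- read_tsv_quiet(path)
  if (!all(c("sample", "group") %in% names(x))) {
    abort(paste0("design file must have sample and group columns: ", path))
  }
  if (anyDuplicated(x$sample)) abort(paste0("duplicate sample in ", path))
  x[, c("sample", "group")]
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Lines with fewer than 3 fields are a format error reported with
#' their line number.
#'
#' @param path GMT file path.
#' @param database database label (defaults to the file base name).
#' @return a [gene_set_db()].
#' @export
read_gmt <- function(path, database = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    abort(paste0("malformed GMT line ", bad[1], " in ", path,
                 " (need name, description, >= 1 member)"))
  }
  gene_set_db(tibble(
    term = vapply(parts, `[`, "", 1),
    description = vapply(parts, `[`, "", 2),
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  ), database = database %||% sub("\\.gmt$", "", basename(path)))
}

#' Write a gene-set database to GMT
#'
#' @param db a [gene_set_db()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(seq_len(nrow(db)), function(i) {
    paste(c(db$term[i], db$description[i], db$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a knowledge-network table
#'
#' @param path TSV file path.
#' @param kind `"ppi"` (gene_a, gene_b, confidence, channel), `"regulon"`
#'   (tf, target) or `"relatedness"` (gene, tf, score, flag).
#' @return validated tibble.
#' @export
read_network <- function(path, kind = c("ppi", "regulon", "relatedness")) {
  kind <- match.arg(kind)
  x <- read_tsv_quiet(path)
  required <- switch(kind,
    ppi = c("gene_a", "gene_b", "confidence"),
    regulon = c("tf", "target"),
    relatedness = c("gene", "tf", "score", "flag"))
  if (!all(required %in% names(x))) {
    abort(paste0(kind, " file must have columns ",
                 paste(required, collapse = ", "), ": ", path))
  }
  if (kind == "ppi") {
    if (any(x$confidence <= 0 | x$confidence > 1)) {
      abort(paste0("PPI confidence outside (0, 1] in ", path))
    }
    loops <- x$gene_a == x$gene_b
    if (any(loops)) {
      warn(paste0("dropping ", sum(loops), " self-loop(s) in ", path))
      x <- x[!loops, , drop = FALSE]
    }
  }
  if (kind == "relatedness") {
    if (any(!x$flag %in% c("direct", "indirect"))) {
      abort(paste0("relatedness flag must be direct/indirect: ", path))
    }
    if (any(x$score < 0)) abort(paste0("negative relatedness score in ", path))
    if (anyDuplicated(paste(x$gene, x$tf))) {
      abort(paste0("duplicate (gene, tf) relatedness row in ", path))
    }
  }
  x
}

#' Read a gene list (one ID per line)
#'
#' @param path text file path.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ids <- readLines(path)
  unique(ids[nzchar(ids)])
}
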