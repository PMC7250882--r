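#' Read a GMT gene-set file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to the GMT file.
#' @return Named list of gene-id character vectors, with the description
#'   lines attached as a named `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3
  if (any(bad)) {
    stop("GMT line(s) with fewer than 3 tab-separated fields in ", path,
         " (first: line ", which(bad)[1], ")")
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, `[[`, character(1), 2), names(sets))
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of gene-id character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of descriptions (recycled
#'   `"NA"` if missing).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("NA", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Flat term enrichment by two-sided Fisher's exact test
#'
#' For every term T, tests whether the subset S is enriched (or depleted)
#' for T's genes relative to the background B via the 2x2 table
#' a = |S &cap; T|, b = |S| - a, c = |T &cap; B| - a, d = |B| - |T &cap; B| - b.
#' Annotation is treated as flat gene sets (no ontology DAG); p-values are
#' raw two-sided Fisher probabilities with a Benjamini-Hochberg column
#' alongside.
#'
#' @param subset Character vector of genes of interest (must be contained
#'   in `background`).
#' @param background Character vector of all analysed genes.
#' @param term_sets Named list of gene-id vectors (e.g. from [read_gmt()]);
#'   genes outside the background are ignored.
#' @return Tibble with `term`, `n_subset`, `n_term`, `overlap`, `expected`,
#'   `p`, `p_bh`, sorted by `p`.
#' @export
enrich_terms <- function(subset, background, term_sets) {
  subset <- unique(subset)
  background <- unique(background)
  if (!all(subset %in% background)) {
    stop("enrich_terms: subset contains gene(s) outside the background")
  }
  B <- length(background)
  S <- length(subset)
  rows <- purrr::imap(term_sets, function(genes, nm) {
    t_genes <- intersect(unique(genes), background)
    a <- length(intersect(subset, t_genes))
    b <- S - a
    cc <- length(t_genes) - a
    d <- B - length(t_genes) - b
    tibble(
      term = nm,
      n_subset = S,
      n_term = length(t_genes),
      overlap = a,
      expected = S * length(t_genes) / B,
      p = fisher_two_sided(a, b, cc, d)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_bh <- benjamini_hochberg(out$p)
  dplyr::arrange(out, .data$p, .data$term)
}

#' Phylostratum enrichment of a gene subset
#'
#' Compares the gene-age composition of a subset against the background by
#' a two-sided Fisher's exact test per stratum (each stratum treated as a
#' flat term over the assignment).
#'
#' @param subset,background Character vectors of gene ids; all genes must
#'   appear in `assignment`.
#' @param assignment Tibble from [assign_phylostrata()] (`gene_id`,
#'   `stratum`, `node_label`).
#' @return Tibble with `stratum`, `node_label`, `n_subset`, `n_term`,
#'   `overlap`, `expected`, `p`, `p_bh`, ordered by stratum.
#' @export
enrich_phylostrata <- function(subset, background, assignment) {
  missing <- setdiff(unique(c(subset, background)), assignment$gene_id)
  if (length(missing) > 0) {
    stop("gene(s) without a phylostratum: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  strata <- sort(unique(assignment$stratum))
  sets <- lapply(strata, function(s) {
    assignment$gene_id[assignment$stratum == s]
  })
  names(sets) <- as.character(strata)
  out <- enrich_terms(subset, background, sets)
  out$stratum <- as.integer(out$term)
  out$node_label <- assignment$node_label[match(
    out$stratum, assignment$stratum)]
  out$term <- NULL
  dplyr::arrange(
    dplyr::select(out, "stratum", "node_label", dplyr::everything()),
    .data$stratum
  )
}
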