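#' Map modules into orthogroup space
#'
#' Converts a per-species module partition into per-module orthogroup sets:
#' a module's set is the union of the orthogroups of its member genes, so a
#' family expanded by lineage-specific duplication still counts once. Genes
#' absent from the orthogroup table are dropped (their number is reported
#' via a message).
#'
#' @param partition Tibble with `gene_id` and `module` (0 = unassigned), as
#'   returned by [detect_modules()].
#' @param table Long orthogroup tibble (`orthogroup`, `species`, `gene_id`).
#' @param species Species whose column of `table` the partition's genes
#'   live in.
#' @return Tibble with `module` and `orthogroup`, one row per pair (module
#'   0 included, so callers can build the background universe from it).
#' @export
module_to_orthogroups <- function(partition, table, species) {
  if (!species %in% table$species) {
    stop("species '", species, "' not present in the orthogroup table")
  }
  sp_tbl <- dplyr::filter(table, .data$species == !!species)
  joined <- dplyr::left_join(partition, sp_tbl[, c("gene_id", "orthogroup")],
                             by = "gene_id")
  n_dropped <- sum(is.na(joined$orthogroup))
  if (n_dropped > 0) {
    rlang::inform(paste0(n_dropped, " gene(s) of ", species,
                         " not in any orthogroup; dropped from mapping"))
  }
  out <- dplyr::filter(joined, !is.na(.data$orthogroup))
  dplyr::distinct(out[, c("module", "orthogroup")])
}

#' Cross-species module overlap by upper-tail hypergeometric tests
#'
#' The central comparative statistic: every module of species A is tested
#' against every module of species B for excess sharing of orthogroups.
#' The universe N is the set of orthogroups carrying at least one analysed
#' gene in *both* species (so the test conditions on what could have been
#' drawn); each module is restricted to that universe, and for a pair
#' (M_A, M_B) with K = |O(M_A)|, n = |O(M_B)|, x = |O(M_A) &cap; O(M_B)| the
#' reported p is P[X >= x] under Hypergeometric(N, K, n). Unassigned genes
#' (module 0) contribute their orthogroups to N but form no module.
#'
#' P-values are raw by default; `adjust = TRUE` adds a Benjamini-Hochberg
#' column across all pairs.
#'
#' @param part_a,part_b Module partitions of the two species.
#' @param table Long orthogroup tibble (apply [filter_min_species()]
#'   upstream).
#' @param species_a,species_b Species names matching `table`.
#' @param adjust Add a `p_bh` column (default FALSE).
#' @return An object of class `overlap_result`: tibble with `module_a`,
#'   `module_b`, `K`, `n`, `x`, `N`, `p_raw` (and `p_bh` if requested) and a
#'   list-column `shared` of shared orthogroup ids; species names and the
#'   universe are carried as attributes.
#' @export
overlap_matrix <- function(part_a, part_b, table, species_a, species_b,
                           adjust = FALSE) {
  map_a <- module_to_orthogroups(part_a, table, species_a)
  map_b <- module_to_orthogroups(part_b, table, species_b)
  universe <- intersect(unique(map_a$orthogroup), unique(map_b$orthogroup))
  if (length(universe) == 0) {
    stop("empty universe: no orthogroup has analysed genes in both species")
  }
  N <- length(universe)
  sets_a <- split(map_a$orthogroup, map_a$module)
  sets_b <- split(map_b$orthogroup, map_b$module)
  sets_a <- lapply(sets_a[names(sets_a) != "0"], intersect, y = universe)
  sets_b <- lapply(sets_b[names(sets_b) != "0"], intersect, y = universe)

  grid <- tidyr::expand_grid(module_a = names(sets_a), module_b = names(sets_b))
  rows <- purrr::pmap(grid, function(module_a, module_b) {
    oa <- sets_a[[module_a]]
    ob <- sets_b[[module_b]]
    shared <- intersect(oa, ob)
    tibble(
      module_a = as.integer(module_a), module_b = as.integer(module_b),
      K = length(oa), n = length(ob), x = length(shared), N = N,
      p_raw = hypergeom_upper_tail(length(shared), N, length(oa), length(ob)),
      shared = list(shared)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (adjust) out$p_bh <- benjamini_hochberg(out$p_raw)
  structure(out,
            class = c("overlap_result", class(out)),
            species_a = species_a, species_b = species_b,
            universe = universe)
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("Cross-species module overlap: ",
      attr(x, "species_a"), " x ", attr(x, "species_b"),
      " (universe N = ", x$N[1], " orthogroups)\n", sep = "")
  NextMethod()
}

#' Overlap result as a matrix
#' @param x An `overlap_result`.
#' @param what Which quantity to spread: `"p_raw"`, `"x"`, or
#'   `"neglog10_p"`.
#' @param ... Unused.
#' @return Matrix with species-A modules in rows, species-B in columns.
#' @export
as.matrix.overlap_result <- function(x, what = c("p_raw", "x", "neglog10_p"), ...) {
  what <- match.arg(what)
  v <- if (what == "neglog10_p") -log10(pmax(x$p_raw, 1e-300)) else x[[what]]
  mods_a <- sort(unique(x$module_a))
  mods_b <- sort(unique(x$module_b))
  m <- matrix(NA_real_, length(mods_a), length(mods_b),
              dimnames = list(paste0("A", mods_a), paste0("B", mods_b)))
  m[cbind(match(x$module_a, mods_a), match(x$module_b, mods_b))] <- v
  m
}

#' Tidy an overlap result
#' @param x An `overlap_result`.
#' @param ... Unused.
#' @return The underlying long tibble without the list-column.
#' @method tidy overlap_result
#' @export
tidy.overlap_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$shared <- NULL
  out
}

#' One-row summary of an overlap result
#' @param x An `overlap_result`.
#' @param ... Unused.
#' @method glance overlap_result
#' @export
glance.overlap_result <- function(x, ...) {
  tibble(
    species_a = attr(x, "species_a"),
    species_b = attr(x, "species_b"),
    n_modules_a = dplyr::n_distinct(x$module_a),
    n_modules_b = dplyr::n_distinct(x$module_b),
    universe = x$N[1],
    min_p = min(x$p_raw),
    n_pairs_p_lt_1e6 = sum(x$p_raw < 1e-6)
  )
}

#' Conserved core gene families of a module pair
#'
#' The shared orthogroups of two mapped modules, expanded back to the member
#' genes of each species. Because families may have expanded differently in
#' each lineage, the per-species gene counts can exceed (and differ from)
#' the number of shared families.
#'
#' @param orthogroups_a,orthogroups_b Character vectors of orthogroup ids
#'   (one module's set per species, e.g. from [module_to_orthogroups()]).
#' @param table Long orthogroup tibble.
#' @param species Optional character vector restricting the gene expansion
#'   to these species (default: all species in `table`).
#' @return List with `orthogroups` (shared ids) and `genes` (tibble
#'   `orthogroup`, `species`, `gene_id` for the shared families).
#' @export
conserved_core <- function(orthogroups_a, orthogroups_b, table, species = NULL) {
  shared <- intersect(orthogroups_a, orthogroups_b)
  genes <- dplyr::filter(table, .data$orthogroup %in% shared)
  if (!is.null(species)) {
    genes <- dplyr::filter(genes, .data$species %in% !!species)
  }
  list(orthogroups = sort(shared),
       genes = dplyr::arrange(genes, .data$orthogroup, .data$species, .data$gene_id))
}
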