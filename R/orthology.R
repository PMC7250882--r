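#' Read an orthogroup table (OrthoFinder `Orthogroups.tsv` dialect)
#'
#' The file has an orthogroup-ID first column, one column per species, and
#' cells holding comma-space separated gene lists (empty cells allowed).
#'
#' @param path Path to the TSV.
#' @return Long tibble with columns `orthogroup`, `species`, `gene_id`, one
#'   row per gene. A gene appearing in more than one orthogroup is an error.
#' @export
read_orthogroups <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = "c"))
  if (ncol(x) < 2) stop("orthogroup table needs an ID column plus species columns")
  names(x)[1] <- "orthogroup"
  long <- tidyr::pivot_longer(x, -"orthogroup",
                              names_to = "species", values_to = "genes")
  long <- dplyr::filter(long, !is.na(.data$genes), .data$genes != "")
  long <- tidyr::separate_rows(long, "genes", sep = ",[ ]?")
  long <- dplyr::rename(long, gene_id = "genes")
  long <- dplyr::filter(long, .data$gene_id != "")
  validate_orthogroups(long)
}

validate_orthogroups <- function(tbl) {
  stopifnot(all(c("orthogroup", "species", "gene_id") %in% names(tbl)))
  per_gene <- dplyr::distinct(tbl, .data$gene_id, .data$orthogroup)
  dup <- per_gene$gene_id[duplicated(per_gene$gene_id)]
  if (length(dup) > 0) {
    stop("gene(s) assigned to more than one orthogroup: ",
         paste(utils::head(unique(dup), 5), collapse = ", "))
  }
  tibble::as_tibble(dplyr::distinct(tbl))
}

#' Write an orthogroup table in the OrthoFinder dialect
#' @param tbl Long orthogroup tibble (`orthogroup`, `species`, `gene_id`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(tbl, path) {
  wide <- dplyr::summarise(
    dplyr::group_by(tbl, .data$orthogroup, .data$species),
    genes = paste(.data$gene_id, collapse = ", "), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(wide, names_from = "species",
                             values_from = "genes", values_fill = "")
  wide <- dplyr::arrange(wide, .data$orthogroup)
  names(wide)[1] <- "Orthogroup"
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Keep orthogroups present in at least k species
#'
#' The cross-species analyses are restricted to gene families reconstructed
#' in two or more species; lineage-restricted singletons carry no
#' comparative signal for module overlap.
#'
#' @param tbl Long orthogroup tibble.
#' @param k Minimum number of species with at least one member (default 2).
#' @return Filtered tibble.
#' @export
filter_min_species <- function(tbl, k = 2) {
  stopifnot(k >= 1)
  counts <- dplyr::summarise(
    dplyr::group_by(tbl, .data$orthogroup),
    n_species = dplyr::n_distinct(.data$species), .groups = "drop"
  )
  keep <- counts$orthogroup[counts$n_species >= k]
  dplyr::filter(tbl, .data$orthogroup %in% keep)
}

# root-to-focal node path (internal nodes then the focal tip)
lineage_path <- function(tree, focal) {
  tip <- match(focal, tree$tip.label)
  if (is.na(tip)) stop("focal species '", focal, "' is not a tip of the tree")
  root <- length(tree$tip.label) + 1L
  ape::nodepath(tree, from = root, to = tip)
}

node_label <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) {
    tree$tip.label[node]
  } else if (!is.null(tree$node.label) && nzchar(tree$node.label[node - ntip])) {
    tree$node.label[node - ntip]
  } else {
    paste0("node_", node)
  }
}

# MRCA of a set of tips; a single tip is its own MRCA
mrca_node <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) {
    stop("species not in tree: ", paste(tips[is.na(idx)], collapse = ", "))
  }
  if (length(unique(idx)) == 1) unique(idx) else ape::getMRCA(tree, unique(idx))
}

#' Assign phylostrata to the focal species' genes
#'
#' A gene's phylostratum is the node on the root-to-focal path at which its
#' family first appears: the most recent common ancestor of the focal
#' species and every species with a member in the gene's orthogroup.
#' Stratum 1 is the root (oldest); the last stratum S is the focal leaf
#' (species-specific). Genes outside any orthogroup, or in focal-only
#' orthogroups, are species-specific.
#'
#' @param tbl Long orthogroup tibble.
#' @param tree Rooted `phylo` tree whose tips cover every species in `tbl`.
#' @param focal Focal species (a tip label).
#' @param genes Optional character vector of focal-species genes to assign;
#'   defaults to the focal genes in `tbl`. Genes listed here but absent from
#'   the table are assigned the species-specific stratum.
#' @return Tibble with `gene_id`, `orthogroup` (NA if none), `stratum`
#'   (integer, 1 = root), `node_label`; the root-to-focal node labels are
#'   attached as attribute `"lineage"`.
#' @export
assign_phylostrata <- function(tbl, tree, focal, genes = NULL) {
  tbl <- validate_orthogroups(tbl)
  path <- lineage_path(tree, focal)
  S <- length(path)
  labels <- vapply(path, function(nd) node_label(tree, nd), character(1))

  focal_tbl <- dplyr::filter(tbl, .data$species == focal)
  if (is.null(genes)) genes <- focal_tbl$gene_id
  og_species <- dplyr::summarise(
    dplyr::group_by(tbl, .data$orthogroup),
    species = list(unique(.data$species)), .groups = "drop"
  )
  og_stratum <- vapply(og_species$species, function(sp) {
    nd <- mrca_node(tree, unique(c(focal, sp)))
    idx <- match(nd, path)
    if (is.na(idx)) S else idx # off-path MRCA cannot occur when focal included
  }, integer(1))
  names(og_stratum) <- og_species$orthogroup

  og_of <- focal_tbl$orthogroup[match(genes, focal_tbl$gene_id)]
  stratum <- ifelse(is.na(og_of), S, og_stratum[og_of])
  out <- tibble(
    gene_id = genes,
    orthogroup = og_of,
    stratum = as.integer(stratum),
    node_label = labels[stratum]
  )
  attr(out, "lineage") <- labels
  out
}

#' Per-node gene-family gains and core gains
#'
#' A family (orthogroup) is gained at the most recent common ancestor of the
#' species in which it is found; every orthogroup is counted exactly once,
#' so gains partition the table across nodes. A gain is a *core* gain when
#' the family is present in every sampled leaf descending from its origin
#' node — i.e. no sampled descendant has lost it.
#'
#' @param tbl Long orthogroup tibble.
#' @param tree Rooted `phylo` tree covering the table's species.
#' @return Tibble over all tree nodes with `node`, `node_label`,
#'   `n_descendant_species`, `gains`, `core_gains`.
#' @export
count_gains <- function(tbl, tree) {
  tbl <- validate_orthogroups(tbl)
  ntip <- length(tree$tip.label)
  all_nodes <- seq_len(ntip + tree$Nnode)
  # descendant tip sets per node
  desc <- lapply(all_nodes, function(nd) {
    if (nd <= ntip) tree$tip.label[nd]
    else ape::extract.clade(tree, nd)$tip.label
  })

  og_species <- dplyr::summarise(
    dplyr::group_by(tbl, .data$orthogroup),
    species = list(unique(.data$species)), .groups = "drop"
  )
  origin <- vapply(og_species$species, function(sp) {
    mrca_node(tree, sp)
  }, integer(1))
  core <- vapply(seq_along(origin), function(i) {
    all(desc[[origin[i]]] %in% og_species$species[[i]])
  }, logical(1))

  gains <- tabulate(origin, nbins = length(all_nodes))
  core_gains <- tabulate(origin[core], nbins = length(all_nodes))
  tibble(
    node = all_nodes,
    node_label = vapply(all_nodes, function(nd) node_label(tree, nd), character(1)),
    n_descendant_species = lengths(desc),
    gains = gains,
    core_gains = core_gains
  )
}
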