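#' Default planted co-expression modules
#'
#' Four module pairs of 40 genes each, orthologous fraction 0.8, with a
#' two-log-unit expression boost at the peak tissue(s). One module peaks
#' jointly in wing pads and gills, emulating a co-expression programme
#' shared by two organs; the others peak in single tissues.
#'
#' @return Tibble with `module`, `size`, `peak` (list-column of condition
#'   labels), `phi`, `mu_eff`.
#' @export
default_planted_modules <- function() {
  tibble(
    module = 1:4,
    size = 40L,
    peak = list("gut", "brain", "muscle", c("wing_pad", "gill")),
    phi = 0.8,
    mu_eff = 2
  )
}

#' Simulation configuration
#'
#' Describes a multi-species bulk expression experiment with planted
#' structure: a species tree, orthogroups with tree-node origins, planted
#' co-expression module pairs shared across the first two species through
#' orthology, planted strictly tissue-specific genes, log-normal baselines,
#' log-scale Gaussian replicate noise, and Poisson (optionally
#' negative-binomial) count sampling at a fixed library size.
#'
#' @param seed Integer seed driving every random draw.
#' @param species Species identifiers (>= 2); gene ids are namespaced by
#'   species (`spA_g0001`).
#' @param tree Newick string over `species`; default is a ladder topology.
#' @param n_orthogroups Number of gene families to simulate.
#' @param p_root Probability that a family originates at the root; the
#'   remainder is split over non-root nodes in proportion to their
#'   descendant leaf counts.
#' @param retention_prob Probability that a family is retained in each
#'   descendant species of its origin node (1 = loss-free).
#' @param p_single_copy Fraction of families kept at one gene per present
#'   species; the rest gain Poisson-distributed extra copies.
#' @param tissues Ordered condition labels (>= 2).
#' @param n_replicates Replicates per condition (>= 1).
#' @param planted_modules Tibble as in [default_planted_modules()]; `phi`
#'   is the fraction of each module's genes whose orthogroup is also in the
#'   partner species' module.
#' @param planted_specific Tibble with `n_genes`, `tissue`: genes expressed
#'   *only* in the target tissue (zero elsewhere), planted per species.
#' @param noise_sd Log-scale Gaussian replicate noise (>= 0).
#' @param baseline_meanlog,baseline_sdlog Per-gene log-normal baseline.
#' @param library_size Mapped reads per sample.
#' @param dispersion Negative-binomial overdispersion; 0 = Poisson.
#' @param length_meanlog,length_sdlog Log-normal effective gene length (kb).
#' @param specific_up Log-scale boost of specific genes in their tissue.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              species = c("spA", "spB"),
                              tree = NULL,
                              n_orthogroups = 350L,
                              p_root = 0.7,
                              retention_prob = 1,
                              p_single_copy = 0.9,
                              tissues = c("embryo", "gill", "wing_pad", "gut",
                                          "brain", "muscle", "head", "ovary"),
                              n_replicates = 2L,
                              planted_modules = default_planted_modules(),
                              planted_specific = tibble(n_genes = 15L, tissue = "head"),
                              noise_sd = 0.3,
                              baseline_meanlog = 3,
                              baseline_sdlog = 1,
                              library_size = 5e5,
                              dispersion = 0,
                              length_meanlog = log(1.5),
                              length_sdlog = 0.4,
                              specific_up = 2) {
  if (is.null(tree)) tree <- ladder_newick(species)
  cfg <- list(
    seed = as.integer(seed), species = species, tree = tree,
    n_orthogroups = as.integer(n_orthogroups), p_root = p_root,
    retention_prob = retention_prob, p_single_copy = p_single_copy,
    tissues = tissues, n_replicates = as.integer(n_replicates),
    planted_modules = planted_modules, planted_specific = planted_specific,
    noise_sd = noise_sd, baseline_meanlog = baseline_meanlog,
    baseline_sdlog = baseline_sdlog, library_size = library_size,
    dispersion = dispersion, length_meanlog = length_meanlog,
    length_sdlog = length_sdlog, specific_up = specific_up
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

ladder_newick <- function(species) {
  stopifnot(length(species) >= 2)
  nwk <- paste0("(", species[1], ",", species[2], ")")
  for (sp in species[-(1:2)]) nwk <- paste0("(", nwk, ",", sp, ")")
  paste0(nwk, ";")
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      length(species) >= 2, n_orthogroups > 0, n_replicates >= 1,
      length(tissues) >= 2, library_size > 0,
      p_root >= 0, p_root <= 1,
      retention_prob >= 0, retention_prob <= 1,
      p_single_copy >= 0, p_single_copy <= 1,
      noise_sd >= 0, dispersion >= 0
    )
    if (nrow(planted_modules) > 0) {
      stopifnot(all(planted_modules$phi >= 0), all(planted_modules$phi <= 1),
                all(planted_modules$size > 0))
      peaks <- unlist(planted_modules$peak)
      if (!all(peaks %in% tissues)) {
        stop("planted module peak condition(s) not among tissues: ",
             paste(setdiff(peaks, tissues), collapse = ", "))
      }
      if (sum(planted_modules$size) + sum(planted_specific$n_genes) > n_orthogroups) {
        stop("sizing error: planted module and specific genes exceed the ",
             "number of orthogroups available")
      }
    }
    if (nrow(planted_specific) > 0 &&
        !all(planted_specific$tissue %in% tissues)) {
      stop("planted specific tissue(s) not among tissues")
    }
  })
  invisible(cfg)
}

#' Simulate a multi-species expression dataset with planted truth
#'
#' Draws the orthogroup scaffold (origin nodes, per-species retention, copy
#' numbers), plants the configured module pairs and tissue-specific genes,
#' and generates per-species count matrices: expression is
#' `exp(baseline + module effect + N(0, noise_sd^2))` per replicate,
#' converted to integer counts by Poisson thinning of each sample to the
#' configured library size (negative binomial when `dispersion > 0`).
#' Planted module pairs share `phi` of their orthogroups between the first
#' two species; planted specific genes are expressed only in their target
#' tissue.
#'
#' @param config A [simulation_config()].
#' @return List with `expression` (named list of count tibbles per
#'   species), `metadata` (sample metadata tibble, shared design),
#'   `lengths` (named list of `gene_id`/`length_kb` tibbles), `orthogroups`
#'   (long tibble), `tree` (`phylo`), `truth` (list of tibbles: `genes`,
#'   `orthogroups`, `module_pairs`), and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  validate_simulation_config(config)
  set.seed(config$seed)
  tree <- ape::read.tree(text = config$tree)
  if (!setequal(tree$tip.label, config$species)) {
    stop("tree tips must match the configured species")
  }
  ntip <- length(tree$tip.label)
  all_nodes <- seq_len(ntip + tree$Nnode)
  root <- ntip + 1L
  desc <- lapply(all_nodes, function(nd) {
    if (nd <= ntip) tree$tip.label[nd] else ape::extract.clade(tree, nd)$tip.label
  })

  # --- orthogroup scaffold -------------------------------------------------
  w <- lengths(desc)
  w[root] <- 0
  w <- if (sum(w) > 0) (1 - config$p_root) * w / sum(w) else w
  w[root] <- if (sum(w) == 0) 1 else config$p_root
  og_ids <- sprintf("OG%04d", seq_len(config$n_orthogroups))
  origin <- sample(all_nodes, config$n_orthogroups, replace = TRUE, prob = w)
  presence <- lapply(origin, function(nd) {
    leaves <- desc[[nd]]
    kept <- leaves[stats::runif(length(leaves)) <= config$retention_prob]
    if (length(kept) == 0) kept <- sample(leaves, 1)
    kept
  })
  single <- stats::runif(config$n_orthogroups) <= config$p_single_copy

  rows <- vector("list", config$n_orthogroups)
  counters <- stats::setNames(integer(length(config$species)), config$species)
  for (i in seq_len(config$n_orthogroups)) {
    sp_rows <- lapply(presence[[i]], function(sp) {
      n_copies <- if (single[i]) 1L else 1L + stats::rpois(1, 0.7)
      ids <- sprintf("%s_g%04d", sp, counters[sp] + seq_len(n_copies))
      counters[sp] <<- counters[sp] + n_copies
      tibble(orthogroup = og_ids[i], species = sp, gene_id = ids)
    })
    rows[[i]] <- dplyr::bind_rows(sp_rows)
  }
  orthogroups <- dplyr::bind_rows(rows)

  # --- plant modules across the first two species --------------------------
  sp_a <- config$species[1]
  sp_b <- config$species[2]
  genes_of <- function(sp) orthogroups$gene_id[orthogroups$species == sp]
  truth_genes <- dplyr::mutate(orthogroups, module = NA_integer_,
                               specific_tissue = NA_character_)

  # single-copy orthogroups present in both partner species, unused so far
  og_wide <- dplyr::summarise(
    dplyr::group_by(orthogroups, .data$orthogroup, .data$species),
    n = dplyr::n(), .groups = "drop"
  )
  in_both_single <- function(used) {
    tab <- dplyr::filter(og_wide, .data$species %in% c(sp_a, sp_b), .data$n == 1)
    counts <- table(tab$orthogroup)
    setdiff(names(counts)[counts == 2], used)
  }

  used_ogs <- character(0)
  assigned <- stats::setNames(
    lapply(config$species, function(sp) character(0)), config$species)
  pm <- config$planted_modules
  for (i in seq_len(nrow(pm))) {
    size <- pm$size[i]
    n_shared <- round(pm$phi[i] * size)
    pool <- in_both_single(used_ogs)
    if (length(pool) < n_shared) {
      stop("sizing error: not enough shared single-copy orthogroups to plant ",
           "module ", pm$module[i])
    }
    shared_ogs <- sample(pool, n_shared)
    used_ogs <- c(used_ogs, shared_ogs)
    for (sp in c(sp_a, sp_b)) {
      core_genes <- orthogroups$gene_id[
        orthogroups$orthogroup %in% shared_ogs & orthogroups$species == sp]
      n_fill <- size - n_shared
      free <- orthogroups$gene_id[
        orthogroups$species == sp &
          !(orthogroups$gene_id %in% assigned[[sp]]) &
          !(orthogroups$orthogroup %in% used_ogs)]
      if (length(free) < n_fill) {
        stop("sizing error: species ", sp, " has too few free genes for ",
             "module ", pm$module[i])
      }
      fill_genes <- if (n_fill > 0) sample(free, n_fill) else character(0)
      fill_ogs <- orthogroups$orthogroup[match(fill_genes, orthogroups$gene_id)]
      used_ogs <- c(used_ogs, fill_ogs)
      members <- c(core_genes, fill_genes)
      assigned[[sp]] <- c(assigned[[sp]], members)
      truth_genes$module[truth_genes$gene_id %in% members &
                           truth_genes$species == sp] <- pm$module[i]
    }
  }

  # --- plant tissue-specific genes (every species) -------------------------
  ps <- config$planted_specific
  for (sp in config$species) {
    for (j in seq_len(nrow(ps))) {
      free <- setdiff(genes_of(sp), assigned[[sp]])
      if (length(free) < ps$n_genes[j]) {
        stop("sizing error: species ", sp, " has too few free genes for ",
             "planted specific set ", j)
      }
      chosen <- sample(free, ps$n_genes[j])
      assigned[[sp]] <- c(assigned[[sp]], chosen)
      truth_genes$specific_tissue[truth_genes$gene_id %in% chosen &
                                    truth_genes$species == sp] <- ps$tissue[j]
    }
  }

  # --- expression and counts ----------------------------------------------
  samples <- as.vector(t(outer(config$tissues, seq_len(config$n_replicates),
                               paste, sep = ".")))
  metadata <- parse_sample_metadata(samples)
  cond_of <- metadata$condition

  expression <- list()
  lengths_out <- list()
  for (sp in config$species) {
    genes <- genes_of(sp)
    ng <- length(genes)
    len_kb <- stats::rlnorm(ng, config$length_meanlog, config$length_sdlog)
    baseline <- stats::rnorm(ng, config$baseline_meanlog, config$baseline_sdlog)
    log_mu <- matrix(baseline, ng, length(config$tissues),
                     dimnames = list(genes, config$tissues))
    sp_truth <- truth_genes[truth_genes$species == sp, ]
    for (i in seq_len(nrow(pm))) {
      members <- sp_truth$gene_id[!is.na(sp_truth$module) &
                                    sp_truth$module == pm$module[i]]
      log_mu[members, pm$peak[[i]]] <-
        log_mu[members, pm$peak[[i]], drop = FALSE] + pm$mu_eff[i]
    }
    for (j in seq_len(nrow(ps))) {
      members <- sp_truth$gene_id[!is.na(sp_truth$specific_tissue) &
                                    sp_truth$specific_tissue == ps$tissue[j]]
      off <- setdiff(config$tissues, ps$tissue[j])
      log_mu[members, ps$tissue[j]] <-
        log_mu[members, ps$tissue[j]] + config$specific_up
      log_mu[members, off] <- -Inf # expressed only in the target tissue
    }
    noise <- matrix(stats::rnorm(ng * length(samples), 0, config$noise_sd),
                    ng, length(samples))
    expr <- exp(log_mu[, cond_of, drop = FALSE] + noise)
    counts <- matrix(0L, ng, length(samples), dimnames = list(genes, samples))
    for (s in seq_along(samples)) {
      wgt <- expr[, s] * len_kb
      lambda <- config$library_size * wgt / sum(wgt)
      counts[, s] <- if (config$dispersion > 0) {
        stats::rnbinom(ng, mu = lambda, size = 1 / config$dispersion)
      } else {
        stats::rpois(ng, lambda)
      }
    }
    expression[[sp]] <- expression_table(counts, unit = "counts")
    lengths_out[[sp]] <- tibble(gene_id = genes, length_kb = len_kb)
  }

  n_mod <- nrow(pm)
  module_pairs <- tidyr::expand_grid(module_a = pm$module, module_b = pm$module)
  module_pairs$partner <- module_pairs$module_a == module_pairs$module_b

  list(
    expression = expression,
    metadata = metadata,
    lengths = lengths_out,
    orthogroups = orthogroups,
    tree = tree,
    truth = list(
      genes = truth_genes,
      orthogroups = tibble(
        orthogroup = og_ids,
        origin_node = vapply(origin, function(nd) node_label(tree, nd),
                             character(1)),
        origin_node_id = origin
      ),
      module_pairs = module_pairs
    ),
    config = config
  )
}

#' Simulate a developmental time course with planted temporal clusters
#'
#' Each true cluster's genes share a Gaussian activation bump (on the log
#' scale) centred on one stage, with peak stages spread along the stage
#' axis; replicate-free expression values are returned directly in
#' normalized units.
#'
#' @param stages Ordered stage labels (>= 3).
#' @param n_clusters Number of temporal clusters (>= 2 and at most the
#'   number of stages, so peaks stay distinct).
#' @param genes_per_cluster Genes per cluster.
#' @param noise_sd Log-scale Gaussian noise.
#' @param seed Integer seed.
#' @param amplitude Height of the activation bump in log units (default 2).
#' @return List with `expression` (tibble, unit `"crpkm"`) and `truth`
#'   (tibble `gene_id`, `cluster`).
#' @export
simulate_timecourse <- function(stages, n_clusters, genes_per_cluster,
                                noise_sd = 0.2, seed = 1, amplitude = 2) {
  S <- length(stages)
  if (S < 3) stop("simulate_timecourse needs at least three stages")
  if (n_clusters < 2) stop("simulate_timecourse needs at least two clusters")
  if (n_clusters > S) {
    stop("more clusters than stages: no distinct peak stages available")
  }
  set.seed(seed)
  peaks <- round(seq(1, S, length.out = n_clusters))
  if (anyDuplicated(peaks)) peaks <- seq_len(n_clusters)
  ng <- n_clusters * genes_per_cluster
  cluster <- rep(seq_len(n_clusters), each = genes_per_cluster)
  genes <- sprintf("g%04d", seq_len(ng))
  log_mu <- amplitude *
    exp(-0.5 * outer(peaks[cluster], seq_len(S), "-")^2)
  noise <- matrix(stats::rnorm(ng * S, 0, noise_sd), ng, S)
  vals <- 50 * exp(log_mu + noise)
  dimnames(vals) <- list(genes, stages)
  list(
    expression = expression_table(vals, unit = "crpkm"),
    truth = tibble(gene_id = genes, cluster = cluster)
  )
}

#' Write a simulated dataset to a fixture directory
#'
#' Emits, under `directory`: one count TSV and one gene-length TSV per
#' species, the shared sample metadata TSV, the orthogroup table in the
#' OrthoFinder dialect, the species tree in Newick, a GMT file whose terms
#' are the planted module labels, and the ground-truth TSVs. Everything
#' round-trips through [read_expression_tsv()], [read_orthogroups()],
#' [ape::read.tree()] and [read_gmt()].
#'
#' @param dataset Result of [simulate_dataset()].
#' @param directory Output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(dataset, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) {
    stop("cannot create fixture directory: ", directory)
  }
  paths <- c()
  for (sp in names(dataset$expression)) {
    p <- file.path(directory, paste0("expression_", sp, ".tsv"))
    write_expression_tsv(dataset$expression[[sp]], p)
    paths[paste0("expression_", sp)] <- p
    pl <- file.path(directory, paste0("lengths_", sp, ".tsv"))
    readr::write_tsv(dataset$lengths[[sp]], pl, progress = FALSE)
    paths[paste0("lengths_", sp)] <- pl
  }
  paths["metadata"] <- file.path(directory, "metadata.tsv")
  readr::write_tsv(dataset$metadata, paths["metadata"], progress = FALSE)
  paths["orthogroups"] <- file.path(directory, "Orthogroups.tsv")
  write_orthogroups(dataset$orthogroups, paths["orthogroups"])
  paths["tree"] <- file.path(directory, "tree.nwk")
  ape::write.tree(dataset$tree, file = paths["tree"])
  tg <- dataset$truth$genes
  planted <- tg[!is.na(tg$module), ]
  sets <- split(planted$gene_id, paste0("module_", planted$module))
  paths["modules_gmt"] <- file.path(directory, "modules.gmt")
  write_gmt(sets, paths["modules_gmt"],
            descriptions = rep("planted co-expression module", length(sets)))
  paths["truth_genes"] <- file.path(directory, "truth_genes.tsv")
  readr::write_tsv(tg, paths["truth_genes"], progress = FALSE)
  paths["truth_orthogroups"] <- file.path(directory, "truth_orthogroups.tsv")
  readr::write_tsv(dataset$truth$orthogroups, paths["truth_orthogroups"],
                   progress = FALSE)
  paths["truth_module_pairs"] <- file.path(directory, "truth_module_pairs.tsv")
  readr::write_tsv(dataset$truth$module_pairs, paths["truth_module_pairs"],
                   progress = FALSE)
  invisible(paths)
}
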