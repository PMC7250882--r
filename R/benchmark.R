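#' Planted-truth recovery benchmark
#'
#' Runs the full comparative pipeline on freshly simulated two-species
#' datasets under the default benchmark conditions (about 300 genes per
#' species, 8 conditions with 2 replicates, 4 planted module pairs of 40
#' genes at orthologous fraction 0.8, log-noise 0.3) and scores recovery
#' against the generator's ground truth, one row per seed:
#'
#' * `fcm_ari` — adjusted Rand index of fuzzy c-means hard assignments vs
#'   planted module labels over the planted genes analysed after the
#'   coefficient-of-variation filter (clustered together with the planted
#'   specific genes, hence one extra centre);
#' * `module_ari_a`, `module_ari_b` — adjusted Rand index of detected
#'   co-expression modules vs planted modules, per species;
#' * `pairs_ok` — TRUE when every planted module pair attains the row and
#'   column minimum of the cross-species overlap p matrix with p < 1e-6;
#' * `max_pair_p` — largest (worst) overlap p among the planted pairs;
#' * `median_nonpartner_p` — median overlap p over non-partner pairs of
#'   planted modules (should look null);
#' * `tau_recovery` — fraction of planted tissue-specific genes with
#'   tau > 0.8;
#' * `siblings` — whether the sample dendrogram joins the two tissues that
#'   share a planted co-expression programme (wing pads and gills) as
#'   siblings.
#'
#' @param seeds Integer vector of simulation seeds (one dataset each).
#' @param config_fn Function mapping a seed to a [simulation_config()];
#'   defaults to the benchmark conditions.
#' @param beta Soft-threshold power for module detection (default 6).
#' @return Tibble with one row per seed and the columns above.
#' @export
recovery_benchmark <- function(seeds = 1:10,
                               config_fn = function(s) simulation_config(seed = s),
                               beta = 6) {
  purrr::map_dfr(seeds, function(s) {
    d <- simulate_dataset(config_fn(s))
    truth <- d$truth$genes
    sp_a <- d$config$species[1]
    sp_b <- d$config$species[2]
    planted_ids <- sort(unique(truth$module[!is.na(truth$module)]))

    crpkm <- lapply(names(d$expression), function(sp) {
      compute_crpkm(d$expression[[sp]], d$lengths[[sp]])
    })
    names(crpkm) <- names(d$expression)

    # module detection per species on per-sample cRPKM
    parts <- lapply(c(sp_a, sp_b), function(sp) {
      detect_modules(tom_similarity(adjacency(crpkm[[sp]], beta = beta)),
                     species = sp)
    })
    names(parts) <- c(sp_a, sp_b)
    module_ari <- vapply(c(sp_a, sp_b), function(sp) {
      tg <- dplyr::filter(truth, .data$species == sp, !is.na(.data$module))
      j <- dplyr::inner_join(tg, parts[[sp]], by = "gene_id")
      mclust::adjustedRandIndex(j$module.x, j$module.y)
    }, numeric(1))

    # soft clustering of condition-averaged, variance-filtered profiles;
    # one centre per planted class (4 modules + 1 specific programme)
    av <- average_replicates(crpkm[[sp_a]], d$metadata)
    st <- standardize_genes(filter_by_cv(av, 1))
    n_classes <- length(planted_ids) +
      as.integer(nrow(d$config$planted_specific) > 0)
    soft <- fuzzy_cmeans(st, c = max(2, n_classes), seed = s + 1000)
    hard <- assign_clusters(soft)
    tg_a <- dplyr::filter(truth, .data$species == sp_a, !is.na(.data$module))
    j <- dplyr::inner_join(tg_a, hard, by = "gene_id")
    fcm_ari <- mclust::adjustedRandIndex(j$module, j$cluster)

    # cross-species overlap of detected modules
    og <- filter_min_species(d$orthogroups, 2)
    ov <- suppressMessages(
      overlap_matrix(parts[[sp_a]], parts[[sp_b]], og, sp_a, sp_b))
    pm <- as.matrix(ov, "p_raw")
    detected_label <- function(sp, planted) {
      tg <- dplyr::filter(truth, .data$species == sp, .data$module == planted)
      jj <- dplyr::inner_join(tg, parts[[sp]], by = "gene_id")
      jj <- dplyr::filter(jj, .data$module.y != 0)
      if (nrow(jj) == 0) return(NA_integer_)
      tab <- table(jj$module.y)
      as.integer(names(tab)[which.max(tab)])
    }
    la <- vapply(planted_ids, detected_label, integer(1), sp = sp_a)
    lb <- vapply(planted_ids, detected_label, integer(1), sp = sp_b)
    pair_p <- rep(NA_real_, length(planted_ids))
    pair_ok <- rep(FALSE, length(planted_ids))
    for (i in seq_along(planted_ids)) {
      if (is.na(la[i]) || is.na(lb[i])) next
      ra <- paste0("A", la[i])
      cb <- paste0("B", lb[i])
      p <- pm[ra, cb]
      pair_p[i] <- p
      pair_ok[i] <- p < 1e-6 && p <= min(pm[ra, ]) && p <= min(pm[, cb])
    }
    nonpartner <- c()
    for (i in seq_along(planted_ids)) {
      for (k in seq_along(planted_ids)) {
        if (i != k && !is.na(la[i]) && !is.na(lb[k])) {
          nonpartner <- c(nonpartner, pm[paste0("A", la[i]), paste0("B", lb[k])])
        }
      }
    }

    # tau recovery of planted specific genes
    spec <- dplyr::filter(truth, .data$species == sp_a,
                          !is.na(.data$specific_tissue))
    tt <- tau_table(av)
    tau_rec <- mean(tt$tau[match(spec$gene_id, tt$gene_id)] > 0.8, na.rm = TRUE)

    # sibling check on the condition dendrogram
    two_peak <- d$config$planted_modules$peak[
      lengths(d$config$planted_modules$peak) == 2]
    sib <- if (length(two_peak) > 0) {
      are_siblings(cluster_samples(av), two_peak[[1]][1], two_peak[[1]][2])
    } else NA
    tibble(
      seed = s,
      fcm_ari = fcm_ari,
      module_ari_a = module_ari[[1]],
      module_ari_b = module_ari[[2]],
      pairs_ok = all(pair_ok),
      max_pair_p = max(pair_p, na.rm = TRUE),
      median_nonpartner_p = stats::median(nonpartner),
      tau_recovery = tau_rec,
      siblings = sib
    )
  })
}
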