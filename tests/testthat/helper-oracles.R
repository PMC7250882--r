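# Independent enumeration oracles and small fixture builders used across
# the suite.

# upper-tail hypergeometric by direct summation of binomial coefficients
enum_hyper_upper <- function(x, N, K, n) {
  hi <- min(K, n)
  if (x > hi) return(0)
  i <- max(x, max(0, n + K - N)):hi
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# two-sided Fisher by enumerating the full support at fixed margins
enum_fisher_two_sided <- function(a, b, c, d) {
  N <- a + b + c + d
  if (N == 0) return(1)
  K <- a + b
  n <- a + c
  i <- max(0, n + K - N):min(K, n)
  probs <- choose(K, i) * choose(N - K, n - i) / choose(N, n)
  sum(probs[probs <= probs[match(a, i)] * (1 + 1e-7)])
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# draw one element from a vector, robust to length-one vectors (base
# sample() would expand a scalar v into 1:v)
sample1 <- function(v) v[sample.int(length(v), 1)]

# expression table from a bare matrix with auto gene/sample names
expr_mat <- function(values, unit = "crpkm",
                     genes = sprintf("g%03d", seq_len(nrow(values))),
                     samples = sprintf("s%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, samples)
  expression_table(values, unit = unit)
}

# coexpr_graph wrapper around a raw symmetric adjacency (for TOM and
# scale-free unit tests that specify the adjacency directly)
graph_from_adjacency <- function(a) {
  if (is.null(dimnames(a))) {
    dimnames(a) <- list(paste0("g", seq_len(nrow(a))),
                        paste0("g", seq_len(nrow(a))))
  }
  structure(
    list(adjacency = a, beta = NA_real_, signed = FALSE,
         genes = rownames(a), tom = NULL),
    class = "coexpr_graph"
  )
}

# small two-species simulation (fewer families than the default study
# conditions) for fast structural tests
small_config <- function(seed = 1, ...) {
  simulation_config(
    seed = seed,
    n_orthogroups = 150L,
    planted_modules = tibble::tibble(
      module = 1:2, size = 15L, peak = list("gut", c("wing_pad", "gill")),
      phi = 0.8, mu_eff = 2
    ),
    planted_specific = tibble::tibble(n_genes = 8L, tissue = "head"),
    ...
  )
}

no_modules <- function() default_planted_modules()[0, ]
no_specific <- function() tibble::tibble(n_genes = integer(), tissue = character())
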