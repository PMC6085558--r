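# Independently coded brute-force oracles and small fixture builders.
# The oracles deliberately avoid the package's own code paths.

# Median-of-ratios size factors, written naively: per-gene geometric mean
# via prod()^(1/n), reference genes those with positive geometric mean,
# per-sample factor the plain median of count/reference ratios.
oracle_size_factors <- function(counts) {
  geo <- apply(counts, 1L, function(r) prod(r)^(1 / length(r)))
  keep <- geo > 0
  vapply(seq_len(ncol(counts)), function(j) {
    median(counts[keep, j] / geo[keep])
  }, numeric(1))
}

# Two-group log-rank chi-square statistic from first principles: walk the
# distinct event times, accumulate observed and expected events in group 1
# and the hypergeometric variance.
oracle_logrank_chisq <- function(time, event, group) {
  group <- as.integer(factor(group))
  stopifnot(all(group %in% c(1L, 2L)))
  o1 <- e1 <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1L)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1L)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# Eight-subject worked example: two groups of four with staggered event
# times and one censored subject per group. Small enough to audit by hand.
logrank_example_8 <- function() {
  data.frame(
    time = c(1, 3, 5, 7, 2, 4, 6, 8),
    event = c(1, 1, 0, 1, 1, 1, 1, 0),
    group = rep(c("a", "b"), each = 4),
    stringsAsFactors = FALSE)
}

# Two well-separated Gaussian blobs with low-rank within-class structure:
# class offset along one direction, a few shared latent factors, and a
# small isotropic residual. Easy ground for the VAE / separator stages.
make_blobs <- function(n_per_class = 50, d = 30, sep = 3, noise = 0.1,
                       n_factors = 5, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  dir <- rep(c(1, -1), length.out = d) / sqrt(d)
  load <- matrix(rnorm(n_factors * d, sd = 2 / sqrt(d)), n_factors, d)
  x <- matrix(rnorm(n * n_factors), n, n_factors) %*% load +
    matrix(rnorm(n * d, sd = noise), n, d)
  x[seq_len(n_per_class), ] <-
    x[seq_len(n_per_class), ] + matrix(sep * dir, n_per_class, d,
                                       byrow = TRUE)
  x[-seq_len(n_per_class), ] <-
    x[-seq_len(n_per_class), ] - matrix(sep * dir, n_per_class, d,
                                        byrow = TRUE)
  rownames(x) <- sprintf("s%03d", seq_len(2 * n_per_class))
  colnames(x) <- sprintf("f%03d", seq_len(d))
  labels <- factor(rep(c("case", "control"), each = n_per_class),
                   levels = c("control", "case"))
  list(x = x, labels = labels)
}

# Small simulated cohort, normalized and transformed, with every sample in
# the training set (balanced classes so the split invariants hold).
make_small_cohort <- function(n_genes = 200, n_case = 30, n_control = 30,
                              n_signal = 5, effect = 2, seed = 1,
                              n_blocks = min(10L, n_genes %/% 20L), ...) {
  sim <- simulate_dataset(n_genes = n_genes, n_case = n_case,
                          n_control = n_control, n_signal = n_signal,
                          effect_log2fc = effect, seed = seed,
                          n_blocks = n_blocks, ...)
  norm <- normalize_counts(sim$matrix)
  split <- split_spec(sim$metadata$sample_id, character(), sim$metadata,
                      seed = seed)
  list(sim = sim, norm = norm, split = split,
       features = transform_features(norm, split),
       metadata = sim$metadata, truth = sim$truth)
}

# Cohort with more cases than controls plus simulated survival, ready for
# make_split() and the evaluation stage.
make_survival_cohort <- function(n_genes = 60, n_case = 120, n_control = 30,
                                 n_signal = 6, effect = 2, beta_scale = NULL,
                                 censor_rate = 0.2, seed = 1) {
  sim <- simulate_dataset(n_genes = n_genes, n_case = n_case,
                          n_control = n_control, n_signal = n_signal,
                          effect_log2fc = effect, n_blocks = 0, seed = seed)
  if (!is.null(beta_scale))
    sim$truth$survival_beta <- beta_scale * sign(sim$truth$survival_beta)
  norm <- normalize_counts(sim$matrix)
  metadata <- add_simulated_survival(sim$metadata, norm, sim$truth,
                                     censor_rate = censor_rate, seed = seed)
  split <- make_split(metadata, seed = seed)
  list(sim = sim, norm = norm, metadata = metadata, split = split,
       features = transform_features(norm, split), truth = sim$truth)
}

recovered <- function(ranking, truth_genes, k = 20) {
  length(intersect(top_genes(ranking, k), truth_genes))
}
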