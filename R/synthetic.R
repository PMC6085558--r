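# Negative-binomial case-control simulator with planted differential
# signal, correlated gene blocks, planted size factors and survival times
# linked to signal-gene expression. Ground truth travels with the data so
# every ranker and the survival benchmark can be scored against it.

#' Simulate a case-control RNA-Seq count dataset with known truth
#'
#' Counts are drawn gene-wise from a negative binomial with variance
#' `mu + dispersion * mu^2`. Gene baseline means span several orders of
#' magnitude (log-uniform over roughly 1 to 10^4); each sample receives a
#' planted size factor drawn log-uniform in `[0.5, 2]`, so that
#' normalization has a known target to recover. A random subset of
#' `n_signal` genes is differentially expressed: their case-class mean is
#' shifted by `effect_log2fc` on the log2 scale, with alternating sign
#' across signal genes. Optionally, `n_blocks` disjoint blocks of genes
#' share a per-sample latent Gaussian factor giving log-scale correlation
#' `block_rho` within a block, mimicking co-regulated modules.
#'
#' Survival coefficients for [simulate_survival()] are planted on the
#' signal genes: `beta_g = 0.5 * sign(log2FC_g)` per standardized unit of
#' transformed expression, zero elsewhere.
#'
#' @param n_genes number of genes.
#' @param n_case number of case (tumor) samples.
#' @param n_control number of control (healthy) samples; may be smaller
#'   than `n_case` to mimic the class imbalance of tumor cohorts.
#' @param n_signal number of planted differentially expressed genes.
#' @param effect_log2fc absolute log2 fold change planted on signal genes.
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param n_blocks number of correlated gene blocks (0 for none).
#' @param block_rho within-block log-scale correlation, in `[0, 1)`.
#' @param block_size genes per correlated block.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return A list with `matrix` (raw-count [expression_matrix()]),
#'   `metadata` (conditions only; survival fields `NA` until
#'   [simulate_survival()]) and `truth` (a `synthetic_truth` list:
#'   `signal_genes`, per-gene `log2fc`, `blocks`, `survival_beta`,
#'   `size_factors`, `seed`).
#' @examples
#' sim <- simulate_dataset(n_genes = 200, n_case = 30, n_control = 10,
#'                         n_signal = 5, seed = 1)
#' length(sim$truth$signal_genes)
#' @export
simulate_dataset <- function(n_genes = 2000, n_case = 150, n_control = 50,
                             n_signal = 10, effect_log2fc = 2,
                             dispersion = 0.1, n_blocks = 10,
                             block_rho = 0.5, block_size = 10, seed = 1) {
  if (n_genes < 1 || n_case < 1 || n_control < 1)
    stop("n_genes, n_case and n_control must be positive")
  if (n_signal < 0 || n_signal > n_genes)
    stop("n_signal must lie in [0, n_genes]")
  if (dispersion <= 0) stop("dispersion must be positive")
  if (block_rho < 0 || block_rho >= 1) stop("block_rho must be in [0, 1)")
  if (n_blocks * block_size > n_genes)
    stop("block structure exceeds the gene universe")

  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  cases <- sprintf("case%03d", seq_len(n_case))
  controls <- sprintf("ctrl%03d", seq_len(n_control))
  samples <- c(cases, controls)
  n_samples <- length(samples)
  is_case <- c(rep(TRUE, n_case), rep(FALSE, n_control))

  base_mean <- 10^runif(n_genes, 0, 4)
  size_factors <- setNames(exp(runif(n_samples, log(0.5), log(2))), samples)

  signal_genes <- if (n_signal > 0) sort(sample(genes, n_signal)) else character()
  log2fc <- setNames(rep(0, n_genes), genes)
  if (n_signal > 0)
    log2fc[signal_genes] <- effect_log2fc *
      rep_len(c(1, -1), n_signal)

  # Block structure: disjoint runs of genes outside the signal set share a
  # per-sample standard-normal factor; log-scale correlation within a block
  # is block_rho, achieved by mixing shared and idiosyncratic factors.
  blocks <- list()
  log_noise_sd <- 0.5
  block_member <- rep(NA_integer_, n_genes)
  if (n_blocks > 0) {
    pool <- setdiff(genes, signal_genes)
    picked <- sample(pool, min(n_blocks * block_size, length(pool)))
    blocks <- split(picked, rep(seq_len(n_blocks), each = block_size,
                                length.out = length(picked)))
    for (b in seq_along(blocks))
      block_member[match(blocks[[b]], genes)] <- b
  }

  mu <- matrix(base_mean, n_genes, n_samples, dimnames = list(genes, samples))
  mu[, is_case] <- mu[, is_case] * 2^log2fc
  mu <- sweep(mu, 2L, size_factors, `*`)
  if (length(blocks)) {
    shared <- matrix(rnorm(length(blocks) * n_samples),
                     length(blocks), n_samples)
    in_block <- which(!is.na(block_member))
    idio <- matrix(rnorm(length(in_block) * n_samples),
                   length(in_block), n_samples)
    z <- sqrt(block_rho) * shared[block_member[in_block], , drop = FALSE] +
      sqrt(1 - block_rho) * idio
    mu[in_block, ] <- mu[in_block, ] *
      exp(log_noise_sd * z - log_noise_sd^2 / 2)
  }

  counts <- matrix(rnbinom(n_genes * n_samples, mu = as.vector(mu),
                           size = 1 / dispersion),
                   n_genes, n_samples, dimnames = list(genes, samples))
  storage.mode(counts) <- "double"

  survival_beta <- setNames(rep(0, n_genes), genes)
  if (n_signal > 0)
    survival_beta[signal_genes] <- 0.5 * sign(log2fc[signal_genes])

  metadata <- data.frame(
    sample_id = samples,
    condition = ifelse(is_case, "case", "control"),
    survival_time = NA_real_, event = NA_integer_,
    stringsAsFactors = FALSE)

  truth <- structure(list(signal_genes = signal_genes, log2fc = log2fc,
                          blocks = blocks, survival_beta = survival_beta,
                          size_factors = size_factors, seed = seed),
                     class = "synthetic_truth")
  list(matrix = expression_matrix(counts, normalized = FALSE),
       metadata = metadata, truth = truth)
}

#' Simulate survival outcomes linked to planted signal genes
#'
#' Draws survival times from an exponential proportional-hazards model.
#' The linear predictor of sample `j` is `sum_g beta_g * s_gj`, where
#' `s_gj` is the gene's log2(x+1)-transformed normalized expression,
#' standardized across samples, and `beta` is `truth$survival_beta`.
#' Censoring is independent uniform on `[0, c_max]`, with `c_max` chosen
#' numerically so the expected censoring fraction matches `censor_rate`
#' (`censor_rate = 0` disables censoring: every event flag is 1).
#'
#' @param matrix a normalized [expression_matrix()].
#' @param truth a `synthetic_truth` from [simulate_dataset()] (or any list
#'   with a named `survival_beta` covering the genes).
#' @param baseline_hazard exponential baseline hazard (events per day).
#' @param censor_rate target fraction of censored samples, in `[0, 1)`.
#' @param seed integer seed.
#' @return Metadata data frame with `survival_time` (days) and `event`
#'   filled for every sample of the matrix.
#' @export
simulate_survival <- function(matrix, truth, baseline_hazard = 1 / 1000,
                              censor_rate = 0.3, seed = 1) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (!matrix$normalized)
    stop("simulate_survival expects a normalized matrix")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)")
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  beta <- truth$survival_beta[gene_ids(matrix)]
  if (anyNA(beta)) stop("survival_beta does not cover the matrix genes")

  set.seed(seed)
  active <- which(beta != 0)
  eta <- rep(0, ncol(matrix$values))
  if (length(active)) {
    expr <- log2(matrix$values[active, , drop = FALSE] + 1)
    s <- apply(expr, 1L, sd)
    s[s == 0] <- 1
    z <- (expr - rowMeans(expr)) / s
    eta <- as.vector(crossprod(z, beta[active]))
  }
  rate <- baseline_hazard * exp(eta)
  t_event <- rexp(length(rate), rate = rate)

  if (censor_rate > 0) {
    # E[P(C < T)] for C ~ U(0, cmax), T ~ Exp(rate_j), averaged over samples.
    pcens <- function(cmax) mean((1 - exp(-rate * cmax)) / (rate * cmax)) -
      censor_rate
    cmax <- uniroot(pcens, lower = 1e-8 / baseline_hazard,
                    upper = 1e8 / baseline_hazard, tol = 1e-10)$root
    t_cens <- runif(length(rate), 0, cmax)
    event <- as.integer(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  } else {
    event <- rep(1L, length(rate))
    time <- t_event
  }
  data.frame(sample_id = sample_ids(matrix),
             condition = NA_character_,
             survival_time = time, event = event,
             stringsAsFactors = FALSE)
}

#' Attach simulated survival to existing metadata
#'
#' Convenience wrapper: runs [simulate_survival()] and merges the times
#' and event flags into a metadata table by `sample_id`.
#'
#' @inheritParams simulate_survival
#' @param metadata metadata data frame whose survival fields get filled.
#' @return The metadata with `survival_time` and `event` populated.
#' @export
add_simulated_survival <- function(metadata, matrix, truth,
                                   baseline_hazard = 1 / 1000,
                                   censor_rate = 0.3, seed = 1) {
  surv <- simulate_survival(matrix, truth, baseline_hazard, censor_rate, seed)
  i <- match(metadata$sample_id, surv$sample_id)
  metadata$survival_time <- surv$survival_time[i]
  metadata$event <- surv$event[i]
  validate_metadata(metadata)
}
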