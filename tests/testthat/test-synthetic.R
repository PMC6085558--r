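test_that("generator is deterministic and validates parameters", {
  a <- simulate_dataset(n_genes = 100, n_case = 15, n_control = 10, seed = 42)
  b <- simulate_dataset(n_genes = 100, n_case = 15, n_control = 10, seed = 42)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth$signal_genes, b$truth$signal_genes)
  c <- simulate_dataset(n_genes = 100, n_case = 15, n_control = 10, seed = 43)
  expect_false(identical(a$matrix$values, c$matrix$values))

  expect_error(simulate_dataset(n_genes = 0), "positive")
  expect_error(simulate_dataset(n_genes = 10, n_signal = 11), "n_signal")
  expect_error(simulate_dataset(dispersion = 0), "dispersion")
  expect_error(simulate_dataset(block_rho = 1), "block_rho")
})

test_that("null generator plants no signal", {
  sim <- simulate_dataset(n_genes = 300, n_case = 40, n_control = 40,
                          n_signal = 0, n_blocks = 0, seed = 5)
  expect_length(sim$truth$signal_genes, 0)
  expect_true(all(sim$truth$log2fc == 0))
  expect_true(all(sim$truth$survival_beta == 0))
  # class-mean log-ratios should scatter around zero
  norm <- normalize_counts(sim$matrix)
  is_case <- sim$metadata$condition == "case"
  lfc <- log2((rowMeans(norm$values[, is_case]) + 0.5) /
              (rowMeans(norm$values[, !is_case]) + 0.5))
  expect_lt(abs(mean(lfc)), 0.1)
})

test_that("planted effect size is recovered after normalization", {
  sim <- simulate_dataset(n_genes = 2000, n_case = 150, n_control = 50,
                          n_signal = 10, effect_log2fc = 2, seed = 1)
  norm <- normalize_counts(sim$matrix)
  is_case <- sim$metadata$condition == "case"
  sg <- sim$truth$signal_genes
  lfc <- log2((rowMeans(norm$values[sg, is_case, drop = FALSE]) + 0.5) /
              (rowMeans(norm$values[sg, !is_case, drop = FALSE]) + 0.5))
  expect_equal(mean(abs(lfc)), 2, tolerance = 0.3 / 2)
})

test_that("planted size factors are recovered by median-of-ratios", {
  sim <- simulate_dataset(n_genes = 1000, n_case = 30, n_control = 20,
                          n_signal = 0, n_blocks = 0, seed = 9)
  est <- estimate_size_factors(sim$matrix)
  planted <- sim$truth$size_factors
  # size factors are identified up to a common scale: compare ratios
  ratio <- est / planted
  expect_lt(sd(log(ratio)), 0.05)
})

test_that("survival generator honors censoring controls and the null", {
  sim <- simulate_dataset(n_genes = 100, n_case = 60, n_control = 30,
                          n_signal = 4, seed = 3)
  norm <- normalize_counts(sim$matrix)
  no_cens <- simulate_survival(norm, sim$truth, censor_rate = 0, seed = 1)
  expect_true(all(no_cens$event == 1))

  cens <- simulate_survival(norm, sim$truth, censor_rate = 0.4, seed = 1)
  expect_equal(mean(cens$event == 0), 0.4, tolerance = 0.12)

  expect_error(simulate_survival(sim$matrix, sim$truth), "normalized")
  expect_error(simulate_survival(norm, sim$truth, censor_rate = 1),
               "censor_rate")
})

test_that("under null survival the median-split log-rank is calibrated", {
  # all betas zero: survival independent of expression, so a split on any
  # expression-derived score must reject at the nominal level
  sim <- simulate_dataset(n_genes = 40, n_case = 120, n_control = 30,
                          n_signal = 0, n_blocks = 0, seed = 11)
  norm <- normalize_counts(sim$matrix)
  split <- make_split(sim$metadata, seed = 11)
  sig <- gene_ids(norm)[1:3]
  reject <- vapply(seq_len(200), function(r) {
    md <- add_simulated_survival(sim$metadata, norm, sim$truth,
                                 censor_rate = 0.2, seed = 1000 + r)
    res <- evaluate_signature(sig, norm, md, split)
    res$p < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("stronger survival effects increase the log-rank statistic", {
  # paired over replicates: doubling every beta must raise the average
  # absolute standardized log-rank statistic of the true-risk median split
  sim <- simulate_dataset(n_genes = 60, n_case = 80, n_control = 20,
                          n_signal = 6, n_blocks = 0, seed = 21)
  norm <- normalize_counts(sim$matrix)
  chisq_for <- function(beta_scale, seed) {
    truth <- sim$truth
    truth$survival_beta <- beta_scale * truth$survival_beta
    md <- simulate_survival(norm, truth, censor_rate = 0.1, seed = seed)
    active <- names(which(truth$survival_beta != 0))
    expr <- log2(norm$values[active, , drop = FALSE] + 1)
    z <- (expr - rowMeans(expr)) / apply(expr, 1L, sd)
    risk <- as.vector(crossprod(z, truth$survival_beta[active]))
    grp <- risk >= median(risk)
    oracle_logrank_chisq(md$survival_time, md$event, grp + 1L)
  }
  weak <- vapply(1:50, function(s) chisq_for(1, s), numeric(1))
  strong <- vapply(1:50, function(s) chisq_for(2, s), numeric(1))
  expect_gt(mean(sqrt(strong)), mean(sqrt(weak)))
})
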