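# Blob-fixture EPS stage tests. The model is trained once per file run
# and reused across blocks to keep the suite fast.
blobs <- make_blobs(n_per_class = 50, d = 30, sep = 3, seed = 5)
blob_model <- train_vae(blobs$x, vae_architecture(30, "desk"),
                        epochs = 200, seed = 1)
blob_latent <- vae_embed(blob_model, blobs$x, seed = 7)

test_that("separator reaches perfect accuracy on separable clouds", {
  sep <- fit_separator(blob_latent$z, blobs$labels)
  expect_identical(sep$accuracy, 1)
  d <- signed_distance(sep, blob_latent$z)
  expect_true(all(d[blobs$labels == "case"] > 0))
  expect_true(all(d[blobs$labels == "control"] < 0))

  # flipping labels negates the direction
  flipped <- factor(ifelse(blobs$labels == "case", "control", "case"),
                    levels = c("control", "case"))
  sep2 <- fit_separator(blob_latent$z, flipped)
  cosine <- sum(sep$weights * sep2$weights) /
    sqrt(sum(sep$weights^2) * sum(sep2$weights^2))
  expect_lt(cosine, -0.99)

  expect_error(fit_separator(matrix(1, 10, 3),
                             rep(c("case", "control"), 5)), "degenerate")
})

test_that("shuffled labels give chance-level separator accuracy", {
  set.seed(9)
  z <- matrix(rnorm(400 * 2), 400, 2)
  y <- sample(rep(c("case", "control"), each = 200))
  sep <- fit_separator(z, y)
  expect_gt(sep$accuracy, 0.4)
  expect_lt(sep$accuracy, 0.6)
})

test_that("extreme regions obey the quantile counting rule", {
  sep <- fit_separator(blob_latent$z, blobs$labels)
  reg_all <- find_extreme_regions(blob_latent, blobs$labels, sep, q = 1)
  expect_identical(length(reg_all$regions$case$members), 50L)
  expect_identical(length(reg_all$regions$control$members), 50L)

  reg <- find_extreme_regions(blob_latent, blobs$labels, sep, q = 0.1)
  expect_identical(length(reg$regions$case$members), 5L)  # ceil(0.1*50)
  expect_identical(length(reg$regions$control$members), 5L)

  # every member is at least as extreme as every same-class non-member
  d <- abs(signed_distance(sep, blob_latent$z))
  for (cls in c("case", "control")) {
    mem <- reg$regions[[cls]]$members
    others <- setdiff(which(blobs$labels == cls), mem)
    expect_gte(min(d[mem]), max(d[others]))
    expect_gte(min(d[mem]), reg$regions[[cls]]$threshold)
  }
  expect_error(find_extreme_regions(blob_latent, blobs$labels, sep, q = 0),
               "q must")
})

test_that("pseudo-samples are balanced, side-consistent and cycle-consistent", {
  sep <- fit_separator(blob_latent$z, blobs$labels)
  reg <- find_extreme_regions(blob_latent, blobs$labels, sep, q = 0.2)
  ps <- draw_pseudo_samples(reg, blob_latent, blob_model,
                            n_per_class = 100, seed = 3)
  expect_identical(as.vector(table(ps$labels)), c(100L, 100L))
  d <- signed_distance(sep, ps$z)
  expect_true(all(d[ps$labels == "case"] > 0))
  expect_true(all(d[ps$labels == "control"] < 0))

  # decoded pseudo-samples re-embed (posterior mean) on their generating side
  re <- vae_embed(blob_model, ps$x, seed = 4)
  agree <- mean((signed_distance(sep, re$mu) > 0) == (ps$labels == "case"))
  expect_gte(agree, 0.95)

  # seeded draws are reproducible
  ps2 <- draw_pseudo_samples(reg, blob_latent, blob_model,
                             n_per_class = 100, seed = 3)
  expect_identical(ps$x, ps2$x)
})

test_that("EPS coefficients zero out constant features and rank separating ones", {
  sep <- fit_separator(blob_latent$z, blobs$labels)
  reg <- find_extreme_regions(blob_latent, blobs$labels, sep, q = 0.2)
  ps <- draw_pseudo_samples(reg, blob_latent, blob_model,
                            n_per_class = 50, seed = 3)
  ps$x <- cbind(ps$x, const_feat = rep(2, nrow(ps$x)))
  r <- rank_by_eps(ps)
  expect_setequal(r$gene_id, colnames(ps$x))
  expect_identical(r$gene_id[nrow(r)], "const_feat")
  expect_identical(r$score[r$gene_id == "const_feat"], 0)
  expect_true(all(diff(r$score) <= 0))
})

test_that("the full EPS pipeline is seed-reproducible end to end", {
  co <- make_small_cohort(n_genes = 120, n_case = 25, n_control = 25,
                          n_signal = 5, effect = 3, seed = 6)
  run <- function() rank_by_eps_pipeline(co$features, co$metadata, co$split,
                                         epochs = 40, seed = 11,
                                         n_per_class = 50)
  r1 <- run(); r2 <- run()
  expect_identical(r1$ranking$gene_id, r2$ranking$gene_id)
  expect_identical(r1$ranking$score, r2$ranking$score)
  expect_identical(r1$pseudo$x, r2$pseudo$x)
})

test_that("stronger planted effects do not demote signal genes", {
  med_rank <- function(effect, seed) {
    co <- make_small_cohort(n_genes = 120, n_case = 25, n_control = 25,
                            n_signal = 5, effect = effect, seed = seed)
    r <- rank_by_eps_pipeline(co$features, co$metadata, co$split,
                              epochs = 40, seed = 5, n_per_class = 50)
    median(r$ranking$rank[r$ranking$gene_id %in% co$truth$signal_genes])
  }
  ranks <- vapply(1:3, function(s)
    c(weak = med_rank(0.5, s), strong = med_rank(3, s)), numeric(2))
  expect_true(all(ranks["strong", ] <= ranks["weak", ]))
})
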