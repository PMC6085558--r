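test_that("size factors match the closed-form two-sample cases", {
  counts <- matrix(c(10, 20, 40, 10, 20, 40), ncol = 2,
                   dimnames = list(paste0("g", 1:3), c("a", "b")))
  m <- expression_matrix(counts)
  expect_equal(unname(estimate_size_factors(m)), c(1, 1))

  counts2 <- cbind(a = c(10, 20, 40), b = c(20, 40, 80))
  rownames(counts2) <- paste0("g", 1:3)
  f <- estimate_size_factors(expression_matrix(counts2))
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)))
})

test_that("size factors equal the brute-force oracle", {
  set.seed(4)
  counts <- matrix(rpois(24, 60) + 1, nrow = 6,
                   dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
  m <- expression_matrix(counts)
  expect_equal(unname(estimate_size_factors(m)),
               oracle_size_factors(counts), tolerance = 1e-12)

  # with zero-containing genes excluded from the reference set only
  counts[2, 3] <- 0
  m2 <- expression_matrix(counts)
  expect_equal(unname(estimate_size_factors(m2)),
               oracle_size_factors(counts), tolerance = 1e-12)

  # scale equivariance: doubling one sample doubles its factor and leaves
  # the others' ratios unchanged up to the shared geometric-mean shift
  counts3 <- counts
  counts3[, 2] <- counts3[, 2] * 2
  f0 <- oracle_size_factors(counts)
  f1 <- estimate_size_factors(expression_matrix(counts3))
  shift <- 2^(1 / ncol(counts))  # geometric-mean change from doubling one sample
  expect_equal(unname(f1[2]), 2 * f0[2] / shift, tolerance = 1e-12)
  expect_equal(unname(f1[-2]), f0[-2] / shift, tolerance = 1e-12)
})

test_that("normalization divides by factors and flags the matrix", {
  co <- make_small_cohort(n_genes = 50, n_case = 10, n_control = 10, seed = 2)
  raw <- co$sim$matrix
  ones <- setNames(rep(1, ncol(raw$values)), sample_ids(raw))
  same <- normalize_counts(raw, ones)
  expect_identical(same$values, raw$values)
  expect_true(same$normalized)

  ones[3] <- 2
  halved <- normalize_counts(raw, ones)
  expect_equal(halved$values[, 3], raw$values[, 3] / 2)
  expect_error(normalize_counts(raw, ones[-1]), "missing size factor")
  expect_error(estimate_size_factors(same), "raw counts")
})

test_that("the balanced split obeys the stated arithmetic and uniformity", {
  md <- data.frame(
    sample_id = c(sprintf("t%04d", 1:1097), sprintf("h%04d", 1:113)),
    condition = rep(c("case", "control"), c(1097, 113)))
  sp <- make_split(md, seed = 1)
  expect_length(sp$training_ids, 226)
  expect_length(sp$validation_ids, 1097 - 113)
  cond <- setNames(md$condition, md$sample_id)
  expect_true(all(cond[sp$validation_ids] == "case"))
  expect_identical(sum(cond[sp$training_ids] == "case"), 113L)
  expect_identical(sum(cond[sp$training_ids] == "control"), 113L)

  expect_identical(make_split(md, seed = 1), sp)
  expect_false(identical(make_split(md, seed = 2)$training_ids,
                         sp$training_ids))

  balanced <- data.frame(sample_id = paste0("s", 1:20),
                         condition = rep(c("case", "control"), 10))
  expect_error(make_split(balanced), "more cases")

  # uniformity: each case lands in training with frequency n/N
  md2 <- data.frame(sample_id = c(sprintf("t%02d", 1:15), sprintf("h%02d", 1:5)),
                    condition = rep(c("case", "control"), c(15, 5)))
  hits <- setNames(rep(0, 15), sprintf("t%02d", 1:15))
  for (s in 1:500) {
    tr <- make_split(md2, seed = s)$training_ids
    cs <- intersect(tr, names(hits))
    hits[cs] <- hits[cs] + 1
  }
  p <- 5 / 15
  se <- sqrt(p * (1 - p) / 500)
  expect_true(all(abs(hits / 500 - p) <= 3 * se))
})

test_that("feature transform centers on training statistics only", {
  co <- make_survival_cohort(n_genes = 80, n_case = 60, n_control = 20,
                             seed = 6)
  f <- co$features
  tr <- f$values[co$split$training_ids, ]
  expect_lt(max(abs(colMeans(tr))), 1e-8)
  expect_equal(unname(apply(tr, 2, sd)), rep(1, ncol(tr)), tolerance = 1e-8)

  # validation rows reuse training constants, so their means differ from 0
  va <- f$values[co$split$validation_ids, ]
  expect_gt(max(abs(colMeans(va))), 1e-8)
})

test_that("degenerate genes and the log2p1 round trip behave as defined", {
  counts <- matrix(c(0, 0, 0, 0, 5, 6, 7, 8, 100, 110, 120, 130), nrow = 3,
                   byrow = TRUE,
                   dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  m <- expression_matrix(counts, normalized = TRUE)
  md <- data.frame(sample_id = paste0("s", 1:4),
                   condition = c("case", "case", "control", "control"))
  sp <- split_spec(paste0("s", 1:4), character(), md, seed = 1)
  plain <- transform_features(m, sp, "log2p1")
  zs <- transform_features(m, sp, "log2p1_zscore")
  expect_true(all(plain$values[, "g1"] == 0))
  expect_true(all(zs$values[, "g1"] == 0))

  back <- inverse_transform_features(plain)
  expect_equal(back, t(m$values), tolerance = 1e-9)
  back2 <- inverse_transform_features(zs)
  expect_equal(back2, t(m$values), tolerance = 1e-9)
})
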