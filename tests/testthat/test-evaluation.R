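test_that("signature families are nested prefixes", {
  r <- gene_ranking(sprintf("g%02d", 1:30), seq(30, 1), "FC")
  sigs <- build_signatures(r)
  expect_length(sigs, 20)
  for (i in seq_len(19)) {
    expect_length(sigs[[i]], i)
    expect_true(all(sigs[[i]] %in% sigs[[i + 1]]))
  }
  expect_identical(attr(sigs, "method"), "FC")
  expect_error(build_signatures(r, 31), "i_max")

  # rankings sharing a top-k prefix share signatures up to k
  r2 <- gene_ranking(c(sprintf("g%02d", 1:10), sprintf("g%02d", 30:11)),
                     seq(30, 1), "DE")
  s2 <- build_signatures(r2, 10)
  expect_identical(unclass(s2)[1:10], unclass(build_signatures(r, 10))[1:10])
})

test_that("log-rank statistic matches the brute-force oracle", {
  ex <- logrank_example_8()
  ours <- survival::survdiff(
    survival::Surv(ex$time, ex$event) ~ ex$group)$chisq
  expect_equal(ours, oracle_logrank_chisq(ex$time, ex$event, ex$group),
               tolerance = 1e-10)

  # random survival data with ties, against the same oracle
  set.seed(31)
  for (rep in 1:5) {
    tm <- sample(1:20, 40, replace = TRUE)
    ev <- rbinom(40, 1, 0.7)
    gr <- rep(c(1, 2), each = 20)
    expect_equal(survival::survdiff(survival::Surv(tm, ev) ~ gr)$chisq,
                 oracle_logrank_chisq(tm, ev, gr), tolerance = 1e-10)
  }
})

test_that("identical survival in both groups gives a null log-rank", {
  # duplicated survival records split evenly across groups
  base <- data.frame(time = c(5, 8, 12, 20, 33, 47), event = c(1, 1, 0, 1, 1, 0))
  tm <- rep(base$time, 2)
  ev <- rep(base$event, 2)
  gr <- rep(c("a", "b"), each = 6)
  chi <- oracle_logrank_chisq(tm, ev, gr)
  expect_equal(chi, 0, tolerance = 1e-12)
  expect_equal(pchisq(chi, 1, lower.tail = FALSE), 1)
})

test_that("evaluate_signature returns a coherent log-rank result", {
  co <- make_survival_cohort(seed = 2)
  res <- evaluate_signature(co$truth$signal_genes[1:3], co$norm,
                            co$metadata, co$split)
  expect_s3_class(res, "logrank_result")
  expect_true(res$converged)
  expect_gt(res$p, 0)
  expect_lte(res$p, 1)
  n_eval <- sum(!is.na(co$metadata$survival_time[
    co$metadata$sample_id %in% co$split$validation_ids]))
  expect_identical(res$n_high + res$n_low, n_eval)

  expect_error(evaluate_signature(c("nope"), co$norm, co$metadata, co$split),
               "absent")
})

test_that("signatures containing the survival-driving gene have power", {
  hits <- vapply(1:20, function(s) {
    co <- make_survival_cohort(n_genes = 60, n_case = 330, n_control = 30,
                               n_signal = 1, beta_scale = 1.5,
                               censor_rate = 0.1, seed = 100 + s)
    res <- evaluate_signature(co$truth$signal_genes, co$norm, co$metadata,
                              co$split)
    res$p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("pairwise comparison counts wins and ties exactly", {
  mk <- function(p) data.frame(method = "x", i = seq_along(p), p = p)
  res <- compare_methods(list(A = mk(c(.01, .2, .03)),
                              B = mk(c(.02, .1, .03))))
  expect_identical(res$wins_a, 1L)
  expect_identical(res$wins_b, 1L)
  expect_identical(res$ties, 1L)
  expect_identical(res$wins_a + res$wins_b + res$ties, res$n_compared)

  same <- compare_methods(list(A = mk(c(.5, .5)), B = mk(c(.5, .5))))
  expect_identical(same$wins_a + same$wins_b, 0L)
  expect_identical(same$ties, 2L)

  expect_error(compare_methods(list(A = mk(1:3 / 10), B = mk(1:4 / 10))),
               "grids")
  expect_warning(compare_methods(list(A = mk(c(.1, NA)), B = mk(c(.2, .3)))),
                 "dropped")
})

test_that("stability analysis handles the deterministic and disjoint cases", {
  genes <- sprintf("g%02d", 1:30)
  fixed <- function(seed) gene_ranking(genes, seq(30, 1), "FC")
  rep_fixed <- stability_analysis(fixed, n_iter = 4, k = 10)
  expect_identical(rep_fixed$mean_overlap, 10)
  expect_true(all(rep_fixed$rank_summary$sd_rank == 0))

  flip <- function(seed) {
    ids <- if (seed %% 2 == 0) genes else rev(genes)
    gene_ranking(ids, seq(30, 1), "FC")
  }
  rep_flip <- stability_analysis(flip, n_iter = 2, k = 10, seeds = c(1, 2))
  expect_identical(rep_flip$mean_overlap, 0)
  expect_error(stability_analysis(fixed, n_iter = 1), "n_iter")
})

test_that("subsample selection follows the stated arithmetic", {
  md <- data.frame(sample_id = c(sprintf("t%03d", 1:450), sprintf("h%03d", 1:50)),
                   condition = rep(c("case", "control"), c(450, 50)))
  ids <- select_subsample(md, fraction = 0.2, min_controls = 20, seed = 1)
  expect_length(ids, 100)
  cond <- setNames(md$condition, md$sample_id)
  expect_identical(sum(cond[ids] == "control"), 20L)
  expect_identical(sum(cond[ids] == "case"), 80L)

  expect_identical(select_subsample(md, 0.2, 20, seed = 5),
                   select_subsample(md, 0.2, 20, seed = 5))
  expect_false(identical(select_subsample(md, 0.2, 20, seed = 6),
                         select_subsample(md, 0.2, 20, seed = 5)))

  all_ids <- select_subsample(md, fraction = 1, min_controls = 20, seed = 1)
  expect_setequal(all_ids, md$sample_id)

  tiny <- md[c(1:30, 451:500), ]
  expect_error(select_subsample(tiny, 0.2, 20, seed = 1), "infeasible")
})
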