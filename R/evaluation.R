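# Survival-signature benchmark: nested signatures from each ranking, Cox
# risk scores on the validation cohort, median-split log-rank tests,
# pairwise win counts, and the stability / subsample experiments.

#' Build nested gene signatures from a ranking
#'
#' `sig_i` is the set of the first `i` genes of the ranking, for
#' `i = 1..i_max`; signatures are nested by construction.
#'
#' @param ranking a [gene_ranking()].
#' @param i_max largest signature size (default 20).
#' @return Object of class `signature_family`: list of gene-id vectors
#'   of lengths `1..i_max`, with the ranking's method as attribute.
#' @export
build_signatures <- function(ranking, i_max = 20) {
  stopifnot(inherits(ranking, "gene_ranking"))
  if (i_max < 1 || i_max > nrow(ranking))
    stop("i_max must lie in [1, number of ranked genes]")
  sigs <- lapply(seq_len(i_max), function(i) ranking$gene_id[seq_len(i)])
  structure(sigs, method = ranking_method(ranking),
            class = "signature_family")
}

#' Evaluate one gene signature by a median-split log-rank test
#'
#' Fits a Cox proportional-hazards model with the signature genes'
#' transformed expression (`log2(x+1)`, standardized) as covariates
#' under a small ridge penalty, scores every validation sample by the
#' model's linear predictor (risk score), splits the validation cohort
#' at the median risk score (scores equal to the median join the
#' high-risk group), and compares the two groups with a two-group
#' log-rank test (1 df). Only validation samples with complete survival
#' records enter the split and the test.
#'
#' By default the Cox model is fitted on the *training* samples with
#' complete survival, so the coefficients are independent of the
#' survival outcomes being tested: under a null in which survival is
#' unrelated to expression, the log-rank test then rejects at its
#' nominal level. Setting `cox_cohort = "validation"` fits the model on
#' the validation cohort itself instead; note that reusing the same
#' outcomes for fitting and testing makes the test anti-conservative.
#'
#' @param signature character vector of gene ids.
#' @param matrix a normalized [expression_matrix()].
#' @param metadata validated metadata with survival fields.
#' @param split a [split_spec()].
#' @param theta ridge penalty of the Cox fit.
#' @param cox_cohort `"training"` (default) or `"validation"`: which
#'   cohort's survival the Cox coefficients are estimated from.
#' @return Object of class `logrank_result`: list with `size`, `chisq`,
#'   `p`, `n_high`, `n_low`, `converged`. A failed or degenerate fit is
#'   flagged (`converged = FALSE`, `p = NA`) with a warning.
#' @export
evaluate_signature <- function(signature, matrix, metadata, split,
                               theta = 1e-4,
                               cox_cohort = c("training", "validation")) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(split, "split_spec"))
  cox_cohort <- match.arg(cox_cohort)
  if (!matrix$normalized)
    stop("evaluate_signature expects a normalized matrix")
  metadata <- validate_metadata(metadata)
  miss <- setdiff(signature, gene_ids(matrix))
  if (length(miss))
    stop("signature gene(s) absent from the matrix: ",
         paste(miss, collapse = ", "))

  complete_surv <- function(ids) {
    md <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
    md[!is.na(md$survival_time) & !is.na(md$event), , drop = FALSE]
  }
  md_val <- complete_surv(split$validation_ids)
  if (nrow(md_val) < 4L)
    stop("fewer than 4 validation samples with complete survival")
  md_fit <- switch(cox_cohort,
                   training = complete_surv(split$training_ids),
                   validation = md_val)
  if (nrow(md_fit) < 4L)
    stop("fewer than 4 ", cox_cohort, " samples with complete survival")

  # covariates standardized with the fitting cohort's statistics
  expr_block <- function(ids) {
    t(log2(matrix$values[signature, ids, drop = FALSE] + 1))
  }
  x_fit <- expr_block(md_fit$sample_id)
  center <- colMeans(x_fit)
  s <- apply(x_fit, 2L, sd)
  s[s == 0] <- 1
  standardize <- function(x) sweep(sweep(x, 2L, center), 2L, s, `/`)
  x_fit <- standardize(x_fit)
  x_val <- standardize(expr_block(md_val$sample_id))
  surv_fit <- survival::Surv(md_fit$survival_time, md_fit$event)
  surv_val <- survival::Surv(md_val$survival_time, md_val$event)

  risk <- tryCatch({
    fit <- survival::coxph(surv_fit ~ survival::ridge(x_fit, theta = theta,
                                                      scale = FALSE))
    as.vector(x_val %*% coef(fit))
  }, error = function(e) NULL, warning = function(w) {
    # ridge Cox warns rather than errors on non-convergence
    fit <- suppressWarnings(
      survival::coxph(surv_fit ~ survival::ridge(x_fit, theta = theta,
                                                 scale = FALSE)))
    as.vector(x_val %*% coef(fit))
  })

  fail <- function(msg) {
    warning("signature of size ", length(signature), ": ", msg)
    structure(list(size = length(signature), chisq = NA_real_, p = NA_real_,
                   n_high = NA_integer_, n_low = NA_integer_,
                   converged = FALSE),
              class = "logrank_result")
  }
  if (is.null(risk) || anyNA(risk) || !all(is.finite(risk)))
    return(fail("Cox fit failed; p recorded as missing"))

  group <- factor(ifelse(risk >= median(risk), "high", "low"),
                  levels = c("low", "high"))
  if (nlevels(droplevels(group)) < 2L)
    return(fail("all risk scores equal; median split degenerate"))
  sd_fit <- survival::survdiff(surv_val ~ group)
  p <- pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE)
  structure(list(size = length(signature), chisq = unname(sd_fit$chisq),
                 p = p, n_high = sum(group == "high"),
                 n_low = sum(group == "low"), converged = TRUE),
            class = "logrank_result")
}

#' Evaluate every nested signature of a ranking
#'
#' @param ranking a [gene_ranking()].
#' @param matrix a normalized [expression_matrix()].
#' @param metadata validated metadata with survival fields.
#' @param split a [split_spec()].
#' @param i_max largest signature size.
#' @param theta ridge penalty of the Cox fits.
#' @param cox_cohort passed to [evaluate_signature()].
#' @return Data frame with one row per signature size: `method`, `i`,
#'   `chisq`, `p`, `n_high`, `n_low`, `converged`.
#' @export
evaluate_ranking <- function(ranking, matrix, metadata, split, i_max = 20,
                             theta = 1e-4,
                             cox_cohort = c("training", "validation")) {
  cox_cohort <- match.arg(cox_cohort)
  sigs <- build_signatures(ranking, i_max)
  rows <- lapply(sigs, function(sig) {
    r <- evaluate_signature(sig, matrix, metadata, split, theta, cox_cohort)
    data.frame(method = attr(sigs, "method"), i = r$size, chisq = r$chisq,
               p = r$p, n_high = r$n_high, n_low = r$n_low,
               converged = r$converged, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise win counts between methods
#'
#' For every ordered pair of methods, counts the signature sizes at
#' which method A's log-rank p-value is strictly smaller than method
#' B's; ties are counted separately, so `wins_A + wins_B + ties` equals
#' the number of compared sizes. Sizes where either method's p is
#' missing are dropped with a warning.
#'
#' @param results named list of [evaluate_ranking()] data frames, one
#'   per method, all over the same signature-size grid.
#' @return Data frame of class `comparison_table` with one row per
#'   unordered method pair: `method_a`, `method_b`, `wins_a`, `wins_b`,
#'   `ties`, `n_compared`.
#' @export
compare_methods <- function(results) {
  stopifnot(is.list(results), length(results) >= 2L,
            !is.null(names(results)))
  grids <- lapply(results, function(r) r$i)
  for (g in grids[-1L])
    if (!identical(g, grids[[1L]]))
      stop("methods were evaluated on different signature-size grids")
  methods <- names(results)
  pairs <- utils::combn(methods, 2L, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    pa <- results[[pr[[1L]]]]$p
    pb <- results[[pr[[2L]]]]$p
    ok <- !is.na(pa) & !is.na(pb)
    if (any(!ok))
      warning(sum(!ok), " signature size(s) dropped from ", pr[[1L]], " vs ",
              pr[[2L]], " (missing p-value)")
    data.frame(method_a = pr[[1L]], method_b = pr[[2L]],
               wins_a = sum(pa[ok] < pb[ok]), wins_b = sum(pb[ok] < pa[ok]),
               ties = sum(pa[ok] == pb[ok]), n_compared = sum(ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Ranking stability across repeated runs
#'
#' Runs a seeded ranking procedure `n_iter` times, records the top-`k`
#' gene set of each iteration, and reports the mean pairwise top-`k`
#' overlap over all iteration pairs along with the per-gene mean and
#' standard deviation of rank across iterations.
#'
#' @param ranker function(seed) returning a [gene_ranking()].
#' @param n_iter number of iterations (>= 2).
#' @param k top-list size for the overlap statistic.
#' @param seeds optional explicit integer seeds (length `n_iter`);
#'   defaults to `1..n_iter`.
#' @return Object of class `stability_report`: `top_sets` (list of
#'   top-k vectors), `mean_overlap` (mean pairwise intersection size,
#'   in `[0, k]`), `rank_summary` (data frame `gene_id`, `mean_rank`,
#'   `sd_rank`).
#' @export
stability_analysis <- function(ranker, n_iter = 10, k = 20, seeds = NULL) {
  if (n_iter < 2L) stop("n_iter must be >= 2")
  if (is.null(seeds)) seeds <- seq_len(n_iter)
  stopifnot(length(seeds) == n_iter)
  rankings <- lapply(seeds, ranker)
  top_sets <- lapply(rankings, top_genes, k = k)
  pairs <- utils::combn(n_iter, 2L, simplify = FALSE)
  overlaps <- vapply(pairs, function(pr)
    length(intersect(top_sets[[pr[[1L]]]], top_sets[[pr[[2L]]]])),
    numeric(1))
  ranks <- sapply(rankings, function(r)
    setNames(r$rank, r$gene_id)[rankings[[1L]]$gene_id])
  rank_summary <- data.frame(
    gene_id = rankings[[1L]]$gene_id,
    mean_rank = rowMeans(ranks),
    sd_rank = apply(ranks, 1L, sd),
    stringsAsFactors = FALSE)
  structure(list(top_sets = top_sets, mean_overlap = mean(overlaps),
                 rank_summary = rank_summary, k = k, n_iter = n_iter),
            class = "stability_report")
}

#' Draw a stratified subsample of a cohort
#'
#' Selects `ceiling(fraction * N)` samples stratified by class
#' (controls in proportion `fraction`, rounded); if the stratified
#' control count falls below `min_controls`, controls are topped up to
#' `min_controls` and the case count reduced so the total is unchanged.
#'
#' @param metadata validated metadata with `condition`.
#' @param fraction fraction of all samples to keep, in `(0, 1]`.
#' @param min_controls minimum number of control samples.
#' @param seed integer seed.
#' @return Character vector of selected sample ids.
#' @export
select_subsample <- function(metadata, fraction = 0.2, min_controls = 20,
                             seed = 1) {
  metadata <- validate_metadata(metadata)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  cases <- metadata$sample_id[metadata$condition == "case"]
  controls <- metadata$sample_id[metadata$condition == "control"]
  n_total <- ceiling(fraction * nrow(metadata))
  n_ctrl <- max(round(fraction * length(controls)), min(min_controls,
                                                        length(controls)))
  n_case <- n_total - n_ctrl
  if (n_ctrl < min(min_controls, length(controls)) || n_case < n_ctrl + 1L)
    stop("infeasible subsample: ", n_case, " cases / ", n_ctrl, " controls")
  if (n_case > length(cases))
    stop("requested more cases than available")
  set.seed(seed)
  sel <- c(sample(controls, n_ctrl), sample(cases, n_case))
  sort(sel)
}

#' Run the full comparison on a stratified subsample
#'
#' Applies [select_subsample()] and reruns the complete methodology
#' (normalization, split, all rankers, signature evaluation and pairwise
#' comparison) on the reduced cohort via [run_full_comparison()].
#'
#' @param matrix a raw-count [expression_matrix()].
#' @param metadata validated metadata with survival fields.
#' @param fraction,min_controls,seed see [select_subsample()].
#' @param ... further arguments passed to [run_full_comparison()]
#'   (e.g. `methods`, `i_max`, `eps_epochs`, `out_dir`).
#' @return A [run_full_comparison()] result for the subsample.
#' @export
subsample_experiment <- function(matrix, metadata, fraction = 0.2,
                                 min_controls = 20, seed = 1, ...) {
  stopifnot(inherits(matrix, "expression_matrix"))
  ids <- select_subsample(metadata, fraction, min_controls, seed)
  sub_matrix <- expression_matrix(matrix$values[, ids, drop = FALSE],
                                  normalized = matrix$normalized)
  sub_md <- metadata[metadata$sample_id %in% ids, , drop = FALSE]
  run_full_comparison(matrix = sub_matrix, metadata = sub_md, ...)
}
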