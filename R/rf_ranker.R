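# Random-forest gene ranking by out-of-bag permutation importance, plus a
# model-agnostic permutation-importance routine usable with any classifier.

#' Random-forest configuration presets
#'
#' The `"full"` preset is the full-scale configuration: 100,000 trees and
#' `m_try = floor(sqrt(G))` features tried per split. The `"desk"` preset
#' keeps the square-root `m_try` rule but grows 1,000 trees, which makes
#' the ranking reproducible on a single workstation CPU; importance
#' variance shrinks as the number of trees grows, so the larger preset is
#' preferable when compute allows.
#'
#' @param preset `"desk"` (default) or `"full"`.
#' @param n_trees optional override of the tree count.
#' @param m_try `"sqrt"` (default) or an explicit integer.
#' @param seed integer seed for forest growth.
#' @return An object of class `forest_config`.
#' @export
forest_config <- function(preset = c("desk", "full"), n_trees = NULL,
                          m_try = "sqrt", seed = 1) {
  preset <- match.arg(preset)
  if (is.null(n_trees))
    n_trees <- switch(preset, full = 100000L, desk = 1000L)
  if (n_trees < 1) stop("n_trees must be >= 1")
  structure(list(preset = preset, n_trees = as.integer(n_trees),
                 m_try = m_try, seed = as.integer(seed)),
            class = "forest_config")
}

# Resolve the m_try rule against the width of the gene universe.
resolve_m_try <- function(config, n_genes) {
  if (identical(config$m_try, "sqrt")) {
    as.integer(floor(sqrt(n_genes)))
  } else {
    m <- as.integer(config$m_try)
    if (m < 1 || m > n_genes) stop("m_try must lie in [1, n_genes]")
    m
  }
}

#' Rank genes by random-forest permutation importance
#'
#' Grows a classification forest on the training samples (bootstrap
#' resampling, `m_try` features per split) and ranks genes by permutation
#' importance: for each tree, the feature of interest is permuted within
#' the tree's out-of-bag samples and the resulting increase in
#' out-of-bag misclassification error over the unpermuted baseline is
#' recorded; the gene's importance is the average over trees. Genes
#' constant across the training samples get importance exactly zero.
#' Ordering is by decreasing importance, ties broken by gene id, and is
#' reproducible for a fixed seed.
#'
#' @param features a `feature_matrix` from [transform_features()].
#' @param metadata validated metadata with `condition`.
#' @param split a [split_spec()]; only training samples are used.
#' @param config a [forest_config()].
#' @param num_threads threads for forest growth (1 keeps results
#'   bit-reproducible across machines).
#' @return A list with `ranking` (a [gene_ranking()], method `"RF"`) and
#'   `importance` (data frame `gene_id`, `importance`,
#'   `permutation_replicates`, one replicate per tree).
#' @export
rank_by_random_forest <- function(features, metadata, split,
                                  config = forest_config(),
                                  num_threads = 1) {
  blk <- training_block(features, metadata, split)
  if (nlevels(droplevels(blk$y)) < 2L)
    stop("training labels contain a single class")
  m_try <- resolve_m_try(config, ncol(blk$x))
  fit <- ranger::ranger(
    x = blk$x, y = blk$y,
    num.trees = config$n_trees, mtry = m_try,
    importance = "permutation",
    seed = config$seed, num.threads = num_threads,
    write.forest = FALSE, verbose = FALSE)
  imp <- fit$variable.importance[colnames(blk$x)]
  report <- data.frame(gene_id = names(imp), importance = unname(imp),
                       permutation_replicates = config$n_trees,
                       stringsAsFactors = FALSE)
  list(ranking = rank_descending(imp, "RF"), importance = report)
}

#' Model-agnostic permutation importance
#'
#' Measures, for each feature, the mean increase in misclassification
#' error on a supplied evaluation block when that feature's values are
#' randomly permuted, over `n_repeats` independent permutations. The
#' predictor is any function mapping a samples-by-features matrix to a
#' vector of class labels, so the measure can be audited independently of
#' the random forest.
#'
#' @param predict_fun function(newdata matrix) -> labels.
#' @param x samples-by-features numeric matrix (evaluation block).
#' @param y true labels, length `nrow(x)`.
#' @param n_repeats number of permutations per feature (>= 1).
#' @param seed integer seed.
#' @return Data frame `feature`, `importance` (mean permuted error minus
#'   baseline error), `permutation_replicates`.
#' @export
permutation_importance <- function(predict_fun, x, y, n_repeats = 10,
                                   seed = 1) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  y <- as.character(y)
  err <- function(pred) mean(as.character(pred) != y)
  baseline <- err(predict_fun(x))
  set.seed(seed)
  imp <- vapply(seq_len(ncol(x)), function(j) {
    deltas <- vapply(seq_len(n_repeats), function(r) {
      xp <- x
      xp[, j] <- xp[sample.int(nrow(x)), j]
      err(predict_fun(xp)) - baseline
    }, numeric(1))
    mean(deltas)
  }, numeric(1))
  data.frame(feature = colnames(x), importance = imp,
             permutation_replicates = n_repeats,
             stringsAsFactors = FALSE)
}
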