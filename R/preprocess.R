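# Median-of-ratios normalization, the balanced train / case-only
# validation split, and the feature transform feeding the rankers.

#' Estimate median-of-ratios size factors
#'
#' For each sample `j` the size factor is the median over reference genes
#' `g` of `count[g, j] / geomean_g`, where `geomean_g` is the geometric
#' mean of gene `g` across all samples and the reference genes are those
#' with a strictly positive geometric mean (i.e. genes expressed in every
#' sample). This is the classical sequencing-depth correction used before
#' any between-sample comparison of counts.
#'
#' @param matrix a raw-count [expression_matrix()].
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(matrix) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (matrix$normalized)
    stop("size factors are estimated on raw counts")
  counts <- matrix$values
  # geometric mean via mean of logs; any zero count zeroes the gene's geomean
  log_geo <- rowMeans(log(counts))
  ref <- is.finite(log_geo)
  if (!any(ref))
    stop("no gene has strictly positive counts in every sample; ",
         "prefilter all-zero-containing genes before normalization")
  ratios <- counts[ref, , drop = FALSE] / exp(log_geo[ref])
  factors <- apply(ratios, 2L, median)
  setNames(factors, sample_ids(matrix))
}

#' Normalize counts by size factors
#'
#' Divides each sample's counts by its size factor and flags the matrix
#' as normalized.
#'
#' @param matrix a raw-count [expression_matrix()].
#' @param factors named positive size factors covering every sample, as
#'   from [estimate_size_factors()].
#' @return A normalized [expression_matrix()].
#' @export
normalize_counts <- function(matrix, factors = estimate_size_factors(matrix)) {
  stopifnot(inherits(matrix, "expression_matrix"))
  miss <- setdiff(sample_ids(matrix), names(factors))
  if (length(miss))
    stop("missing size factor for sample(s): ", paste(miss, collapse = ", "))
  if (any(factors <= 0)) stop("size factors must be positive")
  values <- sweep(matrix$values, 2L, factors[sample_ids(matrix)], `/`)
  expression_matrix(values, normalized = TRUE)
}

#' Construct a train/validation split
#'
#' Low-level constructor validating the split invariants: training and
#' validation are disjoint, the training set contains every control, the
#' training case and control counts are equal, and the validation set
#' contains only cases. Use [make_split()] to draw the split.
#'
#' @param training_ids,validation_ids character vectors of sample ids.
#' @param metadata validated metadata covering all listed samples.
#' @param seed the seed used to draw the split (bookkeeping).
#' @return An object of class `split_spec`: list with `training_ids`,
#'   `validation_ids`, `seed`.
#' @export
split_spec <- function(training_ids, validation_ids, metadata, seed = NA_integer_) {
  metadata <- validate_metadata(metadata)
  if (length(intersect(training_ids, validation_ids)))
    stop("training and validation sets overlap")
  cond <- setNames(metadata$condition, metadata$sample_id)
  unknown <- setdiff(c(training_ids, validation_ids), names(cond))
  if (length(unknown))
    stop("split refers to unknown sample(s): ", paste(unknown, collapse = ", "))
  controls <- metadata$sample_id[metadata$condition == "control"]
  if (!all(controls %in% training_ids))
    stop("training set must contain every control sample")
  n_tr_case <- sum(cond[training_ids] == "case")
  if (n_tr_case != length(controls))
    stop("training case count (", n_tr_case,
         ") must equal control count (", length(controls), ")")
  if (length(validation_ids) && any(cond[validation_ids] != "case"))
    stop("validation set must contain only case samples")
  structure(list(training_ids = as.character(training_ids),
                 validation_ids = as.character(validation_ids),
                 seed = seed),
            class = "split_spec")
}

#' Draw the balanced training / case-only validation split
#'
#' The training set contains all `n` control (healthy) samples plus `n`
#' case (tumor) samples drawn uniformly without replacement; the remaining
#' `N - n` cases form the validation set. Requires more cases than
#' controls, otherwise the validation set would be empty.
#'
#' @param metadata validated metadata with `condition`.
#' @param seed integer seed for the case draw.
#' @return A [split_spec()].
#' @examples
#' md <- data.frame(sample_id = c(sprintf("t%02d", 1:9), sprintf("h%02d", 1:3)),
#'                  condition = rep(c("case", "control"), c(9, 3)))
#' sp <- make_split(md, seed = 7)
#' length(sp$training_ids)    # 6: all 3 controls + 3 cases
#' @export
make_split <- function(metadata, seed = 1) {
  metadata <- validate_metadata(metadata)
  cases <- metadata$sample_id[metadata$condition == "case"]
  controls <- metadata$sample_id[metadata$condition == "control"]
  if (!length(controls)) stop("no control samples")
  if (length(cases) <= length(controls))
    stop("need more cases (", length(cases), ") than controls (",
         length(controls), "): the validation set would be empty")
  set.seed(seed)
  training_cases <- sample(cases, length(controls))
  split_spec(training_ids = c(controls, sort(training_cases)),
             validation_ids = sort(setdiff(cases, training_cases)),
             metadata = metadata, seed = seed)
}

#' Transform normalized counts into model-ready features
#'
#' Applies `log2(x + 1)` to the normalized counts and transposes to
#' samples-by-genes. Under the default `"log2p1_zscore"` transform each
#' gene is additionally centered and scaled to unit variance using
#' statistics computed on the training samples only; validation samples
#' reuse the training constants, so no validation information leaks into
#' any fitted object. Genes constant across the training samples get
#' scale 1 (their transformed values become 0 after centering).
#'
#' @param matrix a normalized [expression_matrix()].
#' @param split a [split_spec()]; z-scoring constants come from
#'   `split$training_ids`.
#' @param transform `"log2p1_zscore"` (default) or `"log2p1"`.
#' @return An object of class `feature_matrix`: list with `values`
#'   (samples x genes), `transform`, and the per-gene `center` / `scale`
#'   constants (zero / one for plain `"log2p1"`).
#' @export
transform_features <- function(matrix, split,
                               transform = c("log2p1_zscore", "log2p1")) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(split, "split_spec"))
  transform <- match.arg(transform)
  if (!matrix$normalized)
    stop("transform_features expects a normalized matrix")
  x <- t(log2(matrix$values + 1))        # samples x genes
  genes <- colnames(x)
  if (transform == "log2p1_zscore") {
    tr <- x[split$training_ids, , drop = FALSE]
    center <- colMeans(tr)
    scale <- apply(tr, 2L, sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
    x <- sweep(sweep(x, 2L, center, `-`), 2L, scale, `/`)
  } else {
    center <- setNames(rep(0, length(genes)), genes)
    scale <- setNames(rep(1, length(genes)), genes)
  }
  structure(list(values = x, transform = transform,
                 center = setNames(center, genes),
                 scale = setNames(scale, genes)),
            class = "feature_matrix")
}

#' Invert the log2(x+1) part of a feature transform
#'
#' @param features a `feature_matrix`.
#' @return Samples-by-genes matrix on the normalized-count scale.
#' @export
inverse_transform_features <- function(features) {
  stopifnot(inherits(features, "feature_matrix"))
  x <- features$values
  x <- sweep(sweep(x, 2L, features$scale, `*`), 2L, features$center, `+`)
  2^x - 1
}

# Subset a feature matrix to the training samples of a split, with the
# matching case/control labels; every ranker funnels through this, which
# is what keeps validation samples out of all fitted objects.
training_block <- function(features, metadata, split) {
  stopifnot(inherits(features, "feature_matrix"),
            inherits(split, "split_spec"))
  metadata <- validate_metadata(metadata)
  ids <- split$training_ids
  miss <- setdiff(ids, rownames(features$values))
  if (length(miss))
    stop("training sample(s) absent from features: ",
         paste(miss, collapse = ", "))
  labels <- setNames(metadata$condition, metadata$sample_id)[ids]
  list(x = features$values[ids, , drop = FALSE],
       y = factor(labels, levels = c("control", "case")))
}
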