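# Extreme Pseudo-Samples: a linear separator in the VAE latent space,
# the extreme (furthest-from-separator) regions of each class, balanced
# pseudo-sample generation by decoding latent draws from those regions,
# and the coefficient-based gene ranking fitted on the pseudo-samples.

#' Fit a linear class separator in latent space
#'
#' Fits a ridge-regularized logistic model on latent points and stores
#' the decision hyperplane. By convention the signed distance
#' `(w . z + b) / ||w||` is positive on the case side.
#'
#' @param z samples-by-latent matrix of latent points.
#' @param labels factor or character vector (`"case"` / `"control"`)
#'   aligned with the rows of `z`.
#' @param lambda ridge penalty of the logistic fit.
#' @return Object of class `separator`: `weights`, `intercept`,
#'   `accuracy` (training accuracy of the stored hyperplane).
#' @export
fit_separator <- function(z, labels, lambda = 1e-3) {
  stopifnot(is.matrix(z), nrow(z) == length(labels))
  labels <- factor(as.character(labels), levels = c("control", "case"))
  if (nlevels(droplevels(labels)) < 2L)
    stop("both classes must be present to fit a separator")
  if (all(apply(z, 2L, function(col) diff(range(col)) == 0)))
    stop("degenerate latent representation: all latent points identical")
  fit <- glmnet::glmnet(z, labels, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  beta <- as.numeric(coef(fit))
  w <- beta[-1L]
  b <- beta[[1L]]
  if (sqrt(sum(w^2)) == 0)
    stop("separator has zero weight vector; latent space carries no signal")
  pred <- ifelse(as.vector(z %*% w) + b > 0, "case", "control")
  structure(list(weights = w, intercept = b,
                 accuracy = mean(pred == as.character(labels))),
            class = "separator")
}

#' Signed distance to a separator
#'
#' @param separator a [fit_separator()] object.
#' @param z latent-point matrix (rows) or single vector.
#' @return Numeric vector of signed Euclidean distances to the
#'   hyperplane; positive on the case side.
#' @export
signed_distance <- function(separator, z) {
  stopifnot(inherits(separator, "separator"))
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  (as.vector(z %*% separator$weights) + separator$intercept) /
    sqrt(sum(separator$weights^2))
}

#' Identify the extreme regions of each class
#'
#' For each class, takes the samples lying on their own class's side of
#' the separator and keeps the fraction `q` with the largest absolute
#' signed distance (at least one sample): the "furthest populated area"
#' of that class. The per-class distance threshold is recorded.
#'
#' @param latent a [vae_embed()] result (uses the sampled `z`).
#' @param labels `"case"` / `"control"` labels aligned with the latent
#'   rows.
#' @param separator a [fit_separator()] object.
#' @param q fraction of correct-side samples kept per class, in `(0, 1]`;
#'   `q = 1` keeps every correct-side sample.
#' @return Object of class `extreme_regions`: per class a list with
#'   `members` (row indices into the latent matrices), `threshold`
#'   (minimum |signed distance| among members) and `side` (+1 case, -1
#'   control); the separator is carried along for downstream draws.
#' @export
find_extreme_regions <- function(latent, labels, separator, q = 0.1) {
  if (q <= 0 || q > 1) stop("q must lie in (0, 1]")
  labels <- as.character(labels)
  d <- signed_distance(separator, latent$z)
  regions <- list()
  for (cls in c("control", "case")) {
    side <- if (cls == "case") 1 else -1
    idx <- which(labels == cls & sign(d) == side)
    if (!length(idx))
      stop("class '", cls, "' has no sample on its own side of the separator")
    n_keep <- ceiling(q * length(idx))
    keep <- idx[order(-abs(d[idx]))][seq_len(n_keep)]
    regions[[cls]] <- list(members = keep,
                           threshold = min(abs(d[keep])),
                           side = side)
  }
  structure(list(regions = regions, separator = separator, q = q),
            class = "extreme_regions")
}

#' Generate balanced extreme pseudo-samples
#'
#' Draws `n_per_class` latent points per class from the extreme regions:
#' each draw picks a region member uniformly at random, samples
#' `z ~ N(mu_member, sigma_member)` from that member's posterior, and
#' rejects-and-redraws any point falling on the wrong side of the
#' separator (up to `max_attempts` per draw). All accepted points are
#' decoded deterministically into feature space. The two classes always
#' contribute exactly the same number of pseudo-samples, which is what
#' keeps the downstream coefficient fit unbiased by class imbalance.
#'
#' @param regions an [find_extreme_regions()] object.
#' @param latent the [vae_embed()] result the regions were built from.
#' @param model the [train_vae()] model used for decoding.
#' @param n_per_class pseudo-samples per class (default 400).
#' @param seed integer seed.
#' @param max_attempts rejection budget per draw.
#' @return Object of class `pseudo_sample_set`: `x` (decoded
#'   2*n_per_class-by-genes matrix), `labels`, `z` (generating latent
#'   points), `n_per_class`.
#' @export
draw_pseudo_samples <- function(regions, latent, model, n_per_class = 400,
                                seed = 1, max_attempts = 100) {
  stopifnot(inherits(regions, "extreme_regions"),
            inherits(model, "trained_vae"))
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  set.seed(seed)
  sep <- regions$separator
  z_all <- list(); lab_all <- character()
  for (cls in c("control", "case")) {
    reg <- regions$regions[[cls]]
    zc <- matrix(NA_real_, n_per_class, ncol(latent$mu))
    for (i in seq_len(n_per_class)) {
      ok <- FALSE
      for (attempt in seq_len(max_attempts)) {
        m <- reg$members[[sample.int(length(reg$members), 1L)]]
        z <- latent$mu[m, ] + latent$sigma[m, ] * rnorm(ncol(latent$mu))
        if (sign(signed_distance(sep, z)) == reg$side) { ok <- TRUE; break }
      }
      if (!ok)
        stop("rejection budget exhausted drawing class '", cls,
             "'; consider a larger q or longer VAE training")
      zc[i, ] <- z
    }
    z_all[[cls]] <- zc
    lab_all <- c(lab_all, rep(cls, n_per_class))
  }
  z <- rbind(z_all$control, z_all$case)
  x <- vae_decode(model, z)
  colnames(x) <- model$feature_names
  structure(list(x = x, labels = factor(lab_all,
                                        levels = c("control", "case")),
                 z = z, n_per_class = n_per_class),
            class = "pseudo_sample_set")
}

#' Rank genes by EPS coefficients
#'
#' Standardizes each gene across the pseudo-samples (genes constant over
#' the pseudo-samples become all-zero), fits a ridge-regularized logistic
#' model of class membership, and scores each gene by the absolute value
#' of its coefficient: with standardized features, larger coefficients
#' mean larger influence on the decision line separating extreme case
#' from extreme control pseudo-samples. Ordering is by decreasing score,
#' ties broken by gene id.
#'
#' @param pseudo a [draw_pseudo_samples()] set (balanced classes).
#' @param lambda ridge penalty; a small value keeps the fit stable when
#'   genes far outnumber pseudo-samples.
#' @return A [gene_ranking()] with method `"EPS"`.
#' @export
rank_by_eps <- function(pseudo, lambda = 1e-3) {
  stopifnot(inherits(pseudo, "pseudo_sample_set"))
  if (min(table(pseudo$labels)) < 2L)
    stop("need at least 2 pseudo-samples per class")
  x <- pseudo$x
  center <- colMeans(x)
  scale <- apply(x, 2L, sd)
  constant <- scale == 0
  scale[constant] <- 1
  xs <- sweep(sweep(x, 2L, center, `-`), 2L, scale, `/`)
  fit <- glmnet::glmnet(xs, pseudo$labels, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  score <- abs(as.numeric(coef(fit))[-1L])
  score[constant] <- 0
  rank_descending(setNames(score, colnames(x)), "EPS")
}

# Deterministic sub-seed derivation so one user seed drives the
# independent random stages (kept below 2^31 - 1).
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * k) %% 2147483647)
}

#' Run the full EPS pipeline on a dataset
#'
#' Convenience wrapper chaining the stages: train the VAE on the training
#' samples, embed them, fit the latent separator, locate the extreme
#' regions, draw balanced pseudo-samples and rank genes by the
#' coefficients of the pseudo-sample classifier. Only
#' `split$training_ids` ever reach any fitted object.
#'
#' @param features a `feature_matrix` from [transform_features()].
#' @param metadata validated metadata with `condition`.
#' @param split a [split_spec()].
#' @param arch a [vae_architecture()]; defaults to the desk preset sized
#'   to the feature count.
#' @param epochs,kl_weight,lr VAE training controls (see [train_vae()]).
#'   The pipeline default `kl_weight = 2` applies a stronger information
#'   bottleneck than bare [train_vae()]: it prunes latent directions that
#'   only memorize sample noise, which makes the decoded class contrast
#'   concentrate on genuinely discriminative genes.
#' @param q extreme-region quantile (see [find_extreme_regions()]).
#' @param n_per_class pseudo-samples per class.
#' @param seed master seed; the VAE, embedding and sampling stages use
#'   sub-seeds derived from it.
#' @return List: `ranking` (method `"EPS"`), `model`, `latent`,
#'   `separator`, `regions`, `pseudo`.
#' @export
rank_by_eps_pipeline <- function(features, metadata, split, arch = NULL,
                                 epochs = 200, kl_weight = 2, lr = 1e-3,
                                 q = 0.1, n_per_class = 400, seed = 1) {
  blk <- training_block(features, metadata, split)
  if (min(table(blk$y)) < 2L)
    stop("need at least 2 training samples per class")
  if (is.null(arch)) arch <- vae_architecture(ncol(blk$x), preset = "desk")
  model <- train_vae(blk$x, arch, epochs = epochs, kl_weight = kl_weight,
                     lr = lr, seed = sub_seed(seed, 1L))
  latent <- vae_embed(model, blk$x, seed = sub_seed(seed, 2L))
  separator <- fit_separator(latent$z, blk$y)
  regions <- find_extreme_regions(latent, blk$y, separator, q = q)
  pseudo <- draw_pseudo_samples(regions, latent, model,
                                n_per_class = n_per_class,
                                seed = sub_seed(seed, 3L))
  list(ranking = rank_by_eps(pseudo), model = model, latent = latent,
       separator = separator, regions = regions, pseudo = pseudo)
}
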