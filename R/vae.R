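# Variational autoencoder on transformed expression profiles.
#
# A deliberately compact dense implementation: configurable hidden
# nonlinearity (linear by default), a Gaussian posterior N(mu, sigma) per
# sample at the bottleneck (sigma via softplus), a deterministic decoder
# with linear output, Gaussian reconstruction likelihood (mean squared
# error) and the analytic KL(N(mu, sigma) || N(0, I)) penalty, trained
# with mini-batch Adam and reparameterized gradients. Everything is plain
# matrix algebra so a fixed seed gives bit-reproducible training on any
# platform.

#' VAE architecture presets
#'
#' Layer widths are symmetric about the bottleneck, whose width is the
#' latent dimension. The `"desk"` preset uses widths
#' `(G, 256, 64, 16, 64, 256, G)` (7 layers, 16 latent dimensions) and
#' trains in seconds-to-minutes on a single CPU. The `"full"` preset is
#' the full-scale 9-layer architecture with widths
#' `(30000, 15000, 10000, 2000, 500, 2000, 10000, 15000, 30000)` and a
#' 500-dimensional latent space; it is constructible for bookkeeping but
#' is cluster-scale to train.
#'
#' @param input_dim number of input features (genes). Ignored with a
#'   warning if `preset = "full"` (that preset fixes its own widths).
#' @param preset `"desk"` or `"full"`.
#' @param widths optional explicit width vector overriding the preset;
#'   must be symmetric with an odd length.
#' @param activation hidden-layer nonlinearity: `"linear"` (default),
#'   `"tanh"` or `"relu"`. With `"linear"` the model reduces to
#'   probabilistic PCA, which reliably captures the dominant covariance
#'   factors of small cohorts in its bottleneck; the nonlinear options
#'   suit large cohorts with pervasive class differences.
#' @return Object of class `vae_architecture` with `widths`,
#'   `latent_dim`, `n_layers`, `activation`, `preset`.
#' @export
vae_architecture <- function(input_dim = NULL, preset = c("desk", "full"),
                             widths = NULL,
                             activation = c("linear", "tanh", "relu")) {
  preset <- match.arg(preset)
  activation <- match.arg(activation)
  if (is.null(widths)) {
    widths <- switch(preset,
      desk = {
        if (is.null(input_dim)) stop("input_dim required for the desk preset")
        c(input_dim, 256L, 64L, 16L, 64L, 256L, input_dim)
      },
      full = c(30000L, 15000L, 10000L, 2000L, 500L,
                2000L, 10000L, 15000L, 30000L))
  }
  widths <- as.integer(widths)
  k <- length(widths)
  if (k %% 2L == 0L || k < 3L)
    stop("widths must have odd length >= 3 (encoder...bottleneck...decoder)")
  if (!identical(widths, rev(widths)))
    stop("widths must be symmetric about the bottleneck")
  structure(list(widths = widths, latent_dim = widths[(k + 1L) %/% 2L],
                 n_layers = k, activation = activation, preset = preset),
            class = "vae_architecture")
}

# activation function and its derivative (from pre-activation and output)
act_funs <- function(activation) {
  switch(activation,
    relu = list(f = function(a) (a > 0) * a,
                df = function(pre, out) (pre > 0) * 1),
    tanh = list(f = tanh,
                df = function(pre, out) 1 - out^2),
    linear = list(f = identity,
                  df = function(pre, out) 1))
}

relu <- function(a) (a > 0) * a
softplus <- function(a) ifelse(a > 30, a, log1p(exp(a)))
sigmoid <- function(a) 1 / (1 + exp(-a))

# KL(N(mu, diag(sigma^2)) || N(0, I)) per sample (row).
vae_kl <- function(mu, sigma) {
  0.5 * rowSums(mu^2 + sigma^2 - 1 - 2 * log(sigma))
}

new_dense <- function(fan_in, fan_out, gain = 2) {
  list(W = matrix(rnorm(fan_in * fan_out, sd = sqrt(gain / fan_in)),
                  fan_in, fan_out),
       b = rep(0, fan_out))
}

init_vae <- function(arch, seed) {
  set.seed(seed)
  hidden_gain <- if (arch$activation == "relu") 2 else 1
  w <- arch$widths
  mid <- (length(w) + 1L) %/% 2L
  enc_widths <- w[seq_len(mid - 1L)]              # input ... last hidden
  dec_widths <- w[mid:length(w)]                  # latent ... output
  enc <- list()
  for (i in seq_len(length(enc_widths) - 1L))
    enc[[i]] <- new_dense(enc_widths[i], enc_widths[i + 1L],
                          gain = hidden_gain)
  latent <- w[mid]
  last_hidden <- enc_widths[length(enc_widths)]
  dec <- list()
  for (i in seq_len(length(dec_widths) - 1L)) {
    gain <- if (i == length(dec_widths) - 1L) 1 else hidden_gain  # linear output
    dec[[i]] <- new_dense(dec_widths[i], dec_widths[i + 1L], gain = gain)
  }
  sig <- new_dense(last_hidden, latent, gain = 1)
  # start with small posterior sigma (softplus(-3) ~ 0.05) so early
  # reparameterization noise does not drown the mu gradients
  sig$b <- rep(-3, latent)
  list(enc = enc,
       mu = new_dense(last_hidden, latent, gain = 1),
       sig = sig,
       dec = dec,
       activation = arch$activation)
}

encode_pass <- function(params, x) {
  af <- act_funs(params$activation)
  h <- x; acts <- list()
  for (i in seq_along(params$enc)) {
    a <- sweep(h %*% params$enc[[i]]$W, 2L, params$enc[[i]]$b, `+`)
    h <- af$f(a)
    acts[[i]] <- list(input = if (i == 1L) x else acts[[i - 1L]]$output,
                      pre = a, output = h)
  }
  mu <- sweep(h %*% params$mu$W, 2L, params$mu$b, `+`)
  s_pre <- sweep(h %*% params$sig$W, 2L, params$sig$b, `+`)
  list(acts = acts, h = h, mu = mu, s_pre = s_pre,
       sigma = softplus(s_pre) + 1e-6)
}

decode_pass <- function(params, z) {
  af <- act_funs(params$activation)
  g <- z; acts <- list()
  nd <- length(params$dec)
  for (i in seq_len(nd)) {
    a <- sweep(g %*% params$dec[[i]]$W, 2L, params$dec[[i]]$b, `+`)
    g <- if (i < nd) af$f(a) else a
    acts[[i]] <- list(input = if (i == 1L) z else acts[[i - 1L]]$output,
                      pre = a, output = g)
  }
  list(acts = acts, xhat = g)
}

# Adam with one moment pair per parameter tensor, operating on the nested
# parameter list in place.
adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.list(p)) {
      out_p <- p
      out_s <- if (is.null(s)) vector("list", length(p)) else s
      for (i in seq_along(p)) {
        r <- walk(p[[i]], g[[i]], out_s[[i]])
        out_p[[i]] <- r$p
        out_s[i] <- list(r$s)      # [i]<-list() keeps NULL states in place
      }
      return(list(p = out_p, s = out_s))
    }
    if (!is.numeric(p)) return(list(p = p, s = s))   # e.g. activation tag
    if (is.null(s)) s <- list(m = 0 * p, v = 0 * p)
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
  }
  walk(params, grads, state)
}

# One forward + backward pass on a batch; returns the loss terms and the
# gradient list matching the parameter structure.
vae_batch_grad <- function(params, xb, w_t, eps_z = NULL) {
  nb <- nrow(xb)
  en <- encode_pass(params, xb)
  if (is.null(eps_z))
    eps_z <- matrix(rnorm(nb * ncol(en$mu)), nb, ncol(en$mu))
  z <- en$mu + en$sigma * eps_z
  de <- decode_pass(params, z)

  resid <- de$xhat - xb
  recon <- 0.5 * sum(resid^2) / nb
  kl <- sum(vae_kl(en$mu, en$sigma)) / nb

  af <- act_funs(params$activation)
  grads <- list(enc = vector("list", length(params$enc)),
                mu = NULL, sig = NULL,
                dec = vector("list", length(params$dec)),
                activation = params$activation)
  delta <- resid / nb                      # d loss / d xhat
  for (i in rev(seq_along(params$dec))) {
    act <- de$acts[[i]]
    if (i < length(params$dec)) delta <- delta * af$df(act$pre, act$output)
    grads$dec[[i]] <- list(W = crossprod(act$input, delta),
                           b = colSums(delta))
    delta <- delta %*% t(params$dec[[i]]$W)
  }
  dz <- delta
  dmu <- dz + w_t * en$mu / nb
  dsigma <- dz * eps_z + w_t * (en$sigma - 1 / en$sigma) / nb
  ds_pre <- dsigma * sigmoid(en$s_pre)
  grads$mu <- list(W = crossprod(en$h, dmu), b = colSums(dmu))
  grads$sig <- list(W = crossprod(en$h, ds_pre), b = colSums(ds_pre))
  delta <- dmu %*% t(params$mu$W) + ds_pre %*% t(params$sig$W)
  for (i in rev(seq_along(params$enc))) {
    act <- en$acts[[i]]
    delta <- delta * af$df(act$pre, act$output)
    grads$enc[[i]] <- list(W = crossprod(act$input, delta),
                           b = colSums(delta))
    delta <- delta %*% t(params$enc[[i]]$W)
  }
  list(recon = recon, kl = kl, grads = grads)
}

#' Train a variational autoencoder
#'
#' Minimizes `mean_i [ 0.5 * ||x_i - xhat_i||^2 + w_t * kl_weight *
#' KL(N(mu_i, sigma_i) || N(0, I)) ]` over the supplied samples by
#' mini-batch Adam with reparameterized gradients. The KL weight `w_t`
#' is warmed up linearly over the first 10% of epochs to avoid posterior
#' collapse on small cohorts. Training is bit-reproducible for a fixed
#' seed.
#'
#' @param x samples-by-genes numeric matrix of transformed features
#'   (training samples only), or a `feature_matrix`.
#' @param arch a [vae_architecture()]; its input width must equal
#'   `ncol(x)`.
#' @param epochs number of passes over the data.
#' @param kl_weight weight of the KL term after warm-up.
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size; batches are reshuffled every epoch.
#'   Use `Inf` for full-batch training.
#' @param seed integer seed (initialization, batch shuffling and
#'   reparameterization noise).
#' @return Object of class `trained_vae`: `params`, `arch`, and `history`
#'   (data frame `epoch`, `recon`, `kl`, the two loss terms averaged per
#'   epoch).
#' @export
train_vae <- function(x, arch, epochs = 150, kl_weight = 1, lr = 1e-3,
                      batch_size = 32, seed = 1) {
  if (inherits(x, "feature_matrix")) x <- x$values
  stopifnot(is.matrix(x), is.numeric(x))
  if (ncol(x) != arch$widths[1L])
    stop("architecture input width (", arch$widths[1L],
         ") does not match feature count (", ncol(x), ")")
  if (epochs < 1) stop("epochs must be >= 1")
  n <- nrow(x)
  batch_size <- min(batch_size, n)
  params <- init_vae(arch, seed)
  state <- NULL
  warm <- max(1L, ceiling(0.1 * epochs))
  history <- data.frame(epoch = seq_len(epochs), recon = NA_real_,
                        kl = NA_real_)
  step <- 0L

  for (epoch in seq_len(epochs)) {
    w_t <- kl_weight * min(1, epoch / warm)
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    recon_sum <- 0; kl_sum <- 0
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      bg <- vae_batch_grad(params, x[idx, , drop = FALSE], w_t)
      if (!is.finite(bg$recon) || !is.finite(bg$kl))
        stop("non-finite VAE loss at epoch ", epoch,
             " (recon=", bg$recon, ", kl=", bg$kl,
             "); lower the learning rate")
      recon_sum <- recon_sum + bg$recon * length(idx)
      kl_sum <- kl_sum + bg$kl * length(idx)
      step <- step + 1L
      upd <- adam_step(params, bg$grads, state, lr, step)
      params <- upd$p
      state <- upd$s
    }
    history$recon[epoch] <- recon_sum / n
    history$kl[epoch] <- kl_sum / n
  }
  structure(list(params = params, arch = arch, history = history,
                 feature_names = colnames(x)),
            class = "trained_vae")
}

#' Embed samples into the VAE latent space
#'
#' Returns the Gaussian posterior parameters `mu` and `sigma` (both
#' deterministic given the model) and one sampled latent point `z` per
#' sample, drawn as `mu + sigma * eps` with `eps ~ N(0, I)`.
#'
#' @param model a [train_vae()] fit.
#' @param x samples-by-genes matrix in the training feature space, or a
#'   `feature_matrix`.
#' @param seed optional integer seed for the `z` draw; without it, `z`
#'   varies from call to call while `mu` and `sigma` do not.
#' @return List `mu`, `sigma`, `z` (matrices, samples x latent_dim).
#' @export
vae_embed <- function(model, x, seed = NULL) {
  stopifnot(inherits(model, "trained_vae"))
  if (inherits(x, "feature_matrix")) x <- x$values
  if (ncol(x) != model$arch$widths[1L])
    stop("feature dimension (", ncol(x), ") does not match the model input (",
         model$arch$widths[1L], ")")
  en <- encode_pass(model$params, x)
  if (!is.null(seed)) set.seed(seed)
  eps_z <- matrix(rnorm(nrow(x) * ncol(en$mu)), nrow(x), ncol(en$mu))
  z <- en$mu + en$sigma * eps_z
  rn <- rownames(x)
  dimnames(z) <- dimnames(en$mu) <- dimnames(en$sigma) <- list(rn, NULL)
  list(mu = en$mu, sigma = en$sigma, z = z)
}

#' Decode latent points into feature space
#'
#' The decoder is deterministic: a latent point always reconstructs the
#' same feature-space vector.
#'
#' @param model a [train_vae()] fit.
#' @param z matrix of latent points (rows) of width `latent_dim`.
#' @return Matrix of decoded feature-space vectors, one row per point.
#' @export
vae_decode <- function(model, z) {
  stopifnot(inherits(model, "trained_vae"))
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  if (ncol(z) != model$arch$latent_dim)
    stop("latent dimension mismatch")
  decode_pass(model$params, z)$xhat
}
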