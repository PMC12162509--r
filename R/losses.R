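# Composite segmentation loss: batch Dice over the three region channels,
# paired with binary cross-entropy or focal loss, combined as
# alpha * dice + (1 - alpha) * secondary, aggregated over deep-supervision
# heads as a normalized weighted sum.  All losses are built once on autograd
# tensors; the exported array API wraps inputs as constants and reads the
# scalar value, so training and evaluation share one implementation.

#' Loss configuration
#'
#' @param alpha Dice weight of the composite loss, in \[0, 1\] (default 0.7,
#'   the optimum of the 0.5-0.8 sweep).
#' @param secondary secondary term: \code{"focal"} or \code{"bce"}.
#' @param gamma focal exponent (default 2; \code{gamma = 0} reduces focal to
#'   binary cross-entropy).
#' @param smooth Dice stabilizer added to numerator and denominator
#'   (default 1e-5).
#' @param batch_dice pool the Dice sums over all batch items jointly
#'   (default) instead of averaging per-item Dice.
#' @param head_weights non-negative deep-supervision head weights, final
#'   head first; \code{NULL} = equal weights.
#' @param vae_weight_rec,vae_weight_kl reconstruction / KL weights of the
#'   autoencoder regularizer (\code{ae_unet} only).
#' @param clamp_eps probability clamp for the logarithms (1e-7).
#' @return An object of class \code{loss_config}.
#' @export
loss_config <- function(alpha = 0.7, secondary = c("focal", "bce"), gamma = 2,
                        smooth = 1e-5, batch_dice = TRUE, head_weights = NULL,
                        vae_weight_rec = 0.1, vae_weight_kl = 0.1,
                        clamp_eps = 1e-7) {
  secondary <- match.arg(secondary)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (gamma < 0) stop("gamma must be >= 0")
  if (smooth <= 0) stop("smooth must be > 0")
  if (!is.null(head_weights)) {
    if (any(head_weights < 0) || all(head_weights == 0)) {
      stop("head_weights must be >= 0 and not all zero")
    }
  }
  structure(list(alpha = alpha, secondary = secondary, gamma = gamma,
                 smooth = smooth, batch_dice = isTRUE(batch_dice),
                 head_weights = head_weights,
                 vae_weight_rec = vae_weight_rec, vae_weight_kl = vae_weight_kl,
                 clamp_eps = clamp_eps),
            class = "loss_config")
}

# normalize probs/targets to parallel batch lists
.as_batch <- function(x) if (is.list(x)) x else list(x)

.check_pair <- function(p, t) {
  if (!identical(dim(p), dim(t))) stop("probability/target shape mismatch")
  if (min(p) < 0 || max(p) > 1) stop("probabilities must lie in [0, 1]")
}

# graph builders -------------------------------------------------------------

.dice_loss_graph <- function(probs, targets, config) {
  nb <- length(probs)
  nch <- dim(targets[[1]])[1]
  per_channel <- vector("list", nch)
  for (ch in seq_len(nch)) {
    tch <- lapply(targets, function(t) matrix(t, nrow = nch)[ch, ])
    pch <- lapply(probs, function(p) ag_channel(p, ch))
    if (config$batch_dice) {
      inter <- Reduce(ag_add, Map(ag_dot_const, pch, tch))
      psum <- Reduce(ag_add, lapply(pch, ag_sum))
      tsum <- sum(vapply(tch, sum, numeric(1)))
      num <- ag_affine(inter, 2, config$smooth)
      den <- ag_affine(psum, 1, tsum + config$smooth)
      per_channel[[ch]] <- ag_affine(ag_div(num, den), -1, 1)
    } else {
      items <- Map(function(p, t) {
        num <- ag_affine(ag_dot_const(p, t), 2, config$smooth)
        den <- ag_affine(ag_sum(p), 1, sum(t) + config$smooth)
        ag_affine(ag_div(num, den), -1, 1)
      }, pch, tch)
      per_channel[[ch]] <- ag_scale(Reduce(ag_add, items), 1 / nb)
    }
  }
  ag_scale(Reduce(ag_add, per_channel), 1 / nch)
}

.secondary_loss_graph <- function(probs, targets, config) {
  gamma <- if (config$secondary == "bce") 0 else config$gamma
  eps <- config$clamp_eps
  total_n <- sum(vapply(probs, function(p) length(p$value), numeric(1)))
  terms <- Map(function(p, t) {
    a <- 2 * t - 1                      # p_t = t*p + (1-t)*(1-p)
    pt <- ag_clamp(ag_affine(p, a, 1 - t), eps, 1 - eps)
    lg <- ag_log(pt)
    if (gamma == 0) ag_sum(lg)
    else ag_sum(ag_mul(ag_pow_const(ag_affine(pt, -1, 1), gamma), lg))
  }, probs, targets)
  ag_scale(Reduce(ag_add, terms), -1 / total_n)
}

.combined_loss_graph <- function(probs, targets, config) {
  ag_add(ag_scale(.dice_loss_graph(probs, targets, config), config$alpha),
         ag_scale(.secondary_loss_graph(probs, targets, config), 1 - config$alpha))
}

.deep_supervision_loss_graph <- function(heads_batch, targets, config) {
  n_heads <- length(heads_batch[[1]])
  w <- config$head_weights %||% rep(1, n_heads)
  if (length(w) != n_heads) stop("head_weights length must match head count")
  per_head <- vector("list", n_heads)
  for (a in seq_len(n_heads)) {
    if (w[a] == 0) next
    ta <- lapply(targets, downsample_regions_nn, factor = 2^(a - 1))
    pa <- lapply(heads_batch, `[[`, a)
    per_head[[a]] <- ag_scale(.combined_loss_graph(pa, ta, config), w[a])
  }
  ag_scale(Reduce(ag_add, Filter(Negate(is.null), per_head)), 1 / sum(w))
}

.vae_loss_graph <- function(recon, input_volume, mu, log_var, config) {
  if (any(!is.finite(mu$value)) || any(!is.finite(log_var$value))) {
    stop("non-finite VAE latent statistics")
  }
  diff <- ag_affine(recon, 1, -input_volume)
  rec <- ag_mean(ag_pow_const(diff, 2))
  k <- ag_add(ag_add(ag_sum(ag_pow_const(mu, 2)), ag_sum(ag_exp(log_var))),
              ag_affine(ag_sum(log_var), -1, -length(mu$value)))
  kl <- ag_scale(k, 0.5)
  ag_add(ag_scale(rec, config$vae_weight_rec), ag_scale(kl, config$vae_weight_kl))
}

# array API -------------------------------------------------------------------

.loss_value <- function(builder, probs, targets, config) {
  probs <- .as_batch(probs)
  targets <- .as_batch(targets)
  Map(.check_pair, lapply(probs, identity), targets)
  pt <- lapply(probs, ag_const)
  builder(pt, targets, config)$value
}

#' Batch Dice loss over the region channels
#'
#' Per channel c: \code{1 - (2*sum(p*t) + s) / (sum(p) + sum(t) + s)}, with
#' sums pooled over all batch items and voxels jointly (batch form) or per
#' item then averaged; the returned value is the mean over the three region
#' channels and lies in \[0, 1\].
#'
#' @param probs probability array (3, D, H, W) or list of such (a batch).
#' @param targets matching binary region mask(s).
#' @param config a \code{loss_config}.
#' @return Scalar loss.
#' @export
dice_loss <- function(probs, targets, config = loss_config()) {
  .loss_value(.dice_loss_graph, probs, targets, config)
}

#' Secondary loss: binary cross-entropy or focal
#'
#' Mean over all voxels and channels of \code{-(1 - p_t)^gamma * log(p_t)},
#' with \code{p_t = p} where the target is 1 and \code{1 - p} elsewhere;
#' \code{gamma = 0} (and the \code{"bce"} setting) gives plain binary
#' cross-entropy.  Probabilities are clamped away from 0 and 1.
#'
#' @inheritParams dice_loss
#' @return Scalar loss, >= 0.
#' @export
secondary_loss <- function(probs, targets, config = loss_config()) {
  .loss_value(.secondary_loss_graph, probs, targets, config)
}

#' Composite segmentation loss
#'
#' Convex combination \code{alpha * dice_loss + (1 - alpha) * secondary_loss}.
#'
#' @inheritParams dice_loss
#' @return Scalar loss.
#' @export
combined_loss <- function(probs, targets, config = loss_config()) {
  .loss_value(.combined_loss_graph, probs, targets, config)
}

#' Deep-supervision loss
#'
#' Normalized weighted sum of the composite loss over the output heads;
#' head A (1 = final, full resolution) is scored against the region target
#' downsampled by nearest neighbor with factor \code{2^(A-1)}.
#'
#' @param heads list of head probability arrays, full resolution first; or a
#'   batch: list of such lists.
#' @param targets full-resolution region mask (3, D, H, W), or list of masks
#'   for a batch.
#' @param config a \code{loss_config}.
#' @return Scalar loss.
#' @export
deep_supervision_loss <- function(heads, targets, config = loss_config()) {
  batch <- if (is.list(heads[[1]])) heads else list(heads)
  targets <- .as_batch(targets)
  hb <- lapply(batch, function(item) lapply(item, ag_const))
  .deep_supervision_loss_graph(hb, targets, config)$value
}

#' Autoencoder regularization loss
#'
#' Weighted sum of the mean squared reconstruction error and the closed-form
#' KL divergence of the diagonal Gaussian latent from the standard normal.
#'
#' @param reconstruction reconstructed input array (C, D, H, W).
#' @param input_volume original input array.
#' @param mu,log_var latent mean and log-variance vectors.
#' @param config a \code{loss_config}.
#' @return Scalar loss.
#' @export
vae_loss <- function(reconstruction, input_volume, mu, log_var,
                     config = loss_config()) {
  .vae_loss_graph(ag_const(reconstruction), input_volume,
                  ag_const(mu), ag_const(log_var), config)$value
}
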