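# Whole-volume prediction: half-overlap sliding windows with Gaussian
# center weighting, and eight-flip test-time augmentation.

#' Plan sliding windows over a volume
#'
#' Window origins are laid out per axis at multiples of the stride (half
#' the patch by default), with the final origin clamped so the last window
#' ends exactly at the volume boundary; every voxel is covered by at least
#' one window.  Volumes smaller than the patch are padded symmetrically
#' with zeros and the padding recorded for crop-back.
#'
#' @param volume_shape spatial extent (length 3).
#' @param patch_size patch extent per axis (scalar or length 3).
#' @param stride window stride; default half the patch.
#' @return An object of class \code{sliding_window_plan}: patch_size,
#'   stride, 0-based \code{origins} matrix (one row per window),
#'   \code{padded_shape}, \code{pad_lo}, \code{orig_shape}.
#' @export
plan_windows <- function(volume_shape, patch_size, stride = NULL) {
  volume_shape <- as.integer(rep(volume_shape, length.out = 3L))
  patch_size <- as.integer(rep(patch_size, length.out = 3L))
  if (is.null(stride)) stride <- pmax(patch_size %/% 2L, 1L)
  stride <- as.integer(rep(stride, length.out = 3L))
  padded <- pmax(volume_shape, patch_size)
  pad_lo <- (padded - volume_shape) %/% 2L
  axis_origins <- lapply(1:3, function(a) {
    last <- padded[a] - patch_size[a]
    if (last == 0L) return(0L)
    o <- seq.int(0L, last, by = stride[a])
    if (o[length(o)] != last) o <- c(o, last)
    o
  })
  grid <- as.matrix(expand.grid(axis_origins))
  dimnames(grid) <- NULL
  structure(list(patch_size = patch_size, stride = stride,
                 origins = grid, padded_shape = padded,
                 pad_lo = pad_lo, orig_shape = volume_shape),
            class = "sliding_window_plan")
}

#' Patch importance map for overlap averaging
#'
#' Gaussian weights centered on the patch (sigma = extent * sigma_fraction
#' per axis, default 1/8), floored at a small positive value so every voxel
#' keeps nonzero weight; or uniform weights.
#'
#' @param patch_size patch extent (scalar or length 3).
#' @param kind \code{"gaussian"} or \code{"uniform"}.
#' @param sigma_fraction Gaussian width as a fraction of the patch extent.
#' @param floor lower bound on the (peak-1) weights.
#' @return Positive 3D weight array of patch shape.
#' @export
importance_map <- function(patch_size, kind = c("gaussian", "uniform"),
                           sigma_fraction = 1 / 8, floor = 1e-3) {
  kind <- match.arg(kind)
  patch_size <- as.integer(rep(patch_size, length.out = 3L))
  if (kind == "uniform") return(array(1, dim = patch_size))
  ax <- lapply(1:3, function(a) {
    n <- patch_size[a]
    c0 <- (n + 1) / 2
    s <- max(n * sigma_fraction, 1e-8)
    exp(-0.5 * ((seq_len(n) - c0) / s)^2)
  })
  w <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
  pmax(w / max(w), floor)
}

.as_predictor <- function(net) {
  if (inherits(net, "resunet3d_model")) {
    function(patch) predict_patch(net, patch)
  } else if (is.function(net)) net
  else stop("net must be a resunet3d_model or a function(patch) -> probs")
}

#' Sliding-window prediction of region probabilities
#'
#' Runs the network on every planned window and combines overlapping
#' predictions as the importance-weighted mean, so each output voxel is
#' sum(w * p) / sum(w) over the windows covering it.
#'
#' @param net a \code{resunet3d_model}, or any function mapping a 4D patch
#'   (C, d, h, w) to a (3, d, h, w) probability array.
#' @param volume 4D input array (C, D, H, W).
#' @param plan a \code{sliding_window_plan}; default planned from the
#'   volume shape and \code{patch_size}.
#' @param importance 3D weight array of patch shape; default Gaussian.
#' @param patch_size used when \code{plan} is NULL.
#' @return 4D probability array (3, D, H, W) on the original extent.
#' @export
sliding_window_predict <- function(net, volume, plan = NULL, importance = NULL,
                                   patch_size = NULL) {
  predictor <- .as_predictor(net)
  d <- dim(volume)
  if (length(d) != 4L) stop("volume must be a 4D (C,D,H,W) array")
  if (is.null(plan)) {
    if (is.null(patch_size)) stop("either plan or patch_size must be given")
    plan <- plan_windows(d[-1], patch_size)
  }
  if (!all(plan$orig_shape == d[-1])) stop("plan does not match volume shape")
  ps <- plan$patch_size
  if (is.null(importance)) importance <- importance_map(ps)
  if (any(dim(importance) != ps) || any(importance <= 0)) {
    stop("importance must be a positive array of patch shape")
  }
  padded <- plan$padded_shape
  lo <- plan$pad_lo
  vol <- volume
  if (any(padded != d[-1])) {
    vol <- array(0, dim = c(d[1], padded))
    vol[, lo[1] + seq_len(d[2]), lo[2] + seq_len(d[3]), lo[3] + seq_len(d[4])] <- volume
  }
  nch <- NULL
  num <- NULL
  den <- array(0, dim = padded)
  for (i in seq_len(nrow(plan$origins))) {
    o <- plan$origins[i, ]
    ix <- lapply(1:3, function(a) o[a] + seq_len(ps[a]))
    patch <- vol[, ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
    p <- predictor(patch)
    if (any(!is.finite(p))) stop("non-finite network output in window ", i)
    if (is.null(num)) {
      nch <- dim(p)[1]
      num <- array(0, dim = c(nch, padded))
    }
    wrep <- rep(as.numeric(importance), each = nch)
    num[, ix[[1]], ix[[2]], ix[[3]]] <-
      num[, ix[[1]], ix[[2]], ix[[3]]] + as.numeric(p) * wrep
    den[ix[[1]], ix[[2]], ix[[3]]] <- den[ix[[1]], ix[[2]], ix[[3]]] + importance
  }
  out <- num / rep(as.numeric(den), each = nch)
  dim(out) <- c(nch, padded)
  out[, lo[1] + seq_len(d[2]), lo[2] + seq_len(d[3]), lo[3] + seq_len(d[4]),
      drop = FALSE]
}

# the 8 axis-flip combinations (identity first)
.flip_set <- function() as.matrix(expand.grid(d1 = c(FALSE, TRUE),
                                              d2 = c(FALSE, TRUE),
                                              d3 = c(FALSE, TRUE)))

.flip4d <- function(x, flips) {
  d <- dim(x)
  ix <- lapply(1:3, function(a) if (flips[a]) rev(seq_len(d[a + 1])) else seq_len(d[a + 1]))
  x[, ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

#' Test-time augmentation over the eight axis flips
#'
#' Flips the input volume along each of the 8 subsets of the three spatial
#' axes, runs sliding-window prediction on each variant, un-flips the
#' predictions, and averages the probabilities.
#'
#' @inheritParams sliding_window_predict
#' @return 4D probability array (3, D, H, W).
#' @export
tta_predict <- function(net, volume, plan = NULL, importance = NULL,
                        patch_size = NULL) {
  flips <- .flip_set()
  acc <- NULL
  for (i in seq_len(nrow(flips))) {
    f <- flips[i, ]
    p <- sliding_window_predict(net, .flip4d(volume, f), plan = plan,
                                importance = importance,
                                patch_size = patch_size)
    p <- .flip4d(p, f)
    acc <- if (is.null(acc)) p else acc + p
  }
  acc / nrow(flips)
}
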