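# Architecture family: plain, residual, attention-gated and
# autoencoder-regularized 3D U-Nets with deep-supervision output heads.
#
# Every conv block is kernel 3^3 (stride 1 or 2, zero padding 1), instance
# normalization, leaky ReLU (slope 0.01).  Downsampling is by stride-2
# convolution; upsampling by kernel-2/stride-2 transposed convolution
# followed by concatenation with the same-level encoder skip and a stride-1
# block.  Output heads are 1x1x1 convolutions + sigmoid over the three
# region channels (WT, TC, ET), attached to the last `n_heads` decoder
# levels when deep supervision is on.

#' Network configuration
#'
#' Declarative description of an architecture variant; fully determines the
#' parameter set and all output-head shapes.
#'
#' @param variant one of \code{"unet"}, \code{"res_unet"},
#'   \code{"attention_unet"}, \code{"ae_unet"} (residual encoder plus a
#'   variational autoencoder branch that reconstructs the input from the
#'   bottleneck as a regularizer).
#' @param depth number of encoder levels (default 7).
#' @param base_channels channels at the first level (default 64).
#' @param channel_cap ceiling on the channel schedule (default 512).
#' @param in_channels input channels: 4 modalities, or 5 with the
#'   salient-voxel foreground channel.
#' @param out_channels region channels (3: WT, TC, ET).
#' @param deep_supervision attach auxiliary heads at coarser decoder levels.
#' @param n_heads number of output heads; defaults to \code{min(3, depth-1)}
#'   under deep supervision, else 1.
#' @param negative_slope leaky ReLU slope (0.01).
#' @param latent_dim VAE latent dimension (256; \code{ae_unet} only).
#' @param input_size spatial input extent (per axis) the \code{ae_unet}
#'   dense layers are sized for; ignored by other variants.
#' @return An object of class \code{network_config}.
#' @export
network_config <- function(variant = c("res_unet", "unet", "attention_unet", "ae_unet"),
                           depth = 7L, base_channels = 64L, channel_cap = 512L,
                           in_channels = 4L, out_channels = 3L,
                           deep_supervision = TRUE, n_heads = NULL,
                           negative_slope = 0.01, latent_dim = 256L,
                           input_size = c(128L, 128L, 128L)) {
  variant <- match.arg(variant)
  depth <- as.integer(depth)
  if (depth < 2L) stop("depth must be >= 2")
  if (base_channels < 1L || channel_cap < base_channels) {
    stop("need 1 <= base_channels <= channel_cap")
  }
  if (is.null(n_heads)) n_heads <- if (deep_supervision) min(3L, depth - 1L) else 1L
  n_heads <- as.integer(n_heads)
  if (n_heads < 1L || n_heads > depth - 1L) stop("n_heads must be in [1, depth-1]")
  cfg <- list(variant = variant, depth = depth,
              base_channels = as.integer(base_channels),
              channel_cap = as.integer(channel_cap),
              in_channels = as.integer(in_channels),
              out_channels = as.integer(out_channels),
              deep_supervision = isTRUE(deep_supervision),
              n_heads = n_heads, negative_slope = negative_slope,
              latent_dim = as.integer(latent_dim),
              input_size = as.integer(rep(input_size, length.out = 3L)))
  class(cfg) <- "network_config"
  cfg
}

#' Channel schedule of an encoder
#'
#' Channels double per level from \code{base_channels}, capped at
#' \code{channel_cap}: level l has \code{min(base * 2^l, cap)} channels.
#' The default configuration gives 64, 128, 256, 512, 512, 512, 512; a
#' depth-6 encoder with base 32 and cap 320 gives the 32..320 progression of
#' the smaller baseline.
#'
#' @param config a \code{network_config}.
#' @return Integer vector of length \code{depth}.
#' @export
channel_schedule <- function(config) {
  vapply(seq_len(config$depth) - 1L,
         function(l) as.integer(min(config$base_channels * 2^l, config$channel_cap)),
         integer(1))
}

.he_init <- function(n, fan_in) rnorm(n, 0, sqrt(2 / fan_in))

# parameter builders ---------------------------------------------------------

.add_conv <- function(params, name, Cout, Cin, k, norm = TRUE) {
  # rectified blocks use He gain 2; purely linear layers (projection
  # shortcuts, output heads) use gain 1 so residual chains do not inflate
  gain <- if (norm) 2 else 1
  params[[paste0(name, ".W")]] <-
    matrix(rnorm(Cout * Cin * k^3, 0, sqrt(gain / (Cin * k^3))), nrow = Cout)
  params[[paste0(name, ".b")]] <- numeric(Cout)
  if (norm) {
    params[[paste0(name, ".g")]] <- rep(1, Cout)
    params[[paste0(name, ".be")]] <- numeric(Cout)
  }
  params
}

.add_tconv <- function(params, name, Cin, Cout) {
  params[[paste0(name, ".W")]] <-
    matrix(.he_init(Cin * Cout * 8L, Cin * 8L), nrow = Cin)
  params[[paste0(name, ".b")]] <- numeric(Cout)
  params
}

.add_dense <- function(params, name, nout, nin) {
  params[[paste0(name, ".W")]] <- matrix(.he_init(nout * nin, nin), nrow = nout)
  params[[paste0(name, ".b")]] <- numeric(nout)
  params
}

.is_residual <- function(config) config$variant %in% c("res_unet", "ae_unet")

.divisor <- function(config) 2L^(config$depth - 1L)

# padded spatial extent the ae_unet dense layers are sized for
.ae_bottleneck_dims <- function(config) {
  need <- .divisor(config)
  padded <- as.integer(ceiling(config$input_size / need) * need)
  as.integer(padded / need)
}

#' Build a network
#'
#' Instantiates the parameter set of a configuration with He-normal
#' initialization.  Construction is deterministic given \code{seed}.
#'
#' @param config a \code{network_config}.
#' @param seed integer seed for weight initialization.
#' @return An object of class \code{resunet3d_model}: list with
#'   \code{config} and the named parameter list \code{params}.
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  set.seed(as.integer(seed))
  sched <- channel_schedule(config)
  depth <- config$depth
  p <- list()
  for (l in seq_len(depth) - 1L) {
    cin <- if (l == 0L) config$in_channels else sched[l]
    cout <- sched[l + 1L]
    p <- .add_conv(p, sprintf("enc%d.a", l), cout, cin, 3L)
    p <- .add_conv(p, sprintf("enc%d.b", l), cout, cout, 3L)
    if (.is_residual(config) && (cin != cout || l > 0L)) {
      # 1x1x1 projection shortcut (strided on downsampling levels)
      p <- .add_conv(p, sprintf("enc%d.sc", l), cout, cin, 1L, norm = FALSE)
    }
  }
  for (l in (depth - 2L):0L) {
    ch <- sched[l + 1L]
    p <- .add_tconv(p, sprintf("dec%d.up", l), sched[l + 2L], ch)
    p <- .add_conv(p, sprintf("dec%d.c", l), ch, 2L * ch, 3L)
    if (.is_residual(config)) {
      p <- .add_conv(p, sprintf("dec%d.sc", l), ch, 2L * ch, 1L, norm = FALSE)
    }
    if (config$variant == "attention_unet") {
      fint <- max(1L, ch %/% 2L)
      p <- .add_conv(p, sprintf("dec%d.att.wx", l), fint, ch, 1L, norm = FALSE)
      p <- .add_conv(p, sprintf("dec%d.att.wg", l), fint, sched[l + 2L], 1L, norm = FALSE)
      p <- .add_conv(p, sprintf("dec%d.att.psi", l), 1L, fint, 1L, norm = FALSE)
    }
  }
  for (a in seq_len(config$n_heads)) {
    p <- .add_conv(p, sprintf("head%d", a), config$out_channels, sched[a], 1L,
                   norm = FALSE)
  }
  if (config$variant == "ae_unet") {
    e <- .ae_bottleneck_dims(config)
    nflat <- 16L * prod(e)
    cb <- sched[depth]
    p <- .add_conv(p, "vae.red", 16L, cb, 1L, norm = FALSE)
    p <- .add_dense(p, "vae.mu", config$latent_dim, nflat)
    p <- .add_dense(p, "vae.lv", config$latent_dim, nflat)
    p <- .add_dense(p, "vae.fc", nflat, config$latent_dim)
    p <- .add_conv(p, "vae.exp", cb, 16L, 1L, norm = FALSE)
    for (l in (depth - 1L):1L) {
      p <- .add_tconv(p, sprintf("vae.up%d", l), sched[l + 1L], sched[l])
    }
    p <- .add_conv(p, "vae.out", config$in_channels, sched[1], 1L, norm = FALSE)
  }
  structure(list(config = config, params = p), class = "resunet3d_model")
}

# forward graph --------------------------------------------------------------

.param_tensors <- function(params) lapply(params, ag_param)

# Symmetric zero padding of a (C,D,H,W) array up to divisibility by `need`.
.pad_volume <- function(x, need) {
  d <- dim(x)
  sp <- d[-1]
  target <- as.integer(ceiling(sp / need) * need)
  lo <- (target - sp) %/% 2L
  if (all(target == sp)) return(list(x = x, lo = c(0L, 0L, 0L), orig = sp))
  out <- array(0, dim = c(d[1], target))
  out[, lo[1] + seq_len(sp[1]), lo[2] + seq_len(sp[2]), lo[3] + seq_len(sp[3])] <- x
  list(x = out, lo = lo, orig = sp)
}

.crop_head <- function(value, lo, orig, f) {
  start <- floor(lo / f)
  len <- ceiling(orig / f)
  value[, start[1] + seq_len(len[1]), start[2] + seq_len(len[2]),
        start[3] + seq_len(len[3]), drop = FALSE]
}

# Forward pass over autograd tensors.  `pt` is the named list of parameter
# tensors; `x` an ag tensor holding a padded (C,D,H,W) input.  Returns head
# probability tensors (index 1 = full resolution) and the VAE branch
# outputs for the ae_unet variant.
.forward_graph <- function(config, pt, x) {
  slope <- config$negative_slope
  cb <- function(prefix, h, stride) {
    ag_leaky_relu(
      ag_instance_norm(
        ag_conv3d(h, pt[[paste0(prefix, ".W")]], pt[[paste0(prefix, ".b")]],
                  3L, stride, 1L),
        pt[[paste0(prefix, ".g")]], pt[[paste0(prefix, ".be")]]),
      slope)
  }
  conv1 <- function(prefix, h, stride = 1L) {
    ag_conv3d(h, pt[[paste0(prefix, ".W")]], pt[[paste0(prefix, ".b")]],
              1L, stride, 0L)
  }
  residual <- .is_residual(config)
  depth <- config$depth
  skips <- vector("list", depth)
  h <- x
  for (l in seq_len(depth) - 1L) {
    stride <- if (l == 0L) 1L else 2L
    out <- cb(sprintf("enc%d.b", l), cb(sprintf("enc%d.a", l), h, stride), 1L)
    if (residual) {
      scn <- sprintf("enc%d.sc", l)
      sc <- if (!is.null(pt[[paste0(scn, ".W")]])) conv1(scn, h, stride) else h
      out <- ag_add(out, sc)
    }
    h <- out
    skips[[l + 1L]] <- h
  }
  vae <- NULL
  if (config$variant == "ae_unet") {
    red <- ag_leaky_relu(conv1("vae.red", h), slope)
    nflat <- length(red$value)
    flat <- ag_reshape(red, nflat)
    mu <- ag_dense(flat, pt[["vae.mu.W"]], pt[["vae.mu.b"]])
    lv <- ag_dense(flat, pt[["vae.lv.W"]], pt[["vae.lv.b"]])
    eps <- rnorm(config$latent_dim)
    z <- ag_add(mu, ag_affine(ag_exp(ag_scale(lv, 0.5)), eps))
    r <- ag_leaky_relu(ag_dense(z, pt[["vae.fc.W"]], pt[["vae.fc.b"]]), slope)
    r <- ag_reshape(r, c(16L, dim(red$value)[-1]))
    r <- ag_leaky_relu(conv1("vae.exp", r), slope)
    for (l in (depth - 1L):1L) {
      r <- ag_leaky_relu(
        ag_tconv3d(r, pt[[sprintf("vae.up%d.W", l)]], pt[[sprintf("vae.up%d.b", l)]]),
        slope)
    }
    vae <- list(recon = conv1("vae.out", r), mu = mu, log_var = lv, eps = eps)
  }
  heads <- vector("list", config$n_heads)
  g <- h
  for (l in (depth - 2L):0L) {
    up <- ag_tconv3d(g, pt[[sprintf("dec%d.up.W", l)]], pt[[sprintf("dec%d.up.b", l)]])
    skip <- skips[[l + 1L]]
    if (config$variant == "attention_unet") {
      pre <- sprintf("dec%d.att", l)
      ga <- ag_upsample2(conv1(paste0(pre, ".wg"), g))
      sa <- conv1(paste0(pre, ".wx"), skip)
      alpha <- ag_sigmoid(conv1(paste0(pre, ".psi"),
                                ag_leaky_relu(ag_add(ga, sa), slope)))
      skip <- ag_mul_broadcast(skip, alpha)
    }
    cat_ <- ag_concat_channels(up, skip)
    out <- cb(sprintf("dec%d.c", l), cat_, 1L)
    if (residual) out <- ag_add(out, conv1(sprintf("dec%d.sc", l), cat_))
    g <- out
    a <- l + 1L
    if (a <= config$n_heads) heads[[a]] <- ag_sigmoid(conv1(sprintf("head%d", a), g))
  }
  list(heads = heads, vae = vae)
}

#' Run a forward pass on a volume
#'
#' Pads the input symmetrically with zeros to the extent the encoder
#' requires (divisible by \code{2^(depth-1)}), runs the network, and crops
#' every head back to the original extent (head A to
#' \code{ceiling(extent / 2^(A-1))}).
#'
#' @param model a \code{resunet3d_model}.
#' @param x 4D array (in_channels, D, H, W).
#' @return List with \code{heads} (list of probability arrays, index 1 =
#'   full resolution) and, for \code{ae_unet}, \code{vae} with
#'   \code{recon}, \code{mu}, \code{log_var} arrays.
#' @export
model_forward <- function(model, x) {
  config <- model$config
  d <- dim(x)
  if (length(d) != 4L || d[1] != config$in_channels) {
    stop("input must be a 4D array with ", config$in_channels, " channels")
  }
  padded <- .pad_volume(x, .divisor(config))
  pt <- .param_tensors(model$params)
  res <- .forward_graph(config, pt, ag_const(padded$x))
  heads <- lapply(seq_along(res$heads), function(a) {
    .crop_head(res$heads[[a]]$value, padded$lo, padded$orig, 2^(a - 1))
  })
  out <- list(heads = heads)
  if (!is.null(res$vae)) {
    rec <- res$vae$recon$value
    out$vae <- list(
      recon = rec[, padded$lo[1] + seq_len(padded$orig[1]),
                  padded$lo[2] + seq_len(padded$orig[2]),
                  padded$lo[3] + seq_len(padded$orig[3]), drop = FALSE],
      mu = res$vae$mu$value, log_var = res$vae$log_var$value)
  }
  out
}

#' Predict region probabilities for one patch
#'
#' Final-head (full-resolution) forward pass; the patch-level primitive the
#' sliding-window engine calls.
#'
#' @param model a \code{resunet3d_model}.
#' @param patch 4D array (in_channels, D, H, W).
#' @return 4D probability array (out_channels, D, H, W), values in (0, 1).
#' @export
predict_patch <- function(model, patch) {
  model_forward(model, patch)$heads[[1]]
}
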