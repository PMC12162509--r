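# Shared fixtures: tiny label volumes, small phantom datasets, stub
# predictors, and a central-difference gradient helper.

random_label_volume <- function(shape = c(3, 3, 3)) {
  array(sample(c(0L, 1L, 2L, 4L), prod(shape), replace = TRUE,
               prob = c(0.55, 0.15, 0.15, 0.15)), dim = shape)
}

# small in-memory phantom dataset
tiny_cases <- function(n = 3, shape = 24, seed = 7) {
  pc <- phantom_config(shape = shape, n_cases = n,
                       radii = c(r_wt = 6, r_tc = 4, r_et = 2),
                       center_jitter = 1L, seed = seed)
  lapply(seq_len(n), function(i) generate_case(pc, i))
}

tiny_net_config <- function(variant = "res_unet", depth = 3L, ...) {
  network_config(variant, depth = depth, base_channels = 2L,
                 channel_cap = 8L, in_channels = 4L, input_size = 8L, ...)
}

# constant-probability stub predictor
constant_stub <- function(value) {
  function(patch) array(value, dim = c(3L, dim(patch)[-1]))
}

# voxel-wise (hence flip-equivariant) stub: sigmoid of the mean intensity
voxelwise_stub <- function(patch) {
  d <- dim(patch)
  m <- colMeans(matrix(patch, nrow = d[1]))
  array(rep(1 / (1 + exp(-m)), each = 3), dim = c(3L, d[-1]))
}

# central-difference numerical gradient of scalar f at x
num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps
    x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

# brute-force Dice of two binary vectors/arrays (no conventions)
dice_bruteforce <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  2 * sum(a & b) / (sum(a) + sum(b))
}
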