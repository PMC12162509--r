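# Architecture construction: channel schedules, head shapes, residual and
# attention behavior, VAE branch contracts, gradient flow.

ns <- asNamespace("resunet3d")

test_that("channel schedule doubles and caps", {
  expect_equal(channel_schedule(network_config("unet", depth = 7)),
               c(64L, 128L, 256L, 512L, 512L, 512L, 512L))
  expect_equal(channel_schedule(network_config("unet", depth = 6,
                                               base_channels = 32,
                                               channel_cap = 320)),
               c(32L, 64L, 128L, 256L, 320L, 320L))
  expect_equal(channel_schedule(network_config("unet", depth = 2,
                                               base_channels = 8,
                                               channel_cap = 8)),
               c(8L, 8L))
})

test_that("config validation enforces depth and head bounds", {
  expect_error(network_config("unet", depth = 1), "depth")
  expect_error(network_config("unet", depth = 3, n_heads = 3), "n_heads")
  expect_equal(network_config("unet", depth = 3)$n_heads, 2L)
  expect_equal(network_config("unet", deep_supervision = FALSE)$n_heads, 1L)
})

test_that("bottleneck extent is input / 2^(depth-1) after padding", {
  bd <- function(depth, size) {
    ns$.ae_bottleneck_dims(network_config("ae_unet", depth = depth,
                                          base_channels = 2, channel_cap = 4,
                                          input_size = size))
  }
  expect_equal(bd(7, 128), c(2L, 2L, 2L))   # the full-scale geometry
  expect_equal(bd(6, 128), c(4L, 4L, 4L))
  expect_equal(bd(7, 64), c(1L, 1L, 1L))
  expect_equal(bd(7, 32), c(1L, 1L, 1L))    # padded up to 64 first
})

test_that("forward emits heads at full/half/quarter resolution and (0,1) range", {
  set.seed(2)
  x <- array(rnorm(4 * 16^3), c(4, 16, 16, 16))
  m <- build_network(tiny_net_config(depth = 4, n_heads = 3), seed = 1)
  out <- model_forward(m, x)
  expect_length(out$heads, 3)
  expect_equal(dim(out$heads[[1]]), c(3L, 16L, 16L, 16L))
  expect_equal(dim(out$heads[[2]]), c(3L, 8L, 8L, 8L))
  expect_equal(dim(out$heads[[3]]), c(3L, 4L, 4L, 4L))
  for (h in out$heads) expect_true(all(h > 0 & h < 1))
  # supervision off: single head
  m1 <- build_network(tiny_net_config(depth = 4, deep_supervision = FALSE), seed = 1)
  expect_length(model_forward(m1, x)$heads, 1)
})

test_that("odd input extents are padded and cropped back", {
  set.seed(3)
  x <- array(rnorm(4 * 11 * 13 * 9), c(4, 11, 13, 9))
  m <- build_network(tiny_net_config(depth = 3), seed = 1)
  out <- model_forward(m, x)
  expect_equal(dim(out$heads[[1]]), c(3L, 11L, 13L, 9L))
  expect_equal(dim(out$heads[[2]]), c(3L, 6L, 7L, 5L))
})

test_that("res_unet and unet emit identical output shapes", {
  set.seed(4)
  x <- array(rnorm(4 * 8^3), c(4, 8, 8, 8))
  for (d in c(3, 4)) {
    o1 <- model_forward(build_network(tiny_net_config("unet", depth = d), 1), x)
    o2 <- model_forward(build_network(tiny_net_config("res_unet", depth = d), 1), x)
    expect_equal(lapply(o1$heads, dim), lapply(o2$heads, dim))
  }
})

test_that("residual wrap: zero block yields the shortcut; projection only changes channels", {
  set.seed(5)
  x <- array(rnorm(4 * 6^3), c(4, 6, 6, 6))
  xt <- ns$ag_const(x)
  # zero block + matched channels: identity shortcut survives untouched
  zero_block <- ns$ag_const(array(0, dim(x)))
  expect_equal(ns$ag_add(zero_block, xt)$value, x)
  # mismatched channels: 1x1x1 projection changes only the channel count
  W <- matrix(rnorm(8 * 4, 0, 0.4), 8)
  proj <- ns$ag_conv3d(xt, ns$ag_const(W), ns$ag_const(numeric(8)), 1L, 1L, 0L)
  expect_equal(dim(proj$value), c(8L, 6L, 6L, 6L))
  # and equals the plain per-voxel matrix product
  expect_equal(matrix(proj$value, 8), W %*% matrix(x, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("attention coefficients lie in [0,1] and gate the skip as limits", {
  set.seed(6)
  skip <- array(rnorm(4 * 4^3), c(4, 4, 4, 4))
  gating <- array(rnorm(8 * 2^3), c(8, 2, 2, 2))
  wx <- matrix(rnorm(2 * 4, 0, 0.5), 2); wg <- matrix(rnorm(2 * 8, 0, 0.5), 2)
  psi <- matrix(rnorm(2, 0, 0.5), 1)
  gate <- function(psi_bias) {
    ga <- ns$ag_upsample2(ns$ag_conv3d(ns$ag_const(gating), ns$ag_const(wg),
                                       ns$ag_const(numeric(2)), 1L, 1L, 0L))
    sa <- ns$ag_conv3d(ns$ag_const(skip), ns$ag_const(wx),
                       ns$ag_const(numeric(2)), 1L, 1L, 0L)
    alpha <- ns$ag_sigmoid(ns$ag_conv3d(ns$ag_leaky_relu(ns$ag_add(ga, sa), 0.01),
                                        ns$ag_const(psi), ns$ag_const(psi_bias),
                                        1L, 1L, 0L))
    list(alpha = alpha$value,
         out = ns$ag_mul_broadcast(ns$ag_const(skip), alpha)$value)
  }
  g <- gate(0)
  expect_true(all(g$alpha > 0 & g$alpha < 1))
  # saturate the gate bias: coefficients -> 1 recovers the skip; -> 0 kills it
  expect_equal(gate(1e4)$out, skip, tolerance = 1e-12)
  expect_true(all(abs(gate(-1e4)$out) < 1e-12))
})

test_that("attention_unet forward runs and matches head shape contract", {
  set.seed(7)
  x <- array(rnorm(4 * 8^3), c(4, 8, 8, 8))
  out <- model_forward(build_network(tiny_net_config("attention_unet", depth = 3), 1), x)
  expect_equal(dim(out$heads[[1]]), c(3L, 8L, 8L, 8L))
})

test_that("VAE branch is deterministic under a fixed seed and reconstructs input shape", {
  cfg <- tiny_net_config("ae_unet", depth = 3)
  m <- build_network(cfg, seed = 8)
  x <- array(rnorm(4 * 8^3), c(4, 8, 8, 8))
  set.seed(99); o1 <- model_forward(m, x)
  set.seed(99); o2 <- model_forward(m, x)
  expect_identical(o1$vae$recon, o2$vae$recon)
  expect_equal(dim(o1$vae$recon), dim(x))
  expect_length(o1$vae$mu, cfg$latent_dim)
  expect_length(o1$vae$log_var, cfg$latent_dim)
})

test_that("gradient reaches every trainable parameter in every variant", {
  set.seed(9)
  x <- array(rnorm(4 * 8^3), c(4, 8, 8, 8))
  lab <- array(0L, c(8, 8, 8)); lab[3:6, 3:6, 3:6] <- 2L; lab[4:5, 4:5, 4:5] <- 4L
  tgt <- labels_to_regions(lab)
  lc <- loss_config()
  for (v in c("unet", "res_unet", "attention_unet", "ae_unet")) {
    cfg <- tiny_net_config(v, depth = 3)
    m <- build_network(cfg, seed = 10)
    pt <- ns$.param_tensors(m$params)
    out <- ns$.forward_graph(cfg, pt, ns$ag_const(x))
    total <- ns$.deep_supervision_loss_graph(list(out$heads), list(tgt), lc)
    if (v == "ae_unet") {
      total <- ns$ag_add(total, ns$.vae_loss_graph(out$vae$recon, x,
                                                   out$vae$mu, out$vae$log_var, lc))
    }
    ns$ag_backward(total)
    dead <- names(pt)[vapply(pt, function(p) is.null(p$grad) || all(p$grad == 0),
                             logical(1))]
    expect_length(dead, 0)
  }
})
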