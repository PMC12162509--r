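# Loss oracles: brute-force Dice/BCE/focal evaluations on tiny tensors,
# analytic reductions, and the aggregation identities.

# independent brute-force implementations (plain loops, no shared code)
dice_loss_oracle <- function(probs_list, targets_list, smooth = 1e-5,
                             batch = TRUE) {
  per_channel <- sapply(1:3, function(ch) {
    if (batch) {
      inter <- 0; ps <- 0; ts <- 0
      for (i in seq_along(probs_list)) {
        p <- probs_list[[i]][ch, , , ]; t <- targets_list[[i]][ch, , , ]
        inter <- inter + sum(p * t); ps <- ps + sum(p); ts <- ts + sum(t)
      }
      1 - (2 * inter + smooth) / (ps + ts + smooth)
    } else {
      mean(sapply(seq_along(probs_list), function(i) {
        p <- probs_list[[i]][ch, , , ]; t <- targets_list[[i]][ch, , , ]
        1 - (2 * sum(p * t) + smooth) / (sum(p) + sum(t) + smooth)
      }))
    }
  })
  mean(per_channel)
}

focal_oracle <- function(probs, targets, gamma, eps = 1e-7) {
  p <- as.numeric(probs); t <- as.numeric(targets)
  pt <- ifelse(t == 1, p, 1 - p)
  pt <- pmin(pmax(pt, eps), 1 - eps)
  mean(-(1 - pt)^gamma * log(pt))
}

rand_probs <- function(shape = c(3, 3, 3, 3)) array(runif(prod(shape)), shape)
rand_targets <- function(shape = c(3, 3, 3, 3)) {
  labels_to_regions(random_label_volume(shape[-1]))
}

test_that("dice_loss matches the brute-force oracle on small tensors", {
  set.seed(21)
  for (rep in 1:5) {
    p <- list(rand_probs(), rand_probs())
    t <- list(rand_targets(), rand_targets())
    expect_equal(dice_loss(p, t), dice_loss_oracle(p, t), tolerance = 1e-9)
    cfg <- loss_config(batch_dice = FALSE)
    expect_equal(dice_loss(p, t, cfg), dice_loss_oracle(p, t, batch = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("dice_loss hits the analytic anchor points", {
  t <- rand_targets()
  expect_lt(dice_loss(t, t), 1e-4)            # perfect overlap
  # disjoint nonempty hard masks -> loss ~ 1
  a <- array(0, c(3, 2, 2, 2)); b <- array(0, c(3, 2, 2, 2))
  a[, 1, 1, 1] <- 1; b[, 2, 2, 2] <- 1
  expect_gt(dice_loss(a, b), 0.999)
  # 2-voxel masks sharing 1 voxel: Dice 1/2 as smooth -> 0
  p <- array(0, c(3, 4, 1, 1)); q <- array(0, c(3, 4, 1, 1))
  p[, 1:2, 1, 1] <- 1; q[, 2:3, 1, 1] <- 1
  expect_equal(dice_loss(p, q, loss_config(smooth = 1e-12)), 0.5,
               tolerance = 1e-9)
})

test_that("dice_loss is monotone in overlap for fixed-size masks", {
  # enumeration on a 1D-embedded grid: |A|=|B|=4, overlap 0..4
  losses <- sapply(0:4, function(k) {
    p <- array(0, c(3, 8, 1, 1)); t <- array(0, c(3, 8, 1, 1))
    p[, 1:4, 1, 1] <- 1
    t[, (5 - k):(8 - k), 1, 1] <- 1
    dice_loss(p, t, loss_config(smooth = 1e-12))
  })
  expect_true(all(diff(losses) <= 1e-12))
  expect_equal(losses, 1 - sapply(0:4, function(k) 2 * k / 8), tolerance = 1e-9)
})

test_that("batch Dice on identical items equals per-item Dice", {
  set.seed(22)
  p <- rand_probs(); t <- rand_targets()
  expect_equal(dice_loss(list(p, p, p), list(t, t, t)),
               dice_loss(p, t), tolerance = 1e-6)
})

test_that("secondary loss matches the focal oracle and reduces to BCE at gamma 0", {
  set.seed(23)
  p <- rand_probs(); t <- rand_targets()
  expect_equal(secondary_loss(p, t, loss_config(secondary = "focal", gamma = 2)),
               focal_oracle(p, t, 2), tolerance = 1e-9)
  expect_equal(secondary_loss(p, t, loss_config(secondary = "bce")),
               focal_oracle(p, t, 0), tolerance = 1e-9)
  expect_equal(secondary_loss(p, t, loss_config(secondary = "focal", gamma = 0)),
               secondary_loss(p, t, loss_config(secondary = "bce")),
               tolerance = 1e-12)
  # hand-evaluated single voxel: p = 0.5, t = 1, gamma = 2 -> 0.25 * ln 2
  p1 <- array(0.5, c(3, 1, 1, 1)); t1 <- array(1, c(3, 1, 1, 1))
  expect_equal(secondary_loss(p1, t1, loss_config(secondary = "focal", gamma = 2)),
               0.25 * log(2), tolerance = 1e-9)
  # p_t = 1 everywhere -> zero loss (up to the clamp)
  expect_lt(secondary_loss(t, t, loss_config(secondary = "bce")), 1e-5)
})

test_that("combined loss is the alpha-convex combination, linear in alpha", {
  set.seed(24)
  p <- rand_probs(); t <- rand_targets()
  d <- dice_loss(p, t); s <- secondary_loss(p, t)
  expect_equal(combined_loss(p, t, loss_config(alpha = 1)), d, tolerance = 1e-12)
  expect_equal(combined_loss(p, t, loss_config(alpha = 0)), s, tolerance = 1e-12)
  expect_equal(combined_loss(p, t, loss_config(alpha = 0.7)), 0.7 * d + 0.3 * s,
               tolerance = 1e-9)
  # linearity: three alphas collinear
  vals <- sapply(c(0.2, 0.5, 0.8), function(a)
    combined_loss(p, t, loss_config(alpha = a)))
  expect_equal(vals[2], mean(vals[c(1, 3)]), tolerance = 1e-9)
})

test_that("deep-supervision loss aggregates per-head composite losses", {
  set.seed(25)
  t <- rand_targets(c(3, 4, 4, 4))
  heads <- list(rand_probs(c(3, 4, 4, 4)), rand_probs(c(3, 2, 2, 2)),
                rand_probs(c(3, 1, 1, 1)))
  # per-head losses computed independently
  per <- sapply(1:3, function(a)
    combined_loss(heads[[a]], downsample_regions_nn(t, 2^(a - 1))))
  expect_equal(deep_supervision_loss(heads, t), mean(per), tolerance = 1e-9)
  # weights (w, 0, 0) reduce to the final head alone
  expect_equal(deep_supervision_loss(heads, t, loss_config(head_weights = c(2, 0, 0))),
               per[1], tolerance = 1e-9)
  # single head (supervision off) equals combined_loss
  expect_equal(deep_supervision_loss(heads[1], t), per[1], tolerance = 1e-12)
  # exact targets at every head -> ~0
  exact <- lapply(1:3, function(a) downsample_regions_nn(t, 2^(a - 1)))
  expect_lt(deep_supervision_loss(exact, t, loss_config(secondary = "bce")), 1e-4)
})

test_that("VAE loss: closed-form KL anchors and zero reconstruction error", {
  x <- array(rnorm(4 * 8), c(4, 2, 2, 2))
  cfg <- loss_config(vae_weight_rec = 1, vae_weight_kl = 1)
  mu0 <- numeric(4); lv0 <- numeric(4)
  expect_equal(vae_loss(x, x, mu0, lv0, cfg), 0, tolerance = 1e-12)
  mu <- c(1, 0, 0, 0)
  expect_equal(vae_loss(x, x, mu, lv0, cfg), 0.5, tolerance = 1e-12)
  expect_error(vae_loss(x, x, c(NaN, 0, 0, 0), lv0, cfg), "non-finite")
})

test_that("loss input validation rejects bad shapes and ranges", {
  p <- rand_probs(); t <- rand_targets()
  expect_error(dice_loss(p, t[, 1:2, , , drop = FALSE]), "mismatch")
  expect_error(dice_loss(p * 2, t), "\\[0, 1\\]")
  expect_error(loss_config(alpha = 1.2), "alpha")
  expect_error(loss_config(head_weights = c(0, 0)), "head_weights")
})
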