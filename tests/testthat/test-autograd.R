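# Numerical gradient checks for the reverse-mode tape: every learned layer
# and the structural ops used by the forward graphs.

ns <- asNamespace("resunet3d")

# attach a sin() head so the incoming gradient is non-trivial
sin_loss <- function(y) {
  ns$.ag_new(sum(sin(y$value)), list(y), function(g) {
    list(array(as.numeric(g) * cos(y$value),
               dim = dim(y$value) %||% length(y$value)))
  })
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("conv3d gradients match central differences (stride 1 and 2)", {
  set.seed(11)
  x <- array(rnorm(2 * 4 * 4 * 4), c(2, 4, 4, 4))
  W <- matrix(rnorm(3 * 54, 0, 0.3), 3)
  b <- rnorm(3)
  for (stride in c(1L, 2L)) {
    xt <- ns$ag_param(x); Wt <- ns$ag_param(W); bt <- ns$ag_param(b)
    loss <- sin_loss(ns$ag_conv3d(xt, Wt, bt, 3L, stride, 1L))
    ns$ag_backward(loss)
    f <- function(par, what) {
      xx <- x; WW <- W; bb <- b
      if (what == "x") xx <- array(par, dim(x))
      if (what == "W") WW <- matrix(par, 3)
      if (what == "b") bb <- par
      col <- ns$cpp_vol2col(as.numeric(xx), dim(x), 3L, stride, 1L)
      sum(sin(WW %*% col + bb))
    }
    expect_lt(max(abs(xt$grad - array(num_grad(function(p) f(p, "x"), as.numeric(x)), dim(x)))), 1e-6)
    expect_lt(max(abs(Wt$grad - matrix(num_grad(function(p) f(p, "W"), as.numeric(W)), 3))), 1e-6)
    expect_lt(max(abs(bt$grad - num_grad(function(p) f(p, "b"), b))), 1e-6)
  }
})

test_that("transposed conv gradients match central differences", {
  set.seed(12)
  x <- array(rnorm(2 * 3 * 3 * 3), c(2, 3, 3, 3))
  W <- matrix(rnorm(2 * 24, 0, 0.3), 2)   # 2 in, 3 out
  b <- rnorm(3)
  xt <- ns$ag_param(x); Wt <- ns$ag_param(W); bt <- ns$ag_param(b)
  y <- ns$ag_tconv3d(xt, Wt, bt)
  expect_equal(dim(y$value), c(3L, 6L, 6L, 6L))
  ns$ag_backward(sin_loss(y))
  f <- function(xv, Wv, bv) {
    yc <- crossprod(matrix(Wv, 2), matrix(xv, 2))
    yv <- ns$cpp_col2vol(yc, c(3L, 6L, 6L, 6L), 2L, 2L, 0L)
    sum(sin(matrix(yv, 3) + bv))
  }
  expect_lt(max(abs(xt$grad - array(num_grad(function(p) f(p, W, b), as.numeric(x)), dim(x)))), 1e-6)
  expect_lt(max(abs(Wt$grad - matrix(num_grad(function(p) f(x, p, b), as.numeric(W)), 2))), 1e-6)
  expect_lt(max(abs(bt$grad - num_grad(function(p) f(x, W, p), b))), 1e-6)
})

test_that("instance norm gradients match central differences", {
  set.seed(13)
  x <- array(rnorm(2 * 64), c(2, 4, 4, 4))
  gam <- c(1.2, 0.8); bet <- c(0.1, -0.2)
  xt <- ns$ag_param(x); gt <- ns$ag_param(gam); bt <- ns$ag_param(bet)
  ns$ag_backward(sin_loss(ns$ag_instance_norm(xt, gt, bt)))
  f <- function(xv, gv, bv) {
    m <- matrix(xv, 2)
    mu <- rowMeans(m); v <- rowMeans(m * m) - mu^2
    sum(sin((m - mu) / sqrt(v + 1e-5) * gv + bv))
  }
  expect_lt(max(abs(xt$grad - array(num_grad(function(p) f(p, gam, bet), as.numeric(x)), dim(x)))), 1e-6)
  expect_lt(max(abs(gt$grad - num_grad(function(p) f(x, p, bet), gam))), 1e-6)
  expect_lt(max(abs(bt$grad - num_grad(function(p) f(x, gam, p), bet))), 1e-6)
})

test_that("upsample, broadcast multiply, concat and dense backprop correctly", {
  set.seed(14)
  x <- array(rnorm(3 * 8), c(3, 2, 2, 2))
  a <- array(rnorm(8), c(1, 2, 2, 2))
  xt <- ns$ag_param(x); at <- ns$ag_param(a)
  ns$ag_backward(sin_loss(ns$ag_upsample2(ns$ag_mul_broadcast(xt, at))))
  f <- function(xv, av) {
    xa <- array(xv, dim(x)) * rep(av, each = 3)
    up <- xa[, rep(1:2, each = 2), rep(1:2, each = 2), rep(1:2, each = 2)]
    sum(sin(up))
  }
  expect_lt(max(abs(xt$grad - array(num_grad(function(p) f(p, a), as.numeric(x)), dim(x)))), 1e-6)
  expect_lt(max(abs(at$grad - array(num_grad(function(p) f(x, p), as.numeric(a)), dim(a)))), 1e-6)

  y1 <- ns$ag_param(array(rnorm(2 * 8), c(2, 2, 2, 2)))
  y2 <- ns$ag_param(array(rnorm(8), c(1, 2, 2, 2)))
  ns$ag_backward(sin_loss(ns$ag_concat_channels(y1, y2)))
  fc <- function(v1, v2) {
    sum(sin(rbind(matrix(v1, 2), matrix(v2, 1))))
  }
  expect_lt(max(abs(y1$grad - array(num_grad(function(p) fc(p, y2$value), as.numeric(y1$value)), c(2, 2, 2, 2)))), 1e-6)

  W <- matrix(rnorm(12), 3); b <- rnorm(3); v <- rnorm(4)
  vt <- ns$ag_param(v); Wt <- ns$ag_param(W); bt <- ns$ag_param(b)
  ns$ag_backward(sin_loss(ns$ag_dense(vt, Wt, bt)))
  expect_lt(max(abs(vt$grad - num_grad(function(p) sum(sin(W %*% p + b)), v))), 1e-6)
  expect_lt(max(abs(Wt$grad - matrix(num_grad(function(p) sum(sin(matrix(p, 3) %*% v + b)), as.numeric(W)), 3))), 1e-6)
})

test_that("scalar chain ops (sigmoid, log, pow, clamp, div) backprop correctly", {
  set.seed(15)
  x <- runif(10, 0.1, 0.9)
  xt <- ns$ag_param(x)
  y <- ns$ag_mean(ns$ag_mul(ns$ag_pow_const(ns$ag_affine(ns$ag_sigmoid(xt), -1, 1), 2),
                            ns$ag_log(ns$ag_clamp(ns$ag_sigmoid(xt), 1e-7, 1 - 1e-7))))
  ns$ag_backward(y)
  f <- function(p) {
    s <- 1 / (1 + exp(-p))
    mean((1 - s)^2 * log(pmin(pmax(s, 1e-7), 1 - 1e-7)))
  }
  expect_lt(max(abs(xt$grad - num_grad(f, x))), 1e-6)
})

test_that("gradients accumulate over shared parameters", {
  w <- ns$ag_param(2)
  l <- ns$ag_add(ns$ag_mul(w, w), ns$ag_scale(w, 3))   # w^2 + 3w
  ns$ag_backward(l)
  expect_equal(as.numeric(w$grad), 2 * 2 + 3)
})
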