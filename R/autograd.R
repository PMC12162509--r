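# Minimal reverse-mode automatic differentiation on dense R arrays.
#
# A tensor is an environment holding `value` (a numeric array), `grad`
# (accumulated during the backward sweep), `parents` (list of tensors) and
# `backfn`, which maps the incoming gradient to a list of parent gradients
# in parent order.  The graph is traversed once, in reverse topological
# order, by ag_backward().  All heavy lifting (GEMM via %*%, im2col via the
# compiled kernels) happens on plain arrays, so the tape overhead is
# negligible next to the linear algebra.

.ag_counter <- new.env(parent = emptyenv())
.ag_counter$id <- 0L

.ag_new <- function(value, parents = list(), backfn = NULL, requires = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  if (is.null(requires)) {
    requires <- length(parents) > 0L &&
      any(vapply(parents, function(p) p$requires, logical(1)))
  }
  e$requires <- requires
  .ag_counter$id <- .ag_counter$id + 1L
  e$id <- .ag_counter$id
  class(e) <- "ag_tensor"
  e
}

#' @noRd
ag_param <- function(value) .ag_new(value, requires = TRUE)

#' @noRd
ag_const <- function(value) .ag_new(value, requires = FALSE)

ag_value <- function(x) x$value

.ag_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

# Reverse sweep from a scalar loss node.
ag_backward <- function(loss) {
  stopifnot(length(loss$value) == 1L)
  # iterative topological sort (post-order DFS)
  order <- vector("list", 256L)
  norder <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = loss, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (p$requires && is.null(seen[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      norder <- norder + 1L
      if (norder > length(order)) order <- c(order, vector("list", length(order)))
      order[[norder]] <- node
    }
  }
  loss$grad <- array(1, dim = dim(loss$value) %||% 1L)
  for (i in rev(seq_len(norder))) {
    node <- order[[i]]
    if (is.null(node$backfn) || is.null(node$grad)) next
    gs <- node$backfn(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (p$requires && !is.null(gs[[j]])) .ag_accum(p, gs[[j]])
    }
    # release the closure (and any cached forward buffers) and this node's
    # gradient as soon as they have been consumed; leaf gradients survive
    node$backfn <- NULL
    node$grad <- NULL
  }
  invisible(loss)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- elementwise and scalar ops ----

ag_add <- function(a, b) {
  .ag_new(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  .ag_new(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

# a*x + b with constant arrays/scalars a, b
ag_affine <- function(x, a, b = 0) {
  .ag_new(a * x$value + b, list(x), function(g) list(g * a))
}

ag_scale <- function(x, s) ag_affine(x, s, 0)

ag_div <- function(a, b) {
  av <- a$value; bv <- b$value
  .ag_new(av / bv, list(a, b),
          function(g) list(g / bv, -g * av / (bv * bv)))
}

ag_log <- function(x) {
  v <- x$value
  .ag_new(log(v), list(x), function(g) list(g / v))
}

ag_exp <- function(x) {
  v <- exp(x$value)
  .ag_new(v, list(x), function(g) list(g * v))
}

ag_pow_const <- function(x, p) {
  v <- x$value
  .ag_new(v^p, list(x), function(g) list(g * p * v^(p - 1)))
}

# clamp with straight-through-zero gradient outside [lo, hi]
ag_clamp <- function(x, lo, hi) {
  v <- x$value
  inside <- (v >= lo & v <= hi) * 1
  .ag_new(pmin(pmax(v, lo), hi), list(x), function(g) list(g * inside))
}

ag_sum <- function(x) {
  d <- dim(x$value) %||% length(x$value)
  .ag_new(sum(x$value), list(x), function(g) list(array(as.numeric(g), d)))
}

ag_mean <- function(x) {
  n <- length(x$value)
  d <- dim(x$value) %||% n
  .ag_new(sum(x$value) / n, list(x),
          function(g) list(array(as.numeric(g) / n, d)))
}

# sum(x * w) with a constant weight array w (memory-lean dot product)
ag_dot_const <- function(x, w) {
  .ag_new(sum(x$value * w), list(x), function(g) list(as.numeric(g) * w))
}

# ---- activations / normalization ----

ag_leaky_relu <- function(x, slope = 0.01) {
  v <- x$value
  mult <- slope + (1 - slope) * (v > 0)
  .ag_new(v * mult, list(x), function(g) list(g * mult))
}

ag_sigmoid <- function(x) {
  v <- 1 / (1 + exp(-x$value))
  .ag_new(v, list(x), function(g) list(g * v * (1 - v)))
}

# Instance normalization over the spatial axes of a (C,D,H,W) array with
# per-channel affine parameters gamma, beta (length-C tensors).
ag_instance_norm <- function(x, gamma, beta, eps = 1e-5) {
  dims <- dim(x$value)
  C <- dims[1]
  n <- prod(dims[-1])
  m <- matrix(x$value, nrow = C)
  mu <- rowMeans(m)
  v <- rowMeans(m * m) - mu * mu
  invstd <- 1 / sqrt(v + eps)
  xhat <- (m - mu) * invstd
  gv <- gamma$value
  out <- array(xhat * gv + beta$value, dim = dims)
  .ag_new(out, list(x, gamma, beta), function(g) {
    gm <- matrix(g, nrow = C)
    ggamma <- rowSums(gm * xhat)
    gbeta <- rowSums(gm)
    gxhat <- gm * gv
    gx <- invstd * (gxhat - rowMeans(gxhat) - xhat * rowMeans(gxhat * xhat))
    list(array(gx, dim = dims), ggamma, gbeta)
  })
}

# ---- structural ops ----

ag_concat_channels <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(all(da[-1] == db[-1]))
  Ca <- da[1]; Cb <- db[1]
  out <- array(rbind(matrix(a$value, nrow = Ca), matrix(b$value, nrow = Cb)),
               dim = c(Ca + Cb, da[-1]))
  .ag_new(out, list(a, b), function(g) {
    gm <- matrix(g, nrow = Ca + Cb)
    list(array(gm[seq_len(Ca), , drop = FALSE], dim = da),
         array(gm[Ca + seq_len(Cb), , drop = FALSE], dim = db))
  })
}

# nearest-neighbor spatial upsampling by 2 on a (C,D,H,W) array
ag_upsample2 <- function(x) {
  d <- dim(x$value)
  C <- d[1]; D <- d[2]; H <- d[3]; W <- d[4]
  out <- x$value[, rep(seq_len(D), each = 2), rep(seq_len(H), each = 2),
                 rep(seq_len(W), each = 2), drop = FALSE]
  .ag_new(out, list(x), function(g) {
    ga <- array(g, dim = c(C, 2L, D, 2L, H, 2L, W))
    gx <- array(0, dim = d)
    for (i in 1:2) for (j in 1:2) for (k in 1:2) {
      gx <- gx + array(ga[, i, , j, , k, ], dim = d)
    }
    list(gx)
  })
}

# broadcast-multiply a single-channel attention map alpha (1,D,H,W) onto a
# (C,D,H,W) tensor
ag_mul_broadcast <- function(x, alpha) {
  dx <- dim(x$value)
  C <- dx[1]
  xm <- matrix(x$value, nrow = C)
  av <- as.numeric(alpha$value)
  out <- array(xm * rep(av, each = C), dim = dx)
  .ag_new(out, list(x, alpha), function(g) {
    gm <- matrix(g, nrow = C)
    gx <- array(gm * rep(av, each = C), dim = dx)
    galpha <- array(colSums(gm * xm), dim = dim(alpha$value))
    list(gx, galpha)
  })
}

ag_reshape <- function(x, newdim) {
  olddim <- dim(x$value) %||% length(x$value)
  .ag_new(array(x$value, dim = newdim), list(x),
          function(g) list(array(g, dim = olddim)))
}

# extract channel c of a (C,...) tensor, keeping a length-prod(spatial) vector
ag_channel <- function(x, ch) {
  d <- dim(x$value)
  C <- d[1]
  m <- matrix(x$value, nrow = C)
  .ag_new(m[ch, ], list(x), function(g) {
    gm <- matrix(0, nrow = C, ncol = ncol(m))
    gm[ch, ] <- g
    list(array(gm, dim = d))
  })
}

# ---- learned layers ----

# 3D convolution: x (C_in,D,H,W), W (C_out x C_in*k^3), b (C_out).
ag_conv3d <- function(x, W, b, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  dims <- dim(x$value)
  col <- cpp_vol2col(as.numeric(x$value), as.integer(dims),
                     as.integer(k), as.integer(stride), as.integer(pad))
  Wm <- W$value
  Cout <- nrow(Wm)
  y <- Wm %*% col + b$value
  odims <- c(Cout, (dims[-1] + 2L * pad - k) %/% stride + 1L)
  .ag_new(array(y, dim = odims), list(x, W, b), function(g) {
    gm <- matrix(g, nrow = Cout)
    gW <- tcrossprod(gm, col)
    gb <- rowSums(gm)
    gx <- NULL
    if (x$requires) {
      gcol <- crossprod(Wm, gm)
      gx <- cpp_col2vol(gcol, as.integer(dims),
                        as.integer(k), as.integer(stride), as.integer(pad))
    }
    list(gx, gW, gb)
  })
}

# Transposed 3D convolution, kernel 2 stride 2 (the decoder upsampler):
# x (C_in,D,H,W), W (C_in x C_out*8), b (C_out); output (C_out,2D,2H,2W).
ag_tconv3d <- function(x, W, b) {
  dims <- dim(x$value)
  Cin <- dims[1]
  Wm <- W$value
  Cout <- ncol(Wm) %/% 8L
  xm <- matrix(x$value, nrow = Cin)
  ycol <- crossprod(Wm, xm)               # (C_out*8) x n_in
  odims <- c(Cout, dims[-1] * 2L)
  y <- cpp_col2vol(ycol, as.integer(odims), 2L, 2L, 0L)
  ym <- matrix(y, nrow = Cout) + b$value
  .ag_new(array(ym, dim = odims), list(x, W, b), function(g) {
    gcol <- cpp_vol2col(as.numeric(g), as.integer(odims), 2L, 2L, 0L)
    gX <- Wm %*% gcol
    gW <- tcrossprod(xm, gcol)
    gb <- rowSums(matrix(g, nrow = Cout))
    list(array(gX, dim = dims), gW, gb)
  })
}

# dense layer: x length-n vector tensor, W (out x n), b (out)
ag_dense <- function(x, W, b) {
  Wm <- W$value
  xv <- as.numeric(x$value)
  .ag_new(as.numeric(Wm %*% xv + b$value), list(x, W, b), function(g) {
    g <- as.numeric(g)
    list(as.numeric(crossprod(Wm, g)), outer(g, xv), g)
  })
}
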