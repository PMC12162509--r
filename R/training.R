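# Patch-based training: foreground-biased sampling, Adam with weight decay,
# ReduceLROnPlateau scheduling, early stopping, and k-fold splitting.

#' Training configuration
#'
#' @param learning_rate Adam learning rate (1e-4).
#' @param weight_decay L2 penalty added to the convolution/dense weight
#'   gradients (1e-5).
#' @param batch_size patches per optimization step (2).
#' @param patch_size training patch extent (default 128^3; scale down for
#'   small studies — every axis must be divisible by \code{2^(depth-1)}).
#' @param max_epochs maximum number of epochs.
#' @param patience early-stopping patience on the validation loss (10).
#' @param sched_factor,sched_patience,min_lr ReduceLROnPlateau parameters
#'   (halve the rate after 5 flat epochs, floor 1e-6).
#' @param folds default cross-validation fold count (5).
#' @param holdout_fraction validation fraction when no explicit split is
#'   given (0.2).
#' @param fg_bias probability that a sampled patch is centered on a tumor
#'   voxel (0.5).
#' @param steps_per_epoch optimization steps per epoch; default cycles once
#'   through the training cases.
#' @param seed master seed: weight initialization, the train/validation
#'   split and patch sampling all derive from it.
#' @return An object of class \code{train_config}.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 1e-5,
                         batch_size = 2L, patch_size = c(128L, 128L, 128L),
                         max_epochs = 100L, patience = 10L,
                         sched_factor = 0.5, sched_patience = 5L,
                         min_lr = 1e-6, folds = 5L, holdout_fraction = 0.2,
                         fg_bias = 0.5, steps_per_epoch = NULL, seed = 1L) {
  if (learning_rate <= 0 || weight_decay < 0) stop("invalid rate")
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop("holdout_fraction must be in (0, 1)")
  }
  if (fg_bias < 0 || fg_bias > 1) stop("fg_bias must be in [0, 1]")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 patch_size = as.integer(rep(patch_size, length.out = 3L)),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 sched_factor = sched_factor,
                 sched_patience = as.integer(sched_patience),
                 min_lr = min_lr, folds = as.integer(folds),
                 holdout_fraction = holdout_fraction, fg_bias = fg_bias,
                 steps_per_epoch = steps_per_epoch, seed = as.integer(seed)),
            class = "train_config")
}

#' Deterministic k-fold split
#'
#' Shuffles the case ids with the given seed and deals them round-robin
#' into k validation sets, so fold sizes differ by at most one, folds are
#' disjoint, and their union covers all cases.
#'
#' @param case_ids vector of case identifiers.
#' @param k number of folds (2 <= k <= length(case_ids)).
#' @param seed integer seed.
#' @return List of fold splits: \code{fold_id}, \code{train_case_ids},
#'   \code{val_case_ids}.
#' @export
make_folds <- function(case_ids, k = 5L, seed = 1L) {
  n <- length(case_ids)
  k <- as.integer(k)
  if (k < 2L || k > n) stop("k must be in [2, number of cases]")
  set.seed(as.integer(seed))
  perm <- sample(case_ids)
  assign <- rep(seq_len(k), length.out = n)
  lapply(seq_len(k), function(f) {
    val <- perm[assign == f]
    list(fold_id = f, train_case_ids = setdiff(case_ids, val),
         val_case_ids = val)
  })
}

#' Sample a co-registered training patch
#'
#' With probability \code{fg_bias} the patch is centered on a uniformly
#' drawn tumor voxel (clamped to the volume); otherwise the origin is
#' uniform.  Volumes smaller than the patch are zero-padded symmetrically.
#' Draws from the current RNG stream, so sampling is reproducible under
#' \code{set.seed}.
#'
#' @param volume 4D modality array (C, D, H, W).
#' @param labels 3D label volume.
#' @param patch_size patch extent (scalar or length 3).
#' @param fg_bias foreground-centering probability.
#' @return List with \code{input} (C-channel patch), \code{labels} (label
#'   patch), \code{target} (3-channel region mask patch) and \code{origin}.
#' @export
sample_patch <- function(volume, labels, patch_size, fg_bias = 0.5) {
  ps <- as.integer(rep(patch_size, length.out = 3L))
  d <- dim(volume)
  sp <- d[-1]
  if (any(sp < ps)) {
    target <- pmax(sp, ps)
    lo <- (target - sp) %/% 2L
    v2 <- array(0, dim = c(d[1], target))
    v2[, lo[1] + seq_len(sp[1]), lo[2] + seq_len(sp[2]), lo[3] + seq_len(sp[3])] <- volume
    l2 <- array(0L, dim = target)
    l2[lo[1] + seq_len(sp[1]), lo[2] + seq_len(sp[2]), lo[3] + seq_len(sp[3])] <- labels
    volume <- v2; labels <- l2; sp <- target
  }
  use_fg <- runif(1) < fg_bias
  fg <- which(labels != 0L)
  if (use_fg && length(fg) == 0L) {
    if (fg_bias >= 1) warning("foreground-biased sampling requested on a tumor-free volume; falling back to uniform")
    use_fg <- FALSE
  }
  if (use_fg) {
    v <- fg[sample.int(length(fg), 1L)]
    ctr <- c((v - 1L) %% sp[1], ((v - 1L) %/% sp[1]) %% sp[2],
             (v - 1L) %/% (sp[1] * sp[2])) + 1L
    origin <- pmin(pmax(ctr - ps %/% 2L, 1L), sp - ps + 1L)
  } else {
    origin <- vapply(1:3, function(a) sample.int(sp[a] - ps[a] + 1L, 1L), integer(1))
  }
  ix <- lapply(1:3, function(a) origin[a] + seq_len(ps[a]) - 1L)
  lab <- labels[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  list(input = volume[, ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
       labels = lab, target = labels_to_regions(lab), origin = origin)
}

# append the salient-voxel channel when the config expects it
.prepare_input <- function(volume, config) {
  if (dim(volume)[1] == config$in_channels) return(volume)
  if (dim(volume)[1] + 1L == config$in_channels) {
    fg <- foreground_channel(volume)
    out <- array(0, dim = c(config$in_channels, dim(volume)[-1]))
    out[seq_len(dim(volume)[1]), , , ] <- volume
    out[config$in_channels, , , ] <- fg
    return(out)
  }
  stop("volume has ", dim(volume)[1], " channels but the network expects ",
       config$in_channels)
}

# deterministic center crop used for validation patches
.center_patch <- function(volume, labels, ps) {
  sp <- dim(volume)[-1]
  if (any(sp < ps)) {
    # delegate padding to sample_patch machinery with a fixed origin
    padded <- pmax(sp, ps)
    lo <- (padded - sp) %/% 2L
    v2 <- array(0, dim = c(dim(volume)[1], padded))
    v2[, lo[1] + seq_len(sp[1]), lo[2] + seq_len(sp[2]), lo[3] + seq_len(sp[3])] <- volume
    l2 <- array(0L, dim = padded)
    l2[lo[1] + seq_len(sp[1]), lo[2] + seq_len(sp[2]), lo[3] + seq_len(sp[3])] <- labels
    volume <- v2; labels <- l2; sp <- padded
  }
  origin <- (sp - ps) %/% 2L + 1L
  ix <- lapply(1:3, function(a) origin[a] + seq_len(ps[a]) - 1L)
  lab <- labels[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  list(input = volume[, ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
       target = labels_to_regions(lab))
}

.early_stop <- function(val_losses, patience) {
  n <- length(val_losses)
  if (n <= patience) return(FALSE)
  best_at <- which.min(val_losses)
  (n - best_at) >= patience
}

# one Adam step over the named parameter list
.adam_step <- function(params, grads, state, lr, wd, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (wd > 0 && endsWith(nm, ".W")) g <- g + wd * params[[nm]]
    m <- beta1 * state$m[[nm]] + (1 - beta1) * g
    v <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    state$m[[nm]] <- m
    state$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  list(params = params, state = state)
}

# training-time loss graph: returns total node plus per-head values
.training_loss <- function(config, loss_cfg, outs, targets, inputs) {
  n_heads <- config$n_heads
  w <- loss_cfg$head_weights %||% rep(1, n_heads)
  per_head <- numeric(n_heads)
  nodes <- vector("list", n_heads)
  for (a in seq_len(n_heads)) {
    ta <- lapply(targets, downsample_regions_nn, factor = 2^(a - 1))
    pa <- lapply(outs, function(o) o$heads[[a]])
    node <- .combined_loss_graph(pa, ta, loss_cfg)
    per_head[a] <- node$value
    nodes[[a]] <- ag_scale(node, w[a])
  }
  total <- ag_scale(Reduce(ag_add, nodes), 1 / sum(w))
  if (config$variant == "ae_unet") {
    vt <- Map(function(o, x) {
      .vae_loss_graph(o$vae$recon, x, o$vae$mu, o$vae$log_var, loss_cfg)
    }, outs, inputs)
    total <- ag_add(total, ag_scale(Reduce(ag_add, vt), 1 / length(vt)))
  }
  list(total = total, per_head = per_head)
}

#' Train a segmentation network
#'
#' Patch-based optimization with Adam (weight decay on the convolution and
#' dense weights), deep-supervision loss, ReduceLROnPlateau scheduling on
#' the validation loss, and early stopping.  The checkpoint returned holds
#' the best-validation parameters.  Runs are fully deterministic given
#' (seed, configs, dataset).
#'
#' @param cases list of cases, each a list with \code{volume} (4D modality
#'   array) and \code{labels} (3D label volume).
#' @param net_config a \code{network_config} (patch axes must be divisible
#'   by \code{2^(depth-1)}).
#' @param loss_cfg a \code{loss_config}.
#' @param tr a \code{train_config}.
#' @param val_idx optional indices of validation cases; default holds out
#'   \code{holdout_fraction} of the cases at random.
#' @return List of class \code{resunet3d_fit}: \code{model} (best
#'   parameters), \code{history} data.frame (epoch, L1..L3, total train
#'   loss, val_loss, lr), \code{best_val}, \code{val_idx}.
#' @export
train_model <- function(cases, net_config, loss_cfg = loss_config(),
                        tr = train_config(), val_idx = NULL) {
  n <- length(cases)
  if (n == 0L) stop("dataset is empty")
  ps <- tr$patch_size
  if (any(ps %% .divisor(net_config) != 0L)) {
    stop("patch_size must be divisible by 2^(depth-1)")
  }
  model <- build_network(net_config, seed = tr$seed)
  set.seed(tr$seed + 1L)
  if (is.null(val_idx)) {
    n_val <- max(1L, floor(n * tr$holdout_fraction))
    val_idx <- sort(sample.int(n, n_val))
  }
  train_idx <- setdiff(seq_len(n), val_idx)
  if (length(train_idx) == 0L) stop("no training cases left after hold-out")
  steps <- tr$steps_per_epoch %||% ceiling(length(train_idx) / tr$batch_size)
  params <- model$params
  state <- list(t = 0L,
                m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  lr <- tr$learning_rate
  n_heads <- net_config$n_heads
  history <- data.frame()
  val_losses <- numeric(0)
  best_val <- Inf
  best_params <- params
  plateau <- 0L
  val_patches <- lapply(cases[val_idx], function(cs) {
    cp <- .center_patch(.prepare_input(cs$volume, net_config), cs$labels, ps)
    cp
  })
  for (epoch in seq_len(tr$max_epochs)) {
    order_idx <- sample(rep(train_idx, length.out = steps * tr$batch_size))
    head_acc <- numeric(n_heads)
    total_acc <- 0
    for (s in seq_len(steps)) {
      batch <- order_idx[(s - 1L) * tr$batch_size + seq_len(tr$batch_size)]
      inputs <- list(); targets <- list()
      for (ci in batch) {
        cs <- cases[[ci]]
        sp <- sample_patch(cs$volume, cs$labels, ps, tr$fg_bias)
        inputs[[length(inputs) + 1L]] <- .prepare_input(sp$input, net_config)
        targets[[length(targets) + 1L]] <- sp$target
      }
      pt <- .param_tensors(params)
      outs <- lapply(inputs, function(x) .forward_graph(net_config, pt, ag_const(x)))
      tl <- .training_loss(net_config, loss_cfg, outs, targets, inputs)
      if (!is.finite(tl$total$value)) {
        stop(sprintf("non-finite training loss at epoch %d step %d (per-head: %s)",
                     epoch, s, paste(signif(tl$per_head, 4), collapse = ", ")))
      }
      ag_backward(tl$total)
      grads <- lapply(pt, function(p) p$grad)
      upd <- .adam_step(params, grads, state, lr, tr$weight_decay)
      params <- upd$params
      state <- upd$state
      head_acc <- head_acc + tl$per_head
      total_acc <- total_acc + tl$total$value
      rm(pt, outs, tl, grads, upd)
    }
    # validation loss with frozen parameters; graphs are detached to arrays
    # one case at a time to keep the footprint at a single forward pass
    ptv <- lapply(params, ag_const)
    vheads <- lapply(val_patches, function(vp) {
      out <- .forward_graph(net_config, ptv, ag_const(vp$input))
      res <- list(heads = lapply(out$heads, ag_value))
      if (!is.null(out$vae)) {
        res$vae <- list(recon = ag_value(out$vae$recon),
                        mu = ag_value(out$vae$mu),
                        log_var = ag_value(out$vae$log_var))
      }
      res
    })
    val_loss <- deep_supervision_loss(lapply(vheads, `[[`, "heads"),
                                      lapply(val_patches, `[[`, "target"),
                                      loss_cfg)
    if (net_config$variant == "ae_unet") {
      vl2 <- mapply(function(vh, vp) {
        vae_loss(vh$vae$recon, vp$input, vh$vae$mu, vh$vae$log_var, loss_cfg)
      }, vheads, val_patches)
      val_loss <- val_loss + mean(vl2)
    }
    rm(ptv, vheads); gc(FALSE)
    val_losses <- c(val_losses, val_loss)
    row <- as.list(c(epoch = epoch, head_acc / steps,
                     total = total_acc / steps,
                     val_loss = val_loss, lr = lr))
    names(row)[1 + seq_len(n_heads)] <- paste0("L", seq_len(n_heads))
    history <- rbind(history, as.data.frame(row))
    if (val_loss < best_val - 1e-8) {
      best_val <- val_loss
      best_params <- params
      plateau <- 0L
    } else {
      plateau <- plateau + 1L
      if (plateau >= tr$sched_patience && lr > tr$min_lr) {
        lr <- max(lr * tr$sched_factor, tr$min_lr)
        plateau <- 0L
      }
    }
    if (.early_stop(val_losses, tr$patience)) break
  }
  model$params <- best_params
  structure(list(model = model, history = history, best_val = best_val,
                 val_idx = val_idx, train_config = tr, loss_config = loss_cfg),
            class = "resunet3d_fit")
}

#' Save / load a training checkpoint
#'
#' The checkpoint embeds the network configuration, so \code{predict} can
#' rebuild the model without outside information.
#'
#' @param fit a \code{resunet3d_fit} (or bare \code{resunet3d_model}).
#' @param path file path (.rds).
#' @return \code{load_checkpoint} returns the stored object.
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Whole-volume prediction with a trained model
#'
#' Appends the foreground channel when the network expects it, then runs
#' half-overlap sliding-window inference (optionally with eight-flip TTA)
#' and returns the full-resolution region probabilities.
#'
#' @param model a \code{resunet3d_model} or \code{resunet3d_fit}.
#' @param volume 4D modality array (4, D, H, W).
#' @param patch_size inference patch extent; defaults to the training
#'   input size capped at the volume extent.
#' @param tta average over the eight axis flips (default TRUE).
#' @param importance \code{"gaussian"} or \code{"uniform"} center weighting.
#' @return 4D array (3, D, H, W) of WT/TC/ET probabilities.
#' @export
predict_volume <- function(model, volume, patch_size = NULL, tta = TRUE,
                           importance = c("gaussian", "uniform")) {
  importance <- match.arg(importance)
  if (inherits(model, "resunet3d_fit")) model <- model$model
  cfg <- model$config
  x <- .prepare_input(volume, cfg)
  if (is.null(patch_size)) patch_size <- pmin(cfg$input_size, dim(x)[-1])
  plan <- plan_windows(dim(x)[-1], patch_size)
  imp <- importance_map(plan$patch_size, kind = importance)
  if (tta) tta_predict(model, x, plan, imp)
  else sliding_window_predict(model, x, plan, imp)
}
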