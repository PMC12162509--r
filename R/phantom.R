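# Deterministic multi-modal phantom generator.
#
# Each case is a brain-shaped ellipsoid of nonzero intensity on an
# exact-zero background, carrying three concentric tumor ellipsoids that
# realize the nested regions: ET (label 4) inside TC (adds NCR, label 1)
# inside WT (adds edema, label 2).  The four "modalities" assign each
# tissue a distinct mean intensity with partially redundant contrasts, plus
# i.i.d. Gaussian noise inside the brain mask.  Everything is a pure
# function of (seed, case_index).

.default_intensities <- function() {
  m <- rbind(background = c(0.00, 0.00, 0.00, 0.00),
             brain      = c(0.45, 0.45, 0.40, 0.35),
             ED         = c(0.55, 0.50, 0.85, 0.90),
             NCR        = c(0.30, 0.25, 0.70, 0.55),
             ET         = c(0.80, 0.95, 0.60, 0.50))
  colnames(m) <- c("t1", "t1ce", "t2", "flair")
  m
}

#' Phantom configuration
#'
#' @param shape spatial extent per axis (default 64^3).
#' @param n_cases number of cases to generate.
#' @param radii named or ordered vector (r_wt, r_tc, r_et) of tumor
#'   ellipsoid radii in voxels, nested r_wt > r_tc >= r_et >= 0; default
#'   scales with the volume (about 20%, 12.5% and 6% of the extent, i.e.
#'   13, 8, 4 voxels at 64^3).
#' @param center_jitter maximum per-axis tumor center displacement (voxels).
#' @param radius_jitter relative per-case radius perturbation (fraction).
#' @param intensity_means 5 x 4 matrix of tissue (background, brain, ED,
#'   NCR, ET) by modality mean intensities.
#' @param noise_sd additive Gaussian noise standard deviation inside the
#'   brain mask (default 0.05).
#' @param seed base seed; case i uses a seed derived from (seed, i).
#' @return An object of class \code{phantom_config}.
#' @export
phantom_config <- function(shape = c(64L, 64L, 64L), n_cases = 10L,
                           radii = NULL, center_jitter = 3L,
                           radius_jitter = 0.15,
                           intensity_means = .default_intensities(),
                           noise_sd = 0.05, seed = 1L) {
  shape <- as.integer(rep(shape, length.out = 3L))
  if (is.null(radii)) {
    radii <- pmax(round(min(shape) * c(0.20, 0.125, 0.0625)), c(2, 1, 0))
  }
  radii <- as.numeric(radii)
  if (!(radii[1] > radii[2] && radii[2] >= radii[3] && radii[3] >= 0)) {
    stop("radii must satisfy r_wt > r_tc >= r_et >= 0")
  }
  if (radii[1] * (1 + radius_jitter) + center_jitter > min(shape) / 2) {
    stop("shape cannot accommodate r_wt plus jitter")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(nrow(intensity_means) == 5L, ncol(intensity_means) == 4L)
  structure(list(shape = shape, n_cases = as.integer(n_cases), radii = radii,
                 center_jitter = as.integer(center_jitter),
                 radius_jitter = radius_jitter,
                 intensity_means = intensity_means,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_config")
}

.ellipsoid_mask <- function(shape, center, r) {
  if (r <= 0) return(array(FALSE, dim = shape))
  d <- lapply(1:3, function(a) ((seq_len(shape[a]) - center[a]) / r)^2)
  g <- outer(outer(d[[1]], d[[2]], `+`), d[[3]], `+`)
  g <= 1
}

#' Generate one phantom case
#'
#' @param config a \code{phantom_config}.
#' @param case_index 1-based case number.
#' @return List with \code{volume} (4, D, H, W modality array),
#'   \code{labels} (D, H, W integer array in \{0,1,2,4\}) and the realized
#'   \code{radii} and \code{center}.
#' @export
generate_case <- function(config, case_index) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed + 7919L * as.integer(case_index))
  shape <- config$shape
  jitter <- if (config$center_jitter > 0) {
    sample(seq(-config$center_jitter, config$center_jitter), 3L, replace = TRUE)
  } else c(0L, 0L, 0L)
  center <- (shape + 1) / 2 + jitter
  scale <- 1 + runif(3L, -config$radius_jitter, config$radius_jitter)
  r <- config$radii * scale
  # re-impose nesting after jitter
  r[2] <- min(r[2], r[1] - 1)
  r[3] <- max(min(r[3], r[2]), 0)
  brain <- .ellipsoid_mask(shape, (shape + 1) / 2, 0.42 * min(shape))
  wt <- .ellipsoid_mask(shape, center, r[1])
  tc <- .ellipsoid_mask(shape, center, r[2])
  et <- .ellipsoid_mask(shape, center, r[3])
  labels <- array(0L, dim = shape)
  labels[wt] <- 2L          # edema shell
  labels[tc] <- 1L          # necrotic core shell
  labels[et] <- 4L          # enhancing center
  labels[!brain] <- 0L
  # tissue row index into the intensity table
  tissue <- array(1L, dim = shape)
  tissue[brain] <- 2L
  tissue[labels == 2L] <- 3L
  tissue[labels == 1L] <- 4L
  tissue[labels == 4L] <- 5L
  nvox <- prod(shape)
  volume <- array(0, dim = c(4L, shape))
  vm <- matrix(volume, nrow = 4L)
  tv <- as.vector(tissue)
  inb <- as.vector(brain)
  for (m in 1:4) {
    x <- config$intensity_means[tv, m]
    if (config$noise_sd > 0) x[inb] <- x[inb] + rnorm(sum(inb), 0, config$noise_sd)
    x[!inb] <- 0
    vm[m, ] <- x
  }
  volume <- array(vm, dim = c(4L, shape))
  dimnames(volume) <- c(list(colnames(config$intensity_means)),
                        vector("list", 3L))
  list(volume = volume, labels = validate_labels(labels),
       radii = r, center = center)
}

#' Generate a phantom dataset on disk
#'
#' Writes each case as four modality NIfTI files plus one label file, and a
#' CSV manifest (case_id, seed, realized radii) that allows exact
#' regeneration.
#'
#' @param config a \code{phantom_config}.
#' @param out_dir output directory (created if missing).
#' @return The manifest data.frame, invisibly; also written as
#'   \code{manifest.csv}.
#' @export
generate_dataset <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  modnames <- colnames(config$intensity_means)
  rows <- lapply(seq_len(config$n_cases), function(i) {
    case <- generate_case(config, i)
    id <- sprintf("case_%03d", i)
    for (m in 1:4) {
      write_volume(array(case$volume[m, , , ], config$shape),
                   file.path(out_dir, sprintf("%s_%s.nii.gz", id, modnames[m])))
    }
    write_volume(case$labels,
                 file.path(out_dir, sprintf("%s_seg.nii.gz", id)))
    data.frame(case_id = id, seed = config$seed,
               r_wt = case$radii[1], r_tc = case$radii[2], r_et = case$radii[3],
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
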