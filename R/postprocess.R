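# Region probabilities -> integer labels: threshold cascade plus the two
# enhancing-tumor component rules.
#
# The cascade follows the region nesting: a voxel whose WT probability is
# below 0.45 is background; otherwise, TC below 0.40 makes it edema (2);
# otherwise, ET below 0.45 makes it NCR (1); otherwise it is enhancing
# tumor (4).  Two ET clean-up stages follow: per-component (components
# smaller than 16 voxels with mean ET probability below 0.9 become NCR) and
# global (if fewer than 73 ET voxels remain in total with mean probability
# below 0.9, all become NCR).

#' Post-processing configuration
#'
#' @param thr_wt,thr_tc,thr_et region probability thresholds of the cascade
#'   (0.45, 0.40, 0.45); comparisons are strict.
#' @param comp_min_size per-component ET size threshold (16 voxels).
#' @param comp_mean_thr per-component mean ET probability threshold (0.9).
#' @param global_et_max global ET voxel-count threshold (73).
#' @param global_mean_thr global mean ET probability threshold (0.9).
#' @param connectivity component connectivity: 6, 18 or 26 (default 26).
#' @param enable_component_rules run the two ET stages after the cascade.
#' @return An object of class \code{postprocess_config}.
#' @export
postprocess_config <- function(thr_wt = 0.45, thr_tc = 0.40, thr_et = 0.45,
                               comp_min_size = 16L, comp_mean_thr = 0.9,
                               global_et_max = 73L, global_mean_thr = 0.9,
                               connectivity = 26L,
                               enable_component_rules = TRUE) {
  thr <- c(thr_wt, thr_tc, thr_et)
  if (any(thr <= 0 | thr >= 1)) stop("thresholds must lie in (0, 1)")
  if (comp_min_size < 0 || global_et_max < 0) stop("sizes must be >= 0")
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  structure(list(thr_wt = thr_wt, thr_tc = thr_tc, thr_et = thr_et,
                 comp_min_size = as.integer(comp_min_size),
                 comp_mean_thr = comp_mean_thr,
                 global_et_max = as.integer(global_et_max),
                 global_mean_thr = global_mean_thr,
                 connectivity = as.integer(connectivity),
                 enable_component_rules = isTRUE(enable_component_rules)),
            class = "postprocess_config")
}

#' Threshold cascade: region probabilities to labels
#'
#' @param probs 4D array (3, D, H, W) of WT/TC/ET probabilities in \[0, 1\].
#' @param config a \code{postprocess_config}.
#' @return 3D integer label volume with values in \{0, 1, 2, 4\}.
#' @export
regions_to_labels <- function(probs, config = postprocess_config()) {
  d <- dim(probs)
  if (length(d) != 4L || d[1] != 3L) stop("probs must have 3 region channels")
  m <- matrix(probs, nrow = 3L)
  if (min(m) < 0 || max(m) > 1) stop("probabilities must lie in [0, 1]")
  lab <- ifelse(m[1, ] < config$thr_wt, 0L,
                ifelse(m[2, ] < config$thr_tc, 2L,
                       ifelse(m[3, ] < config$thr_et, 1L, 4L)))
  array(as.integer(lab), dim = d[-1])
}

#' Relabel small low-confidence ET components as NCR
#'
#' Each ET connected component whose size is below \code{comp_min_size} and
#' whose mean ET probability is below \code{comp_mean_thr} is relabeled to
#' NCR (1); everything else is untouched.  The operation is idempotent.
#'
#' @param labels 3D label volume (\{0,1,2,4\}).
#' @param et_probs co-registered 3D array of ET probabilities.
#' @param config a \code{postprocess_config}.
#' @return Modified label volume.
#' @export
filter_et_components <- function(labels, et_probs, config = postprocess_config()) {
  if (!identical(dim(labels), dim(et_probs))) stop("label/probability shape mismatch")
  et <- labels == 4L
  if (!any(et)) return(labels)
  comp <- cpp_label_components(as.logical(et), dim(labels), config$connectivity)
  cc <- comp[et]
  sizes <- tabulate(cc)
  means <- vapply(seq_along(sizes),
                  function(k) mean(et_probs[comp == k]), numeric(1))
  drop <- which(sizes < config$comp_min_size & means < config$comp_mean_thr)
  if (length(drop)) labels[comp %in% drop] <- 1L
  labels
}

#' Global ET replacement rule
#'
#' If the total ET voxel count is below \code{global_et_max} and the mean ET
#' probability over those voxels is below \code{global_mean_thr}, every ET
#' voxel becomes NCR.
#'
#' @inheritParams filter_et_components
#' @return Modified label volume.
#' @export
global_et_replacement <- function(labels, et_probs, config = postprocess_config()) {
  if (!identical(dim(labels), dim(et_probs))) stop("label/probability shape mismatch")
  et <- labels == 4L
  n <- sum(et)
  if (n == 0) return(labels)
  if (n < config$global_et_max && mean(et_probs[et]) < config$global_mean_thr) {
    labels[et] <- 1L
  }
  labels
}

#' Full post-processing pipeline
#'
#' Threshold cascade followed (when enabled) by the per-component and global
#' ET stages, in that order.
#'
#' @param probs 4D array (3, D, H, W) of region probabilities.
#' @param config a \code{postprocess_config}.
#' @return 3D integer label volume.
#' @export
postprocess_labels <- function(probs, config = postprocess_config()) {
  labels <- regions_to_labels(probs, config)
  if (config$enable_component_rules) {
    d <- dim(probs)[-1]
    et_probs <- array(probs[3, , , ], d)
    labels <- filter_et_components(labels, et_probs, config)
    labels <- global_et_replacement(labels, et_probs, config)
  }
  labels
}
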