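# Label vocabulary and region target encoding.
#
# Voxel labels follow the BraTS convention: 0 background, 1 necrotic /
# non-enhancing core (NCR), 2 peritumoral edema (ED), 4 enhancing tumor (ET).
# The network is trained on three overlapping binary regions instead of
# mutually exclusive classes: WT (whole tumor) = {1,2,4}, TC (tumor core) =
# {1,4}, ET = {4}, so ET <= TC <= WT at every voxel.

BRATS_LABELS <- c(0L, 1L, 2L, 4L)
REGION_NAMES <- c("WT", "TC", "ET")

#' Validate a label volume
#'
#' Checks that a 3D integer label volume uses only the BraTS vocabulary
#' \{0, 1, 2, 4\}.
#'
#' @param labels 3D array of integer voxel labels.
#' @return The validated array (invisibly), with integer storage.
#' @export
validate_labels <- function(labels) {
  if (length(dim(labels)) != 3L) {
    stop("labels must have exactly 3 spatial axes, got ",
         length(dim(labels)))
  }
  bad <- setdiff(unique(as.vector(labels)), BRATS_LABELS)
  if (length(bad)) {
    stop("unknown label value(s): ", paste(bad, collapse = ", "),
         " (allowed: 0, 1, 2, 4)")
  }
  storage.mode(labels) <- "integer"
  invisible(labels)
}

#' Encode integer labels as overlapping region masks
#'
#' Converts a \{0,1,2,4\} label volume into the 3-channel binary region
#' target (WT, TC, ET) used by the sigmoid output heads.  The channels are
#' nested: every ET voxel is also TC, every TC voxel also WT.
#'
#' @param labels 3D array of voxel labels in \{0, 1, 2, 4\}.
#' @return 4D binary array with dim \code{c(3, dim(labels))}; channel order
#'   WT, TC, ET.
#' @examples
#' lab <- array(0L, c(4, 4, 4)); lab[2, 2, 2] <- 4L; lab[3, 3, 3] <- 2L
#' regions <- labels_to_regions(lab)
#' regions[, 2, 2, 2]  # 1 1 1: ET voxels belong to all three regions
#' @export
labels_to_regions <- function(labels) {
  labels <- validate_labels(labels)
  d <- dim(labels)
  out <- array(0, dim = c(3L, d))
  m <- matrix(0, nrow = 3L, ncol = prod(d))
  v <- as.vector(labels)
  m[1, ] <- as.numeric(v %in% c(1L, 2L, 4L))
  m[2, ] <- as.numeric(v %in% c(1L, 4L))
  m[3, ] <- as.numeric(v == 4L)
  array(m, dim = c(3L, d))
}

#' Salient-voxel foreground channel
#'
#' Builds the binary input channel marking voxels where any modality is
#' nonzero.  Skull-stripped MRI has exact-zero background, so this channel
#' flags the brain support; it is appended to the modality stack when the
#' network is configured with an extra input channel.
#'
#' @param volume 4D array (C, D, H, W) of modality intensities.
#' @return 3D binary array (D, H, W).
#' @export
foreground_channel <- function(volume) {
  d <- dim(volume)
  if (length(d) != 4L) stop("volume must be a 4D (C,D,H,W) array")
  m <- matrix(volume, nrow = d[1])
  array(as.numeric(colSums(m != 0) > 0), dim = d[-1])
}

#' Nearest-neighbor downsampling of region masks
#'
#' Quantizes a 3-channel region mask to a coarser grid for the auxiliary
#' deep-supervision heads.  Sampling is voxel-wise nearest neighbor anchored
#' at index 0 (source index \code{floor(i * factor)}), so binary values and
#' region nesting are preserved exactly.
#'
#' @param mask 4D binary array (3, D, H, W).
#' @param factor integer downsampling factor, scalar or per-axis length 3.
#' @return 4D binary array (3, ceiling(D/f), ceiling(H/f), ceiling(W/f)).
#' @export
downsample_regions_nn <- function(mask, factor) {
  d <- dim(mask)
  if (length(d) != 4L) stop("mask must be a 4D (3,D,H,W) array")
  factor <- as.integer(rep(factor, length.out = 3L))
  if (any(factor < 1L)) stop("factor must be >= 1")
  idx <- lapply(1:3, function(a) {
    n_out <- ceiling(d[a + 1L] / factor[a])
    pmin(floor((seq_len(n_out) - 1L) * factor[a]) + 1L, d[a + 1L])
  })
  mask[, idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}
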