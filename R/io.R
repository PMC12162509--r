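# NIfTI readers/writers and case records.
#
# Volumes travel as plain R arrays: modalities channels-first (C,D,H,W) in
# memory, one 3D NIfTI file per modality (or a single 4D file) on disk;
# probability maps are stored as 4D NIfTI with the region channel last.

#' Read / write a single NIfTI volume
#'
#' @param path file path (.nii or .nii.gz).
#' @param x 3D array (labels kept integer) to write.
#' @param datatype on-disk datatype; \code{"float"} (32-bit) for
#'   intensities and probabilities, \code{"int16"} for labels.
#' @return \code{read_volume}: the array with NIfTI attributes dropped.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attr(arr, "affine") <- RNifti::xform(img)
  arr
}

#' @rdname read_volume
#' @export
write_volume <- function(x, path, datatype = if (is.integer(x)) "int16" else "float") {
  RNifti::writeNifti(RNifti::asNifti(x), path, datatype = datatype)
  invisible(path)
}

#' Read / write a 3-channel region probability map
#'
#' Stored on disk as a 4D NIfTI (D, H, W, 3) with channels WT, TC, ET.
#'
#' @param probs 4D array (3, D, H, W).
#' @param path file path.
#' @return \code{read_probabilities}: 4D array (3, D, H, W).
#' @export
write_probabilities <- function(probs, path) {
  stopifnot(length(dim(probs)) == 4L, dim(probs)[1] == 3L)
  write_volume(aperm(probs, c(2, 3, 4, 1)), path, datatype = "float")
}

#' @rdname write_probabilities
#' @export
read_probabilities <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 4L || dim(arr)[4] != 3L) {
    stop("expected a 4D (D,H,W,3) probability file: ", path)
  }
  aperm(arr, c(4, 1, 2, 3))
}

#' Case record
#'
#' Binds the file paths of one case: four ordered modality volumes and an
#' optional label volume.
#'
#' @param case_id identifier.
#' @param modality_paths character vector of modality NIfTI paths (4), or a
#'   single 4D NIfTI path.
#' @param label_path optional label NIfTI path.
#' @param fold optional fold assignment.
#' @return An object of class \code{case_record}.
#' @export
case_record <- function(case_id, modality_paths, label_path = NULL, fold = NA) {
  for (p in c(modality_paths, label_path)) {
    if (!file.exists(p)) stop("missing file: ", p)
  }
  structure(list(case_id = case_id, modality_paths = modality_paths,
                 label_path = label_path, fold = fold),
            class = "case_record")
}

.check_affines <- function(affines, paths, tol = 1e-4) {
  ref <- affines[[1]]
  for (i in seq_along(affines)[-1]) {
    if (max(abs(affines[[i]] - ref)) > tol) {
      stop("affine mismatch between ", paths[1], " and ", paths[i])
    }
  }
}

#' Read a case into memory
#'
#' Stacks the modalities in declared order into a (4, D, H, W) array,
#' validates shapes and affines across files, and validates label values
#' against \{0, 1, 2, 4\}.
#'
#' @param record a \code{case_record}.
#' @return List with \code{volume}, \code{labels} (NULL when unlabeled),
#'   \code{affine}, \code{case_id}.
#' @export
read_case <- function(record) {
  stopifnot(inherits(record, "case_record"))
  mp <- record$modality_paths
  if (length(mp) == 1L) {
    arr <- read_volume(mp)
    if (length(dim(arr)) != 4L) stop("single modality file must be 4D: ", mp)
    volume <- aperm(arr, c(4, 1, 2, 3))
    affines <- list(attr(arr, "affine"))
  } else {
    imgs <- lapply(mp, read_volume)
    dims <- lapply(imgs, dim)
    if (length(unique(lapply(dims, as.integer))) != 1L) {
      stop("modality shape mismatch in case ", record$case_id)
    }
    affines <- lapply(imgs, attr, "affine")
    .check_affines(affines, mp)
    volume <- array(0, dim = c(length(imgs), dims[[1]]))
    for (m in seq_along(imgs)) volume[m, , , ] <- imgs[[m]]
  }
  if (any(!is.finite(volume))) stop("non-finite intensities in case ", record$case_id)
  labels <- NULL
  if (!is.null(record$label_path)) {
    lab <- read_volume(record$label_path)
    laffine <- attr(lab, "affine")
    attr(lab, "affine") <- NULL
    if (!identical(as.integer(dim(lab)), as.integer(dim(volume)[-1]))) {
      stop("label shape mismatch in case ", record$case_id)
    }
    .check_affines(list(affines[[1]], laffine),
                   c(mp[1], record$label_path))
    labels <- validate_labels(array(as.integer(round(lab)), dim = dim(lab)))
  }
  list(volume = volume, labels = labels, affine = affines[[1]],
       case_id = record$case_id)
}

# read every case listed in a phantom-style dataset directory
.read_dataset <- function(data_dir, with_labels = TRUE) {
  manifest <- read.csv(file.path(data_dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  modnames <- c("t1", "t1ce", "t2", "flair")
  lapply(manifest$case_id, function(id) {
    rec <- case_record(
      id,
      file.path(data_dir, sprintf("%s_%s.nii.gz", id, modnames)),
      label_path = if (with_labels)
        file.path(data_dir, sprintf("%s_seg.nii.gz", id)) else NULL)
    read_case(rec)
  })
}
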