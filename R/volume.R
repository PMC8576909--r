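#' CT volume container
#'
#' A 3D scalar field in Hounsfield units (HU) with anisotropic voxel spacing.
#' Axes are ordered (axial, coronal, sagittal) throughout the package and all
#' voxel indices are 0-based with half-open crop windows.
#'
#' @param values 3D numeric array of HU values.
#' @param spacing_mm numeric triple, mm per voxel along (axial, coronal,
#'   sagittal).
#' @param origin physical coordinate of voxel (0,0,0); defaults to the zero
#'   vector.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(values, spacing_mm, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite voxel at (axial=%d, coronal=%d, sagittal=%d)",
                 bad[1] - 1L, bad[2] - 1L, bad[3] - 1L))
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) {
    stop("spacing_mm must be three strictly positive values")
  }
  structure(list(values = values, spacing_mm = spacing_mm,
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, HU range [%.0f, %.0f]\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2],
              x$spacing_mm[3], min(x$values), max(x$values)))
  invisible(x)
}

#' Binary mask aligned to a CT volume
#'
#' @param values 3D array coercible to {0,1}.
#' @return An integer {0,1} 3D array of class `binary_mask`.
#' @export
binary_mask <- function(values) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  v <- array(as.integer(values != 0), dim = dim(values))
  class(v) <- c("binary_mask", class(v))
  v
}

as_mask_array <- function(m) {
  if (inherits(m, "binary_mask")) return(unclass(m))
  if (is.array(m) && length(dim(m)) == 3L) return(array(as.integer(m != 0), dim = dim(m)))
  stop("expected a binary_mask or 3D array")
}

#' Connected components of a binary mask
#'
#' 6-connected labelling; used to recover individual nodules from a mask.
#'
#' @param mask binary mask or 3D array.
#' @return list with `labels` (3D integer array, 0 = background) and `n`
#'   (number of components).
#' @export
connected_components <- function(mask) {
  m <- as_mask_array(mask)
  res <- label3(as.integer(m), dim(m))
  list(labels = array(res$labels, dim = dim(m)), n = res$n)
}

#' Equivalent-sphere diameter of a voxel set
#'
#' Inverts the sphere volume formula on `count * prod(spacing)`.
#'
#' @param n_voxels voxel count of the component.
#' @param spacing_mm voxel spacing triple in mm.
#' @return diameter in mm.
#' @export
equivalent_diameter_mm <- function(n_voxels, spacing_mm) {
  vol <- n_voxels * prod(spacing_mm)
  2 * (3 * vol / (4 * pi))^(1 / 3)
}

#' Nodule annotation record
#'
#' One rater's record for one nodule: either a contour-derived mask or a
#' (center voxel, diameter mm) pair, plus a malignancy level 1-5.
#'
#' @param rater_id identifier of the annotating rater.
#' @param malignancy_level integer in 1..5.
#' @param mask optional per-rater binary mask.
#' @param center_voxel optional 0-based voxel triple.
#' @param diameter_mm optional diameter in mm.
#' @return An object of class `nodule_annotation`.
#' @export
nodule_annotation <- function(rater_id, malignancy_level, mask = NULL,
                              center_voxel = NULL, diameter_mm = NULL) {
  malignancy_level <- as.integer(malignancy_level)
  if (!malignancy_level %in% 1:5) stop("malignancy_level must be in 1..5")
  if (is.null(mask) && (is.null(center_voxel) || is.null(diameter_mm))) {
    stop("annotation needs a mask or a (center_voxel, diameter_mm) pair")
  }
  structure(list(rater_id = rater_id, malignancy_level = malignancy_level,
                 mask = if (is.null(mask)) NULL else as_mask_array(mask),
                 center_voxel = center_voxel, diameter_mm = diameter_mm),
            class = "nodule_annotation")
}
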