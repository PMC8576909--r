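# Morphological CT preprocessing: lung-window normalization, parenchyma
# extraction (threshold -> delete ambient air/bed -> keep lungs -> fill
# holes -> morphological repair), resampling to the common grid, the
# 48x192x192 subcase split, 16x48x48 ROI cropping, and the consensus /
# malignancy / size labeling rules.

#' Window a CT volume to [0, 1] grayscale
#'
#' Lung-window normalization: HU values are clipped to `[lo_hu, hi_hu]` and
#' affinely mapped to `[0, 1]`. The default window is -1000..400 HU.
#'
#' @param ct a [ct_volume()] or 3D HU array.
#' @param lo_hu,hi_hu window bounds in HU, `lo_hu < hi_hu`.
#' @return 3D array in `[0, 1]`.
#' @export
window_to_grayscale <- function(ct, lo_hu = -1000, hi_hu = 400) {
  if (lo_hu >= hi_hu) stop("lo_hu must be < hi_hu")
  v <- if (inherits(ct, "ct_volume")) ct$values else ct
  if (any(!is.finite(v))) {
    bad <- which(!is.finite(v), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite voxel at (axial=%d, coronal=%d, sagittal=%d)",
                 bad[1] - 1L, bad[2] - 1L, bad[3] - 1L))
  }
  (pmin(pmax(v, lo_hu), hi_hu) - lo_hu) / (hi_hu - lo_hu)
}

# offsets of an ellipsoid structuring element with physical radius r_mm
ellipsoid_offsets <- function(r_mm, spacing_mm) {
  rad <- pmax(1L, round(r_mm / spacing_mm))
  g <- as.matrix(expand.grid(-rad[1]:rad[1], -rad[2]:rad[2], -rad[3]:rad[3]))
  keep <- (g[, 1] / rad[1])^2 + (g[, 2] / rad[2])^2 + (g[, 3] / rad[3])^2 <= 1
  g[keep, , drop = FALSE]
}

#' Extract the lung parenchyma mask
#'
#' Low-density voxels are isolated with a fixed -320 HU threshold, components
#' touching the volume faces (ambient air, and air around the bed) are
#' removed, the largest one or two remaining components are kept as the
#' lungs, internal holes (vessels, nodules) are filled per axial slice, and
#' the boundary is repaired by morphological closing with an ellipsoid
#' element of 4.5 mm physical radius.
#'
#' @param ct a [ct_volume()] with at least 2 axial slices.
#' @param threshold_hu binarization cut; -320 HU separates parenchyma from
#'   soft tissue.
#' @return [binary_mask()] of the parenchyma.
#' @export
segment_lung_parenchyma <- function(ct, threshold_hu = -320) {
  stopifnot(inherits(ct, "ct_volume"))
  shape <- dim(ct$values)
  if (shape[1] < 2) stop("need at least 2 axial slices")
  low <- array(as.integer(ct$values < threshold_hu), dim = shape)
  lab <- label3(as.integer(low), shape)
  labels <- array(lab$labels, dim = shape)
  if (lab$n == 0) {
    stop(sprintf("empty parenchyma: no voxels below %g HU", threshold_hu))
  }
  # drop components 6-connected to any volume face
  border <- unique(c(labels[c(1, shape[1]), , ], labels[, c(1, shape[2]), ],
                     labels[, , c(1, shape[3])]))
  border <- border[border > 0]
  sizes <- tabulate(labels, nbins = lab$n)
  sizes[border] <- 0L
  if (all(sizes == 0L)) {
    stop(sprintf("empty parenchyma: %d low-density component(s), all touching the volume border",
                 lab$n))
  }
  # keep the largest one or two interior components (the lungs); a second
  # component is kept only when comparable in size to the first
  ord <- order(sizes, decreasing = TRUE)
  keep <- ord[1]
  if (lab$n >= 2 && sizes[ord[2]] >= 0.2 * sizes[ord[1]]) keep <- ord[1:2]
  lung <- array(as.integer(labels %in% keep), dim = shape)
  lung <- fill_holes_axial(as.integer(lung), shape)
  se <- ellipsoid_offsets(4.5, ct$spacing_mm)
  lung <- binary_morph3(binary_morph3(lung, shape, se, TRUE), shape, se, FALSE)
  binary_mask(array(lung, dim = shape))
}

#' Resample a CT volume to a target voxel spacing
#'
#' Trilinear interpolation for intensities, nearest-neighbour for masks.
#' The output shape is `round(shape * spacing / target)`, preserving the
#' physical extent to within one voxel.
#'
#' @param ct a [ct_volume()].
#' @param target_spacing_mm spacing triple, default the common 3 x 1.5 x
#'   1.5 mm grid.
#' @param mode `"linear"` for intensities, `"nearest"` for label fields.
#' @return resampled [ct_volume()].
#' @export
resample_volume <- function(ct, target_spacing_mm = c(3, 1.5, 1.5),
                            mode = c("linear", "nearest")) {
  stopifnot(inherits(ct, "ct_volume"))
  mode <- match.arg(mode)
  target <- as.numeric(target_spacing_mm)
  if (length(target) != 3L || any(target <= 0)) {
    stop("target_spacing_mm must be three positive values")
  }
  if (isTRUE(all.equal(ct$spacing_mm, target))) return(ct)
  res <- resample3(as.numeric(ct$values), dim(ct$values), ct$spacing_mm,
                   target, mode == "nearest")
  ct_volume(array(res$values, dim = res$dim), target, ct$origin)
}

#' @rdname resample_volume
#' @param mask a [binary_mask()] on the same grid as the volume it belongs to.
#' @param source_spacing_mm spacing of the mask's grid.
#' @export
resample_mask <- function(mask, source_spacing_mm,
                          target_spacing_mm = c(3, 1.5, 1.5)) {
  m <- as_mask_array(mask)
  res <- resample3(as.numeric(m), dim(m), as.numeric(source_spacing_mm),
                   as.numeric(target_spacing_mm), TRUE)
  binary_mask(array(res$values, dim = res$dim))
}

# Crop-or-pad `vol` to `size` with the window starting at 0-based `start`
# in source coordinates (negative start = leading padding).
crop_pad <- function(vol, start, size, pad_value) {
  out <- array(pad_value, dim = size)
  src_lo <- pmax(start, 0L)
  src_hi <- pmin(start + size, dim(vol))
  if (all(src_hi > src_lo)) {
    dst_lo <- src_lo - start
    out[(dst_lo[1] + 1):(dst_lo[1] + src_hi[1] - src_lo[1]),
        (dst_lo[2] + 1):(dst_lo[2] + src_hi[2] - src_lo[2]),
        (dst_lo[3] + 1):(dst_lo[3] + src_hi[3] - src_lo[3])] <-
      vol[(src_lo[1] + 1):src_hi[1], (src_lo[2] + 1):src_hi[2],
          (src_lo[3] + 1):src_hi[3]]
  }
  out
}

#' Split a resampled case into two 48 x 192 x 192 subcases
#'
#' The axial axis is split into two halves, each cropped or padded to 48
#' slices (pad value -1000 HU, i.e. air); in-plane the volume is
#' center-cropped or padded to 192 x 192. The returned transform records the
#' 0-based source start of each subcase window so masks map back and forth.
#'
#' @param ct a [ct_volume()] on the common spacing grid.
#' @param subcase_shape output shape per half, default `c(48, 192, 192)`.
#' @param pad_value fill HU for out-of-volume voxels.
#' @return list with `subcases` (list of two [ct_volume()]) and `transform`
#'   (per half, the 0-based `src_start` of the window).
#' @export
split_subcases <- function(ct, subcase_shape = c(48L, 192L, 192L),
                           pad_value = -1000) {
  stopifnot(inherits(ct, "ct_volume"))
  shape <- dim(ct$values)
  sc <- as.integer(subcase_shape)
  half <- shape[1] %/% 2L
  depths <- c(half, shape[1] - half)
  ax_start <- c(0L, half)
  # each half is first isolated so axial padding never leaks slices from
  # the other half, then crop/padded to the subcase shape
  starts <- vector("list", 2)
  subcases <- vector("list", 2)
  for (i in 1:2) {
    slices <- (ax_start[i] + 1):(ax_start[i] + depths[i])
    halfvol <- ct$values[slices, , , drop = FALSE]
    s <- c(-((sc[1] - depths[i]) %/% 2L),
           (shape[2] - sc[2]) %/% 2L,
           (shape[3] - sc[3]) %/% 2L)
    subcases[[i]] <- ct_volume(crop_pad(halfvol, as.integer(s), sc, pad_value),
                               ct$spacing_mm, ct$origin)
    starts[[i]] <- c(ax_start[i] + s[1], s[2], s[3])
  }
  list(subcases = subcases,
       transform = list(src_start = starts, subcase_shape = sc,
                        case_shape = shape, half_depths = depths,
                        half_axial_start = ax_start))
}

#' Map voxel coordinates between subcase and case frames
#'
#' @param coords matrix (n x 3) of 0-based voxel triples.
#' @param transform the transform record from [split_subcases()].
#' @param half which subcase (1 or 2).
#' @return matrix of mapped 0-based coordinates.
#' @export
subcase_to_case <- function(coords, transform, half) {
  sweep(as.matrix(coords), 2, as.numeric(transform$src_start[[half]]), "+")
}

#' @rdname subcase_to_case
#' @export
case_to_subcase <- function(coords, transform, half) {
  sweep(as.matrix(coords), 2, as.numeric(transform$src_start[[half]]), "-")
}

#' Crop a classification ROI around a nodule component
#'
#' The 16 x 48 x 48 window is centered on the component's rounded voxel
#' centroid; parts outside the volume are padded with -1000 HU.
#'
#' @param ct a [ct_volume()].
#' @param nodule_component [binary_mask()] of a single nodule (nonempty).
#' @param roi_shape output shape, default `c(16, 48, 48)`.
#' @param pad_value fill HU.
#' @return 3D array of shape `roi_shape` (HU values).
#' @export
crop_roi <- function(ct, nodule_component, roi_shape = c(16L, 48L, 48L),
                     pad_value = -1000) {
  stopifnot(inherits(ct, "ct_volume"))
  comp <- as_mask_array(nodule_component)
  idx <- which(comp > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty nodule component")
  centroid <- round(colMeans(idx - 1L))
  rs <- as.integer(roi_shape)
  start <- as.integer(centroid) - rs %/% 2L
  crop_pad(ct$values, start, rs, pad_value)
}

#' Multi-rater consensus mask
#'
#' A voxel belongs to the ground truth iff at least `min_raters` distinct
#' raters marked it.
#'
#' @param annotations list of [nodule_annotation()] with masks on one grid,
#'   or a list of binary masks.
#' @param min_raters consensus threshold, default 3.
#' @return [binary_mask()].
#' @export
consensus_mask <- function(annotations, min_raters = 3L) {
  masks <- lapply(annotations, function(a) {
    if (inherits(a, "nodule_annotation")) {
      if (is.null(a$mask)) stop("annotation has no mask")
      a$mask
    } else as_mask_array(a)
  })
  dims <- lapply(masks, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stop("annotation masks are on different grids")
  }
  rater <- vapply(annotations, function(a) {
    if (inherits(a, "nodule_annotation")) as.character(a$rater_id) else NA_character_
  }, "")
  if (!anyNA(rater)) {
    # count distinct raters per voxel, not records
    votes <- Reduce(`+`, lapply(unique(rater), function(r) {
      sub <- masks[rater == r]
      m <- Reduce(function(a, b) pmax(a, b), sub)
      array(as.integer(m > 0), dim = dim(m))
    }))
  } else {
    votes <- Reduce(`+`, masks)
  }
  binary_mask(votes >= min_raters)
}

#' Reduce per-rater malignancy levels to a diagnosis label
#'
#' Levels are reduced by the median (ties rounded down); a median of 1-2 is
#' benign, 4-5 malignant, and 3 (uncertain) is excluded.
#'
#' @param levels integer vector of rater levels in 1..5.
#' @return `"benign"`, `"malignant"` or `"excluded"`.
#' @export
malignancy_label <- function(levels) {
  if (length(levels) == 0L) stop("empty level list")
  levels <- as.integer(levels)
  if (!all(levels %in% 1:5)) stop("levels must be in 1..5")
  med <- floor(median(levels))
  if (med <= 2) "benign" else if (med >= 4) "malignant" else "excluded"
}

#' Size category of a nodule
#'
#' Left-open/right-closed bins: micro (d <= 5), small (5 < d <= 10), nodule
#' (10 < d <= 30), mass (30 < d), diameters in mm.
#'
#' @param diameter_mm positive diameter(s) in mm.
#' @return factor with levels micro, small, nodule, mass.
#' @export
size_category <- function(diameter_mm) {
  if (any(diameter_mm <= 0)) stop("diameter must be positive")
  cut(diameter_mm, breaks = c(0, 5, 10, 30, Inf),
      labels = c("micro", "small", "nodule", "mass"), right = TRUE)
}
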