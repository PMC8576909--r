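# On-disk formats. NIfTI (via RNifti) is the canonical volume format;
# DICOM series are input-only and handled by a minimal reader for
# uncompressed little-endian single-frame CT slices (both explicit and
# implicit VR), since no R DICOM reader is available. Annotations travel as
# JSON lines; checkpoints are RDS weight lists plus a JSON architecture
# descriptor.

# Internal arrays are (axial, coronal, sagittal); NIfTI customarily stores
# (sagittal, coronal, axial), so volumes are transposed on the way through.

#' Read a CT volume
#'
#' Accepts a NIfTI file or a directory containing a DICOM series (slices
#' sorted by image position, rescale slope/intercept applied).
#'
#' @param path file or directory path.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  img <- RNifti::readNifti(path)
  pix <- RNifti::pixdim(img)
  arr <- aperm(array(as.numeric(img), dim = dim(img)), c(3, 2, 1))
  ct_volume(arr, spacing_mm = rev(pix[1:3]))
}

#' Write a CT volume or mask as NIfTI
#'
#' @param ct a [ct_volume()] or a binary mask plus `spacing_mm`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing_mm required when `ct` is a plain array/mask.
#' @return `path`, invisibly.
#' @export
write_volume <- function(ct, path, spacing_mm = NULL) {
  if (inherits(ct, "ct_volume")) {
    arr <- ct$values; sp <- ct$spacing_mm
  } else {
    if (is.null(spacing_mm)) stop("spacing_mm required for plain arrays")
    arr <- as_mask_array(ct) * 1.0; sp <- as.numeric(spacing_mm)
  }
  img <- RNifti::asNifti(aperm(arr, c(3, 2, 1)))
  RNifti::pixdim(img) <- rev(sp)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Minimal DICOM parser ----------------------------------------------------

read_uint <- function(raw, size) sum(as.integer(raw[seq_len(size)]) * 256^(0:(size - 1)))

parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM") {
    stop(sprintf("%s: not a DICOM file (missing DICM magic)", basename(path)))
  }
  pos <- 133L
  explicit <- TRUE
  tags <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 8 <= length(raw)) {
    group <- read_uint(raw[pos:(pos + 1)], 2)
    elem <- read_uint(raw[(pos + 2):(pos + 3)], 2)
    pos <- pos + 4L
    if (explicit && group != 0xFFFE) {
      vr <- rawToChar(raw[pos:(pos + 1)])
      if (grepl("^[A-Z]{2}$", vr)) {
        if (vr %in% long_vrs) {
          len <- read_uint(raw[(pos + 4):(pos + 7)], 4)
          pos <- pos + 8L
        } else {
          len <- read_uint(raw[(pos + 2):(pos + 3)], 2)
          pos <- pos + 4L
        }
      } else {
        explicit <- FALSE
        len <- read_uint(raw[pos:(pos + 3)], 4)
        pos <- pos + 4L
      }
    } else {
      len <- read_uint(raw[pos:(pos + 3)], 4)
      pos <- pos + 4L
    }
    if (len == 0xFFFFFFFF) stop("undefined-length elements are not supported")
    key <- sprintf("%04X%04X", group, elem)
    tags[[key]] <- if (len > 0) raw[seq.int(pos, length.out = len)] else raw(0)
    pos <- pos + len
    if (key == "7FE00010") break
  }
  tags
}

dicom_str <- function(tags, key) {
  if (is.null(tags[[key]])) return(NULL)
  trimws(rawToChar(tags[[key]]))
}

dicom_num <- function(tags, key) {
  s <- dicom_str(tags, key)
  if (is.null(s)) NULL else as.numeric(strsplit(s, "\\\\")[[1]])
}

# binary unsigned-short elements (Rows, Columns, BitsAllocated, ...)
dicom_us <- function(tags, key) {
  v <- tags[[key]]
  if (is.null(v)) NULL else readBin(v, "integer", n = length(v) %/% 2,
                                    size = 2, signed = FALSE,
                                    endian = "little")
}

#' @noRd
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop(sprintf("empty directory: %s", dir))
  slices <- lapply(files, parse_dicom_file)
  rows <- dicom_us(slices[[1]], "00280010")
  cols <- dicom_us(slices[[1]], "00280011")
  pixsp <- dicom_num(slices[[1]], "00280030")
  if (is.null(pixsp)) stop("missing spacing metadata: PixelSpacing (0028,0030)")
  pos3 <- t(vapply(slices, function(s) {
    p <- dicom_num(s, "00200032")
    if (is.null(p)) stop("missing spacing metadata: ImagePositionPatient (0020,0032)")
    p
  }, numeric(3)))
  ord <- order(pos3[, 3])
  slices <- slices[ord]
  z <- pos3[ord, 3]
  if (length(z) > 1) {
    dz <- diff(z)
    if (max(dz) - min(dz) > 1e-3) {
      stop(sprintf("inconsistent DICOM slice spacing: %g vs %g mm",
                   min(dz), max(dz)))
    }
    slice_sp <- mean(dz)
  } else {
    st <- dicom_num(slices[[1]], "00180050")
    slice_sp <- if (is.null(st)) 1 else st
  }
  bits <- dicom_us(slices[[1]], "00280100")
  if (is.null(bits)) bits <- 16
  signed <- isTRUE(dicom_us(slices[[1]], "00280103") == 1)
  vol <- array(0, dim = c(length(slices), rows, cols))
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    px <- readBin(s[["7FE00010"]], "integer", n = rows * cols,
                  size = bits / 8, signed = signed, endian = "little")
    slope <- dicom_num(s, "00281053"); if (is.null(slope)) slope <- 1
    inter <- dicom_num(s, "00281052"); if (is.null(inter)) inter <- 0
    # PixelData is row-major (row by row)
    vol[i, , ] <- matrix(px * slope + inter, nrow = rows, byrow = TRUE)
  }
  ct_volume(vol, spacing_mm = c(slice_sp, pixsp[1], pixsp[2]))
}

# Minimal explicit-VR little-endian writer for a single 16-bit CT slice.
# Exists only so tests can build a synthetic 2-slice series in a tempdir;
# not a general DICOM writer.
#' @noRd
write_dicom_slice <- function(path, pixels, position = c(0, 0, 0),
                              pixel_spacing = c(1, 1), slope = 1,
                              intercept = 0) {
  pixels <- as.matrix(pixels)
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  elem_str <- function(group, elem, vr, s) {
    if (nchar(s) %% 2 == 1) s <- paste0(s, " ")
    u16(group); u16(elem); writeChar(vr, con, eos = NULL)
    u16(nchar(s)); writeChar(s, con, eos = NULL)
  }
  elem_us <- function(group, elem, v) {
    u16(group); u16(elem); writeChar("US", con, eos = NULL); u16(2); u16(v)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  elem_str(0x0020, 0x0032, "DS", paste(position, collapse = "\\"))
  elem_us(0x0028, 0x0010, nrow(pixels))
  elem_us(0x0028, 0x0011, ncol(pixels))
  elem_str(0x0028, 0x0030, "DS", paste(pixel_spacing, collapse = "\\"))
  elem_us(0x0028, 0x0100, 16)
  elem_us(0x0028, 0x0103, 1)
  elem_str(0x0028, 0x1052, "DS", format(intercept))
  elem_str(0x0028, 0x1053, "DS", format(slope))
  u16(0x7FE0); u16(0x0010); writeChar("OW", con, eos = NULL)
  u16(0); u32(2 * length(pixels))
  # row-major pixel order
  writeBin(as.integer(t(pixels)), con, size = 2, endian = "little")
  invisible(path)
}

# Annotations ------------------------------------------------------------

#' Write annotations as JSON lines
#'
#' One line per (nodule, rater) record: rater, center voxel (0-based),
#' diameter in mm, malignancy level.
#'
#' @param annotations nested list as produced by [generate_phantom()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(annotations)) {
    for (a in annotations[[i]]) {
      rec <- list(nodule = i, rater = a$rater_id,
                  center_voxel = as.numeric(a$center_voxel),
                  diameter_mm = a$diameter_mm,
                  malignancy = a$malignancy_level)
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  lapply(readLines(path), jsonlite::fromJSON)
}

#' Write a phantom sample to a cohort directory
#'
#' Writes `ct.nii.gz`, `lung_mask.nii.gz`, `nodule_mask.nii.gz` and
#' `annotations.jsonl` under `dir/<id>/`.
#'
#' @param sample a `phantom_sample`.
#' @param dir cohort directory.
#' @param id case identifier (directory name).
#' @return the case directory, invisibly.
#' @export
write_phantom_sample <- function(sample, dir, id) {
  case_dir <- file.path(dir, id)
  dir.create(case_dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(sample$ct, file.path(case_dir, "ct.nii.gz"))
  write_volume(sample$lung_mask, file.path(case_dir, "lung_mask.nii.gz"),
               sample$ct$spacing_mm)
  write_volume(sample$nodule_mask, file.path(case_dir, "nodule_mask.nii.gz"),
               sample$ct$spacing_mm)
  write_annotations(sample$annotations, file.path(case_dir, "annotations.jsonl"))
  invisible(case_dir)
}

#' Build a validated manifest of a cohort directory
#'
#' Scans case subdirectories in lexicographic order; cases missing any of
#' the expected files are flagged but still listed.
#'
#' @param dir cohort directory.
#' @param path optional path to also write the manifest as JSON.
#' @return data.frame: case_id, ct, lung_mask, nodule_mask, annotations
#'   (paths or NA), complete (flag).
#' @export
cohort_manifest <- function(dir, path = NULL) {
  cases <- sort(list.dirs(dir, recursive = FALSE))
  want <- c(ct = "ct.nii.gz", lung_mask = "lung_mask.nii.gz",
            nodule_mask = "nodule_mask.nii.gz",
            annotations = "annotations.jsonl")
  rows <- lapply(cases, function(cd) {
    p <- file.path(cd, want)
    ok <- file.exists(p)
    out <- data.frame(case_id = basename(cd),
                      t(ifelse(ok, p, NA_character_)),
                      complete = all(ok))
    names(out)[2:5] <- names(want)
    out
  })
  man <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_id = character(), ct = character(),
               lung_mask = character(), nodule_mask = character(),
               annotations = character(), complete = logical())
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  }
  man
}

# Checkpoints ------------------------------------------------------------

#' Save / load model weights
#'
#' Weights go to an RDS list keyed by layer index and parameter name; a
#' JSON descriptor with the architecture settings sits alongside so a model
#' can be rebuilt and restored.
#'
#' @param model a `seg_network` or `cls_network`.
#' @param path checkpoint path (`.rds`); the descriptor is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  layers <- collect_layers(model$blocks)
  weights <- lapply(layers, function(l) {
    stats::setNames(lapply(l$pnames, function(p) get(p, l)), l$pnames)
  })
  desc <- if (inherits(model, "seg_network")) {
    list(kind = "seg_network", channels = model$channels,
         bottleneck = model$bottleneck, in_channels = model$in_channels)
  } else {
    list(kind = "cls_network", width_mult = model$width_mult,
         in_channels = model$in_channels,
         reduced_kernels = model$reduced_kernels)
  }
  saveRDS(weights, path)
  jsonlite::write_json(desc, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  desc <- jsonlite::fromJSON(paste0(path, ".json"))
  model <- if (desc$kind == "seg_network") {
    build_segmentation_network(desc$channels, desc$bottleneck, desc$in_channels)
  } else {
    build_classifier(desc$width_mult, desc$in_channels, desc$reduced_kernels)
  }
  weights <- readRDS(path)
  layers <- collect_layers(model$blocks)
  stopifnot(length(layers) == length(weights))
  for (i in seq_along(layers)) {
    for (p in names(weights[[i]])) assign(p, weights[[i]][[p]], layers[[i]])
  }
  model
}
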