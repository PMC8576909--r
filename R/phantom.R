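# Synthetic CT phantoms: a high-attenuation body cylinder holding two
# low-attenuation lung ellipsoids, optional bed slab and vessels, plus
# spherical (benign trait) or spiculated (malignant trait) nodules with
# exactly known masks. The phantom is the test bed for every downstream
# stage; it makes no attempt at radiologically realistic texture.

# HU palette; fixed so the thresholding pipeline has a clean separation.
HU_AIR <- -1000
HU_LUNG <- -850
HU_BODY <- 40
HU_BED <- 200
HU_VESSEL <- 50

#' Phantom generator configuration
#'
#' @param volume_shape voxel triple (axial, coronal, sagittal), all >= 16.
#' @param voxel_spacing_mm spacing triple in mm; default matches the
#'   pipeline's common resampling grid.
#' @param n_nodules number of nodules to place.
#' @param diameter_range_mm min/max nodule diameter in mm, within (0, 60].
#' @param malignant_fraction probability that a nodule carries the malignant
#'   (spiculated) trait.
#' @param noise_sd_hu standard deviation of additive Gaussian noise, HU.
#' @param include_bed paint a bed slab below the body.
#' @param include_vessels paint tubular vessels inside the lungs.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(volume_shape = c(64, 128, 128),
                           voxel_spacing_mm = c(3, 1.5, 1.5),
                           n_nodules = 2,
                           diameter_range_mm = c(5, 25),
                           malignant_fraction = 0.5,
                           noise_sd_hu = 20,
                           include_bed = TRUE,
                           include_vessels = TRUE,
                           seed = 1L) {
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape < 16L)) {
    stop("volume_shape must be three integers, all >= 16")
  }
  if (length(diameter_range_mm) != 2L || diameter_range_mm[1] <= 0 ||
      diameter_range_mm[2] > 60 || diameter_range_mm[1] > diameter_range_mm[2]) {
    stop("diameter_range_mm must lie within (0, 60] with min <= max")
  }
  if (malignant_fraction < 0 || malignant_fraction > 1) {
    stop("malignant_fraction must be in [0, 1]")
  }
  structure(list(volume_shape = volume_shape,
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 n_nodules = as.integer(n_nodules),
                 diameter_range_mm = as.numeric(diameter_range_mm),
                 malignant_fraction = malignant_fraction,
                 noise_sd_hu = noise_sd_hu,
                 include_bed = isTRUE(include_bed),
                 include_vessels = isTRUE(include_vessels),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Run expr under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Squared normalized distance fields -------------------------------------

# body: elliptic cylinder along the axial axis.
phantom_body_mask <- function(shape, sp) {
  H <- shape[2]; W <- shape[3]
  hp <- H * sp[2]; wp <- W * sp[3]
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  ey <- (((seq_len(H) - 1) - cy) * sp[2] / (0.38 * hp))^2
  ex <- (((seq_len(W) - 1) - cx) * sp[3] / (0.44 * wp))^2
  plane <- outer(ey, ex, "+") <= 1
  array(rep(plane, each = shape[1]), dim = shape)
}

phantom_lung_mask <- function(shape, sp) {
  D <- shape[1]; H <- shape[2]; W <- shape[3]
  ap <- D * sp[1]; hp <- H * sp[2]; wp <- W * sp[3]
  cd <- (D - 1) / 2; cy <- (H - 1) / 2; cx <- (W - 1) / 2
  semi <- c(0.40 * ap, 0.30 * hp, 0.17 * wp)
  ed <- (((seq_len(D) - 1) - cd) * sp[1] / semi[1])^2
  ey <- (((seq_len(H) - 1) - cy) * sp[2] / semi[2])^2
  mask <- array(FALSE, dim = shape)
  for (side in c(-1, 1)) {
    cxs <- cx + side * 0.20 * wp / sp[3]
    ex <- (((seq_len(W) - 1) - cxs) * sp[3] / semi[3])^2
    mask <- mask | (outer(outer(ed, ey, "+"), ex, "+") <= 1)
  }
  mask
}

# Voxelize one nodule shape around a center (0-based voxel triple). Benign:
# sphere of radius R. Malignant: sphere of radius 0.9 R plus 4-10 narrow
# radial cones out to 1.2 R (the spiculation trait); volume stays close to
# the nominal sphere so the equivalent diameter remains recoverable.
voxelize_nodule <- function(shape, sp, center, diameter_mm, malignant,
                            spike_dirs = NULL) {
  R <- diameter_mm / 2
  reach <- if (malignant) 1.2 * R else R
  lo <- pmax(0L, floor(center - reach / sp))
  hi <- pmin(shape - 1L, ceiling(center + reach / sp))
  dd <- (lo[1]:hi[1] - center[1]) * sp[1]
  hh <- (lo[2]:hi[2] - center[2]) * sp[2]
  ww <- (lo[3]:hi[3] - center[3]) * sp[3]
  g <- expand.grid(d = dd, h = hh, w = ww)
  r <- sqrt(g$d^2 + g$h^2 + g$w^2)
  if (malignant) {
    inside <- r <= 0.9 * R
    cosa <- cos(20 * pi / 180)
    for (k in seq_len(nrow(spike_dirs))) {
      u <- spike_dirs[k, ]
      proj <- (g$d * u[1] + g$h * u[2] + g$w * u[3]) / pmax(r, 1e-9)
      inside <- inside | (r <= 1.2 * R & proj >= cosa)
    }
  } else {
    inside <- r <= R
  }
  idx <- which(inside)
  if (length(idx) == 0L) return(NULL)
  ar <- arrayInd(idx, .dim = c(length(dd), length(hh), length(ww)))
  cbind(ar[, 1] + lo[1], ar[, 2] + lo[2], ar[, 3] + lo[3])  # 0-based voxels
}

#' Generate one synthetic CT phantom
#'
#' Paints the body (+40 HU), two lung lobes (-850 HU), ambient air
#' (-1000 HU), an optional bed slab (+200 HU), optional vessels (+50 HU) and
#' the requested nodules (around -50..+80 HU base intensity), then adds
#' Gaussian noise. Lung and nodule masks are exactly consistent with the
#' painted geometry, and every nodule voxel lies inside the lung mask.
#' All random draws happen in a fixed order independent of the bed/vessel
#' flags, so toggling `include_bed` changes only the bed voxels.
#'
#' @param config a [phantom_config()].
#' @return A `phantom_sample` list: `ct` ([ct_volume()]), `lung_mask`,
#'   `nodule_mask` ([binary_mask()]), `annotations` (per nodule, a list of 4
#'   [nodule_annotation()] records), `per_nodule_diameter_mm`,
#'   `per_nodule_malignant`, `nodule_centers`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  shape <- config$volume_shape
  sp <- config$voxel_spacing_mm
  with_local_seed(config$seed, {
    n_vox <- prod(shape)
    noise <- rnorm(n_vox, 0, config$noise_sd_hu)

    body <- phantom_body_mask(shape, sp)
    lung <- phantom_lung_mask(shape, sp) & body

    # vessel parameters are always drawn so the RNG stream does not depend
    # on include_vessels
    lung_centers <- list(
      c((shape[1] - 1) / 2, (shape[2] - 1) / 2,
        (shape[3] - 1) / 2 - 0.20 * shape[3]),
      c((shape[1] - 1) / 2, (shape[2] - 1) / 2,
        (shape[3] - 1) / 2 + 0.20 * shape[3]))
    vessel_pars <- lapply(1:6, function(i) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      list(center = lung_centers[[1 + (i - 1) %% 2]], dir = u,
           len_mm = runif(1, 15, 0.35 * min(shape * sp)),
           radius_mm = runif(1, 1.0, 2.0))
    })

    n <- config$n_nodules
    malignant <- if (n > 0) runif(n) < config$malignant_fraction else logical(0)
    diam <- if (n > 0) runif(n, config$diameter_range_mm[1],
                             config$diameter_range_mm[2]) else numeric(0)
    spikes <- lapply(seq_len(n), function(i) {
      ns <- sample(4:10, 1)
      m <- matrix(rnorm(3 * ns), ncol = 3)
      m / sqrt(rowSums(m^2))
    })

    lung_idx <- which(lung)
    nodule_mask <- array(0L, dim = shape)
    nodule_vox <- vector("list", n)
    centers <- vector("list", n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in 1:100) {
        cand <- arrayInd(sample(lung_idx, 1), .dim = shape) - 1L
        vox <- voxelize_nodule(shape, sp, as.numeric(cand), diam[i],
                               malignant[i], spikes[[i]])
        if (is.null(vox)) next
        lin <- vox[, 1] + 1L + shape[1] * (vox[, 2] + shape[2] * vox[, 3])
        # keep nodules separated by at least one voxel so connected
        # components stay one-to-one with placed nodules
        nb <- c(0L, -1L, 1L, -shape[1], shape[1],
                -shape[1] * shape[2], shape[1] * shape[2])
        halo <- unique(pmin(pmax(rep(lin, each = 7) + nb, 1L), n_vox))
        if (all(lung[lin]) && !any(nodule_mask[halo] > 0)) {
          nodule_mask[lin] <- 1L
          nodule_vox[[i]] <- lin
          centers[[i]] <- as.numeric(cand)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf("could not place nodule %d (%.1f mm) inside a lung after 100 retries (seed %d)",
                     i, diam[i], config$seed))
      }
    }

    # paint
    ct <- array(HU_AIR, dim = shape)
    ct[body] <- HU_BODY
    ct[lung] <- HU_LUNG
    if (config$include_bed) {
      y0 <- floor(0.93 * shape[2]); y1 <- min(shape[2] - 1, floor(0.98 * shape[2]))
      bed <- array(FALSE, dim = shape)
      bed[, (y0 + 1):(y1 + 1), ] <- TRUE
      ct[bed & !body] <- HU_BED
    }
    if (config$include_vessels) {
      for (vp in vessel_pars) {
        steps <- seq(0, vp$len_mm, by = min(sp) / 2)
        for (t in steps) {
          cpos <- vp$center + t * vp$dir / sp
          rv <- ceiling(vp$radius_mm / sp)
          lo <- pmax(0, floor(cpos - rv)); hi <- pmin(shape - 1, ceiling(cpos + rv))
          if (any(lo > hi)) break
          for (w in lo[3]:hi[3]) for (h in lo[2]:hi[2]) for (d in lo[1]:hi[1]) {
            if (lung[d + 1, h + 1, w + 1] &&
                sum((((c(d, h, w)) - cpos) * sp)^2) <= vp$radius_mm^2) {
              ct[d + 1, h + 1, w + 1] <- HU_VESSEL
            }
          }
        }
      }
    }
    nodule_hu <- runif(max(n, 1), -50, 80)
    for (i in seq_len(n)) ct[nodule_vox[[i]]] <- nodule_hu[i]

    ct <- ct + array(noise, dim = shape)

    # four raters: jittered masks (dilate/erode by <= 1 voxel) and levels
    # drawn from the trait's plausible range
    annotations <- vector("list", n)
    for (i in seq_len(n)) {
      comp <- array(0L, dim = shape)
      comp[nodule_vox[[i]]] <- 1L
      ann <- vector("list", 4)
      for (r in 1:4) {
        jit <- sample(c(-1L, 0L, 1L), 1)
        if (diam[i] < 6 && jit < 0L) jit <- 0L
        rmask <- comp
        if (jit != 0L) {
          off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
          off <- off[rowSums(abs(off)) <= 1, , drop = FALSE]
          rmask <- array(binary_morph3(as.integer(comp), shape,
                                       off, jit > 0L), dim = shape)
        }
        lvl <- if (runif(1) < 0.1) 3L
               else if (malignant[i]) sample(4:5, 1) else sample(1:2, 1)
        ann[[r]] <- nodule_annotation(
          rater_id = r, malignancy_level = lvl, mask = rmask,
          center_voxel = centers[[i]],
          diameter_mm = equivalent_diameter_mm(sum(rmask), sp))
      }
      annotations[[i]] <- ann
    }

    structure(list(
      ct = ct_volume(ct, sp),
      lung_mask = binary_mask(lung),
      nodule_mask = binary_mask(nodule_mask),
      annotations = annotations,
      per_nodule_diameter_mm = diam,
      per_nodule_malignant = malignant,
      nodule_centers = centers,
      config = config
    ), class = "phantom_sample")
  })
}

#' Generate a cohort of phantoms
#'
#' Per-sample seeds are derived deterministically from `config$seed`, so the
#' cohort is reproducible as a whole while samples stay independent.
#'
#' @param n_samples number of phantoms (>= 1).
#' @param config a [phantom_config()]; its `seed` seeds the cohort.
#' @return list of `phantom_sample` objects.
#' @export
generate_cohort <- function(n_samples, config) {
  stopifnot(n_samples >= 1)
  seeds <- with_local_seed(config$seed,
                           sample.int(.Machine$integer.max - 1L, n_samples))
  lapply(seq_len(n_samples), function(i) {
    cfg <- config
    cfg$seed <- seeds[i]
    generate_phantom(cfg)
  })
}
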