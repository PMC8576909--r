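test_that("identical config and seed give bit-identical phantoms", {
  cfg <- phantom_config(volume_shape = c(32, 64, 64), n_nodules = 2,
                        diameter_range_mm = c(8, 16), seed = 7)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(unclass(a$lung_mask), unclass(b$lung_mask))
  expect_identical(unclass(a$nodule_mask), unclass(b$nodule_mask))
})

test_that("phantom geometry is mutually consistent", {
  s <- subvolume_phantom(3)
  lung <- unclass(s$lung_mask); nod <- unclass(s$nodule_mask)
  expect_true(all(lung[nod == 1] == 1))                    # nodule inside lung
  expect_equal(connected_components(nod)$n, 1)
  # HU contrast: lung air-like, body soft-tissue-like
  expect_lt(mean(s$ct$values[lung == 1]), -500)
  body <- nn$phantom_body_mask(dim(lung), s$ct$spacing_mm)
  expect_gt(mean(s$ct$values[body & lung == 0]), -200)
})

test_that("zero nodules give an empty nodule mask", {
  s <- generate_phantom(phantom_config(volume_shape = c(32, 64, 64),
                                       n_nodules = 0, seed = 1))
  expect_equal(sum(s$nodule_mask), 0)
  expect_length(s$per_nodule_diameter_mm, 0)
})

test_that("equivalent-sphere diameters recover the requested size", {
  s <- generate_phantom(phantom_config(
    volume_shape = c(48, 96, 96), voxel_spacing_mm = c(3, 1.5, 1.5),
    n_nodules = 3, diameter_range_mm = c(12, 12), seed = 3))
  cc <- connected_components(s$nodule_mask)
  expect_equal(cc$n, 3)
  for (i in 1:3) {
    d <- equivalent_diameter_mm(sum(cc$labels == i), s$ct$spacing_mm)
    expect_lt(abs(d - 12) / 12, 0.20)
  }
})

test_that("an oversized nodule fails placement with a clear error", {
  cfg <- phantom_config(volume_shape = c(32, 64, 64),
                        diameter_range_mm = c(45, 45), n_nodules = 1,
                        seed = 1)
  expect_error(generate_phantom(cfg), "could not place nodule 1")
})

test_that("configs are validated", {
  expect_error(phantom_config(volume_shape = c(8, 64, 64)), ">= 16")
  expect_error(phantom_config(diameter_range_mm = c(0, 10)), "diameter")
  expect_error(phantom_config(diameter_range_mm = c(10, 70)), "diameter")
  expect_error(phantom_config(malignant_fraction = 1.2), "malignant_fraction")
})

test_that("cohorts are reproducible with independent samples", {
  cfg <- phantom_config(volume_shape = c(32, 64, 64), n_nodules = 1,
                        diameter_range_mm = c(8, 16), seed = 1)
  co <- generate_cohort(5, cfg)
  co2 <- generate_cohort(5, cfg)
  expect_length(co, 5)
  for (i in 1:5) expect_identical(co[[i]]$ct$values, co2[[i]]$ct$values)
  # samples differ from each other
  expect_false(identical(co[[1]]$ct$values, co[[2]]$ct$values))
  # singleton equals generate_phantom at the derived seed
  one <- generate_cohort(1, cfg)
  expect_identical(one[[1]]$ct$values,
                   generate_phantom(one[[1]]$config)$ct$values)
})

test_that("malignant trait frequency matches the configured fraction", {
  cfg <- phantom_config(volume_shape = c(24, 48, 48), n_nodules = 1,
                        diameter_range_mm = c(6, 10),
                        malignant_fraction = 0.5, include_vessels = FALSE,
                        seed = 42)
  co <- generate_cohort(50, cfg)
  k <- sum(vapply(co, function(s) s$per_nodule_malignant[1], TRUE))
  lo <- qbinom(0.005, 50, 0.5)
  hi <- qbinom(0.995, 50, 0.5)
  expect_gte(k, lo)
  expect_lte(k, hi)
})
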