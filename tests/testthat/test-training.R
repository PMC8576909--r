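test_that("the active loss is a pure function of epoch and warm-start length", {
  expect_equal(active_loss(1:6, 3), c("bce", "bce", "bce", "dice", "dice", "dice"))
  expect_equal(active_loss(1, 0), "dice")
  expect_equal(active_loss(4, 4), "bce")
  expect_equal(active_loss(5, 4), "dice")
})

test_that("segmentation training tags BCE epochs then switches to Dice", {
  s <- seg_cohort_20()[[1]]
  small <- list(volume = s$volume[1:16, 1:16, 1:16],
                mask = s$mask[1:16, 1:16, 1:16])
  set.seed(1)
  m <- tiny_seg_net(1)
  cfg <- seg_train_config(epochs = 5, batch_size = 2, bce_epochs = 3,
                          lr_stages = c(1e-3, 1e-3, 1e-4), seed = 1)
  r <- train_segmentation(m, list(small, small), cfg)
  expect_equal(r$log$loss_name, c("bce", "bce", "bce", "dice", "dice"))
  expect_false(is.unsorted(rev(r$log$lr)))
  expect_error(train_segmentation(m, list(), cfg), "empty")
})

test_that("seeded training is reproducible and a zero rate freezes weights", {
  s <- seg_cohort_20()[[1]]
  small <- list(volume = s$volume[1:16, 1:16, 1:16],
                mask = s$mask[1:16, 1:16, 1:16])
  run1 <- {
    set.seed(9); m <- tiny_seg_net(9)
    train_segmentation(m, list(small),
                       seg_train_config(epochs = 2, batch_size = 1,
                                        bce_epochs = 1, seed = 9))$log
  }
  run2 <- {
    set.seed(9); m <- tiny_seg_net(9)
    train_segmentation(m, list(small),
                       seg_train_config(epochs = 2, batch_size = 1,
                                        bce_epochs = 1, seed = 9))$log
  }
  expect_identical(run1$loss[1], run2$loss[1])
  expect_identical(run1, run2)

  set.seed(10); m <- tiny_seg_net(10)
  w0 <- lapply(nn$collect_layers(m$blocks), function(l) lapply(l$pnames, get, l))
  train_segmentation(m, list(small),
                     seg_train_config(epochs = 2, batch_size = 1,
                                      bce_epochs = 1,
                                      lr_stages = c(0, 0, 0), seed = 10))
  w1 <- lapply(nn$collect_layers(m$blocks), function(l) lapply(l$pnames, get, l))
  expect_identical(w0, w1)
})

test_that("classifier training reduces the NLL on a separable ROI set", {
  rois <- roi_cohort(8, seed0 = 800)          # 16 ROIs
  set.seed(12)
  m <- build_classifier(width_mult = 1 / 16)
  cfg <- cls_train_config(epochs = 10, batch_size = 8, lr = 1e-3, seed = 12)
  r <- train_classifier(m, rois, cfg)
  expect_lt(tail(r$log$loss, 1), r$log$loss[1])
  expect_lt(mean(diff(r$log$loss) > 0), 0.5)   # mostly decreasing
  expect_equal(sum(attr(r$log, "class_balance")), 16)
  # single-class input warns but proceeds
  ben <- Filter(function(s) s$label == "benign", rois)
  set.seed(13)
  m2 <- build_classifier(width_mult = 1 / 16)
  expect_warning(train_classifier(m2, ben,
                                  cls_train_config(epochs = 1, seed = 13)),
                 "single-class")
})

test_that("segmentation evaluation stratifies per-nodule metrics by size", {
  # perfect predictor: ground truth in, ground truth out
  s <- seg_cohort_20()[[2]]
  per <- evaluate_segmentation_from_masks(
    list(list(pred = s$mask, mask = s$mask, spacing_mm = s$spacing_mm)))
  pop <- per[per$n > 0, ]
  expect_true(all(pop$dice == 1 & pop$precision == 1 & pop$recall == 1))

  empty <- evaluate_segmentation_from_masks(
    list(list(pred = s$mask * 0L, mask = s$mask, spacing_mm = s$spacing_mm)))
  expect_true(all(empty[empty$n > 0, ]$recall == 0))

  # census by size category matches the generator's diameters
  samples <- lapply(c(31, 32, 33), function(sd) {
    ph <- subvolume_phantom(sd, diameter_range = c(6, 20))
    c(seg_sample(ph), list(diameter_mm = ph$per_nodule_diameter_mm))
  })
  per3 <- evaluate_segmentation_from_masks(
    lapply(samples, function(s) list(pred = s$mask, mask = s$mask,
                                     spacing_mm = s$spacing_mm)))
  expected <- table(size_category(vapply(samples, `[[`, 0, "diameter_mm")))
  for (cat in names(expected)) {
    expect_equal(per3$n[per3$category == cat], as.integer(expected[[cat]]))
  }
})

test_that("classifier evaluation reports the confusion matrix and ROC", {
  rois <- roi_cohort(4, seed0 = 500)
  set.seed(14)
  m <- build_classifier(width_mult = 1 / 16)
  ev <- evaluate_classifier(m, rois)
  expect_s3_class(ev$confusion, "confusion_matrix")
  with(ev$confusion, expect_equal(TP + FP + TN + FN, 8))
  expect_true(ev$auc >= 0 && ev$auc <= 1)
  # metrics agree with the standalone confusion-matrix routine
  expect_identical(ev$metrics, classification_metrics(ev$confusion))
})

test_that("cohort splits are deterministic and disjoint", {
  sp <- split_cohort(20, seed = 4)
  expect_identical(sp, split_cohort(20, seed = 4))
  all_idx <- c(sp$train, sp$validation, sp$test)
  expect_equal(sort(all_idx), 1:20)
  expect_equal(length(sp$train), 14)
})
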