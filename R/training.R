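# Training loops for both networks. Segmentation uses the dynamically
# switched loss: summed BCE for the first `bce_epochs` epochs (a weight
# "warm start" that tames the early Dice gradient), soft Dice loss
# afterwards. Classification minimizes the mean NLL of the 2-way head.
# Batches are accumulated sample-by-sample (instance normalization makes
# per-sample processing equivalent to batched processing up to gradient
# averaging), and all randomness flows from the config seed.

#' Segmentation training configuration
#'
#' Defaults follow the reference schedule: 64 epochs, batch size 6, Adam
#' with learning rate 1e-2 dropped to 1e-3 and 1e-4 by thirds of the epoch
#' budget, BCE for the first 3 epochs.
#'
#' @param epochs total epochs.
#' @param batch_size samples per optimizer step.
#' @param lr_stages three non-increasing learning rates, one per third of
#'   the epoch budget.
#' @param bce_epochs number of initial epochs optimizing BCE
#'   (`bce_epochs < epochs`).
#' @param seed RNG seed for shuffling (and any init done under it).
#' @return A `seg_train_config` list.
#' @export
seg_train_config <- function(epochs = 64L, batch_size = 6L,
                             lr_stages = c(1e-2, 1e-3, 1e-4),
                             bce_epochs = 3L, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, bce_epochs < epochs,
            length(lr_stages) == 3, !is.unsorted(rev(lr_stages)))
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_stages = lr_stages, bce_epochs = as.integer(bce_epochs),
                 seed = as.integer(seed)),
            class = "seg_train_config")
}

#' Classifier training configuration
#'
#' Defaults follow the reference schedule: 52 epochs, batch size 16, Adam
#' at learning rate 1e-4.
#'
#' @param epochs total epochs.
#' @param batch_size samples per optimizer step.
#' @param lr Adam learning rate.
#' @param seed RNG seed.
#' @return A `cls_train_config` list.
#' @export
cls_train_config <- function(epochs = 52L, batch_size = 16L, lr = 1e-4,
                             seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, lr >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 seed = as.integer(seed)),
            class = "cls_train_config")
}

#' Active segmentation loss for an epoch
#'
#' Pure function of `(epoch, bce_epochs)`: `"bce"` for epochs `1..bce_epochs`,
#' `"dice"` afterwards.
#'
#' @param epoch 1-based epoch number.
#' @param bce_epochs length of the BCE warm-start phase.
#' @return `"bce"` or `"dice"`.
#' @export
active_loss <- function(epoch, bce_epochs = 3L) {
  ifelse(epoch <= bce_epochs, "bce", "dice")
}

epoch_lr <- function(epoch, epochs, lr_stages) {
  stage <- min(3L, 1L + ((epoch - 1L) * 3L) %/% epochs)
  lr_stages[stage]
}

#' Train the 3D Res U-Net
#'
#' @param model a `seg_network` (modified in place and returned).
#' @param dataset list of samples, each `list(volume =` 3D `[0,1]` array
#'   `, mask =` binary 3D array`)`.
#' @param config a [seg_train_config()].
#' @param stop_loss optional early-stopping bound: training ends once the
#'   mean Dice loss of an epoch falls to or below it (the epoch budget is a
#'   maximum; properties phrased as "within N epochs" remain valid).
#' @return list with `model` and `log` (per-epoch data.frame: epoch, loss,
#'   loss_name, lr).
#' @export
train_segmentation <- function(model, dataset, config = seg_train_config(),
                               stop_loss = NULL) {
  stopifnot(inherits(model, "seg_network"), inherits(config, "seg_train_config"))
  if (length(dataset) == 0L) stop("empty dataset")
  layers <- collect_layers(model$blocks)
  opt <- adam_optimizer(layers)
  log <- vector("list", config$epochs)
  set.seed(config$seed)
  for (epoch in seq_len(config$epochs)) {
    loss_name <- active_loss(epoch, config$bce_epochs)
    lr <- epoch_lr(epoch, config$epochs, config$lr_stages)
    ord <- sample.int(length(dataset))
    losses <- numeric(length(dataset))
    zero_grads(layers)
    in_batch <- 0L
    for (j in seq_along(ord)) {
      s <- dataset[[ord[j]]]
      sp <- dim(s$volume)
      Tm <- as.numeric(s$mask)
      out <- seg_forward(model, feat(matrix(as.numeric(s$volume), nrow = 1), sp))
      P <- as.numeric(out$x)
      if (loss_name == "bce") {
        losses[j] <- bce_loss(P, Tm)
        # exact (P - T) at the pre-sigmoid activation, mean-scaled for the
        # optimizer step
        dP <- (P - Tm) / pmax(P * (1 - P), 1e-12) / length(P)
      } else {
        losses[j] <- dice_loss(P, Tm)
        dP <- dice_loss_grad(P, Tm)
      }
      seg_backward(model, matrix(dP, nrow = 1), sp)
      in_batch <- in_batch + 1L
      if (in_batch == config$batch_size || j == length(ord)) {
        adam_step(opt, lr)
        zero_grads(layers)
        in_batch <- 0L
      }
    }
    log[[epoch]] <- data.frame(epoch = epoch, loss = mean(losses),
                               loss_name = loss_name, lr = lr)
    if (!is.null(stop_loss) && loss_name == "dice" &&
        mean(losses) <= stop_loss) break
  }
  list(model = model, log = do.call(rbind, log[!vapply(log, is.null, TRUE)]))
}

#' Train the 3D ResNet50 classifier
#'
#' @param model a `cls_network` (modified in place and returned).
#' @param dataset list of samples, each `list(roi =` 3D `[0,1]` array
#'   `, label =` `"benign"` or `"malignant"``)`.
#' @param config a [cls_train_config()].
#' @param stop_accuracy optional early-stopping bound: training ends once an
#'   epoch's running training accuracy reaches it.
#' @return list with `model` and `log` (per-epoch data.frame: epoch, loss,
#'   accuracy, plus the class balance as attributes).
#' @export
train_classifier <- function(model, dataset, config = cls_train_config(),
                             stop_accuracy = NULL) {
  stopifnot(inherits(model, "cls_network"), inherits(config, "cls_train_config"))
  if (length(dataset) == 0L) stop("empty dataset")
  cls <- vapply(dataset, function(s) match(s$label, c("benign", "malignant")), 0L)
  if (anyNA(cls)) stop("labels must be 'benign' or 'malignant'")
  if (length(unique(cls)) < 2L) {
    warning("single-class dataset; training proceeds but separability is untestable")
  }
  layers <- collect_layers(model$blocks)
  opt <- adam_optimizer(layers)
  log <- vector("list", config$epochs)
  set.seed(config$seed)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(length(dataset))
    losses <- numeric(length(ord))
    correct <- logical(length(ord))
    zero_grads(layers)
    in_batch <- 0L
    for (j in seq_along(ord)) {
      s <- dataset[[ord[j]]]
      sp <- dim(s$roi)
      logp <- cls_forward(model, feat(matrix(as.numeric(s$roi), nrow = 1), sp))
      k <- cls[ord[j]]
      losses[j] <- -logp[k]
      correct[j] <- which.max(logp) == k
      dlogp <- c(0, 0)
      dlogp[k] <- -1
      cls_backward(model, dlogp / config$batch_size)
      in_batch <- in_batch + 1L
      if (in_batch == config$batch_size || j == length(ord)) {
        adam_step(opt, config$lr)
        zero_grads(layers)
        in_batch <- 0L
      }
    }
    log[[epoch]] <- data.frame(epoch = epoch, loss = mean(losses),
                               accuracy = mean(correct))
    if (!is.null(stop_accuracy) && mean(correct) >= stop_accuracy) break
  }
  log <- do.call(rbind, log[!vapply(log, is.null, TRUE)])
  attr(log, "class_balance") <- table(factor(cls, 1:2, c("benign", "malignant")))
  list(model = model, log = log)
}

#' Evaluate segmentation per nodule, stratified by size
#'
#' Each connected component of the ground-truth mask is scored against the
#' prediction inside the component's bounding box (padded by a margin), and
#' scores are averaged within each size category.
#'
#' @param model a `seg_network`.
#' @param dataset list of samples as in [train_segmentation()]; an optional
#'   `spacing_mm` per sample (default `c(3, 1.5, 1.5)`) sets the diameter
#'   scale.
#' @param threshold binarization threshold.
#' @param margin bounding-box margin in voxels.
#' @return data.frame: category, n, dice, precision, recall.
#' @export
evaluate_segmentation <- function(model, dataset, threshold = 0.5, margin = 8L) {
  evaluate_segmentation_from_masks(lapply(dataset, function(s) {
    list(pred = unclass(predict_mask(forward_segment(model, s$volume),
                                     threshold)),
         mask = s$mask, spacing_mm = s$spacing_mm)
  }), margin = margin)
}

#' @rdname evaluate_segmentation
#' @param samples list of `list(pred =, mask =, spacing_mm =)` triples; the
#'   mask-level core behind [evaluate_segmentation()], useful for scoring
#'   precomputed predictions.
#' @export
evaluate_segmentation_from_masks <- function(samples, margin = 8L) {
  rows <- list()
  for (s in samples) {
    spac <- if (!is.null(s$spacing_mm)) s$spacing_mm else c(3, 1.5, 1.5)
    pred <- as_mask_array(s$pred)
    comp <- connected_components(s$mask)
    for (ci in seq_len(comp$n)) {
      idx <- which(comp$labels == ci, arr.ind = TRUE)
      lo <- pmax(apply(idx, 2, min) - margin, 1L)
      hi <- pmin(apply(idx, 2, max) + margin, dim(pred))
      pw <- pred[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
      tw <- (comp$labels == ci)[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] * 1L
      d <- equivalent_diameter_mm(nrow(idx), spac)
      rows[[length(rows) + 1]] <- data.frame(
        diameter_mm = d,
        category = as.character(size_category(d)),
        dice = if (sum(pw) + sum(tw) > 0) dice_coefficient(pw, tw) else NA_real_,
        precision = precision_metric(pw, tw),
        recall = recall_metric(pw, tw))
    }
  }
  per <- do.call(rbind, rows)
  cats <- c("micro", "small", "nodule", "mass")
  out <- do.call(rbind, lapply(cats, function(cat) {
    sub <- per[per$category == cat, , drop = FALSE]
    data.frame(category = cat, n = nrow(sub),
               dice = if (nrow(sub)) mean(sub$dice, na.rm = TRUE) else NA_real_,
               precision = if (nrow(sub)) mean(sub$precision, na.rm = TRUE) else NA_real_,
               recall = if (nrow(sub)) mean(sub$recall, na.rm = TRUE) else NA_real_)
  }))
  attr(out, "per_nodule") <- per
  out
}

#' Evaluate the classifier on a labeled ROI set
#'
#' @param model a `cls_network`.
#' @param dataset list of samples as in [train_classifier()].
#' @return list with `confusion` ([confusion_matrix()], positive class =
#'   malignant), `metrics` (accuracy, recall, specificity), `roc` and `auc`
#'   (from malignant-class probabilities; `NA` if only one class present).
#' @export
evaluate_classifier <- function(model, dataset) {
  truth <- vapply(dataset, function(s) s$label, "")
  p_mal <- vapply(dataset, function(s) classify_roi(model, s$roi)$p_malignant, 0)
  pred <- ifelse(p_mal >= 0.5, "malignant", "benign")
  cm <- confusion_matrix(TP = sum(pred == "malignant" & truth == "malignant"),
                         FP = sum(pred == "malignant" & truth == "benign"),
                         TN = sum(pred == "benign" & truth == "benign"),
                         FN = sum(pred == "benign" & truth == "malignant"))
  roc <- if (length(unique(truth)) == 2L) {
    roc_auc(p_mal, as.integer(truth == "malignant"))
  } else NULL
  list(confusion = cm, metrics = classification_metrics(cm),
       roc = roc$curve, auc = if (is.null(roc)) NA_real_ else roc$auc)
}

#' Deterministic train/validation/test split
#'
#' @param n number of samples.
#' @param fractions three fractions summing to 1 (train, validation, test).
#' @param seed RNG seed.
#' @return list of index vectors `train`, `validation`, `test`.
#' @export
split_cohort <- function(n, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  idx <- with_local_seed(seed, sample.int(n))
  n_tr <- round(fractions[1] * n)
  n_va <- round(fractions[2] * n)
  list(train = sort(idx[seq_len(n_tr)]),
       validation = sort(idx[n_tr + seq_len(min(n_va, n - n_tr))]),
       test = sort(idx[seq_len(n) > n_tr + n_va]))
}
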