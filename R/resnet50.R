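# Modified 3D ResNet50 classifier for 16x48x48 nodule ROIs. Changes from
# the stock 2D ResNet50: all convolutions are 3D; the stem kernel is
# reduced from 7x7x7 to 3x3x3; there is no max-pooling anywhere (the stem
# pool is dropped and all downsampling is by strided convolutions); the
# middle convolutions of the last two stages use depth-sparing 1x3x3
# kernels; stage strides (1,1,1), (1,2,2), (2,2,2), (2,2,2) keep the final
# grid at 4x6x6 for the standard ROI. Global average pooling feeds a 2-way
# head with log-probabilities.

cls_bottleneck <- function(cin, inner, cout, stride, mid_k, mid_p) {
  b <- new.env(parent = emptyenv())
  b$type <- "bottleneck"
  b$conv1 <- conv3d_layer(cin, inner, k = 1L, pad = 0L)
  b$in1 <- inorm_layer(inner); b$relu1 <- relu_layer()
  b$conv2 <- conv3d_layer(inner, inner, k = mid_k, stride = stride, pad = mid_p)
  b$in2 <- inorm_layer(inner); b$relu2 <- relu_layer()
  b$conv3 <- conv3d_layer(inner, cout, k = 1L, pad = 0L)
  b$in3 <- inorm_layer(cout)
  b$project <- !identical(stride, c(1L, 1L, 1L)) || cin != cout
  if (b$project) {
    b$convp <- conv3d_layer(cin, cout, k = 1L, stride = stride, pad = 0L)
    b$inp <- inorm_layer(cout)
  }
  b$relu_out <- relu_layer()
  b$layers <- Filter(Negate(is.null),
                     list(b$conv1, b$in1, b$relu1, b$conv2, b$in2, b$relu2,
                          b$conv3, b$in3,
                          if (b$project) b$convp, if (b$project) b$inp,
                          b$relu_out))
  b$forward <- function(f, training = TRUE) {
    m <- b$relu1$forward(b$in1$forward(b$conv1$forward(f, training), training), training)
    m <- b$relu2$forward(b$in2$forward(b$conv2$forward(m, training), training), training)
    m <- b$in3$forward(b$conv3$forward(m, training), training)
    sc <- if (b$project) {
      b$inp$forward(b$convp$forward(f, training), training)
    } else f
    b$relu_out$forward(feat(m$x + sc$x, m$sp), training)
  }
  b$backward <- function(df) {
    ds <- b$relu_out$backward(df)
    dm <- b$conv1$backward(b$in1$backward(b$relu1$backward(
      b$conv2$backward(b$in2$backward(b$relu2$backward(
        b$conv3$backward(b$in3$backward(ds))))))))
    dsc <- if (b$project) b$convp$backward(b$inp$backward(ds)) else ds
    feat(dm$x + dsc$x, dm$sp)
  }
  b
}

#' Build the modified 3D ResNet50 classifier
#'
#' Bottleneck stages with block counts (3, 4, 6, 3), no max-pooling,
#' strided-convolution downsampling, reduced stem and late-stage kernels,
#' global average pooling and a 2-way log-probability head. `width_mult`
#' scales all channel counts for desk-scale experiments (1 reproduces the
#' reference width: stem 64, stage outputs 256/512/1024/2048).
#'
#' @param width_mult channel multiplier in (0, 1].
#' @param in_channels input channels.
#' @param reduced_kernels use the 1x3x3 middle kernels in the last two
#'   stages (the reduced-kernel modification); `FALSE` keeps 3x3x3.
#' @return A `cls_network` object.
#' @export
build_classifier <- function(width_mult = 1, in_channels = 1,
                             reduced_kernels = TRUE) {
  w <- function(n) max(1L, as.integer(round(n * width_mult)))
  stem_ch <- w(64)
  stem <- conv3d_layer(in_channels, stem_ch, k = 3L, stride = 1L, pad = 1L)
  stem_in <- inorm_layer(stem_ch); stem_relu <- relu_layer()
  block_counts <- c(3L, 4L, 6L, 3L)
  strides <- list(c(1L, 1L, 1L), c(1L, 2L, 2L), c(2L, 2L, 2L), c(2L, 2L, 2L))
  stages <- vector("list", 4)
  cin <- stem_ch
  for (s in 1:4) {
    inner <- w(64 * 2^(s - 1))
    cout <- inner * 4L
    late <- reduced_kernels && s >= 3
    mid_k <- if (late) c(1L, 3L, 3L) else c(3L, 3L, 3L)
    mid_p <- if (late) c(0L, 1L, 1L) else c(1L, 1L, 1L)
    blocks <- vector("list", block_counts[s])
    for (j in seq_len(block_counts[s])) {
      st <- if (j == 1L) strides[[s]] else c(1L, 1L, 1L)
      blocks[[j]] <- cls_bottleneck(cin, inner, cout, st, mid_k, mid_p)
      cin <- cout
    }
    stages[[s]] <- blocks
  }
  head_W <- xavier_mat(2, cin, cin, 2)
  fc <- new.env(parent = emptyenv())
  fc$type <- "fc"
  fc$W <- head_W; fc$b <- numeric(2)
  fc$gW <- head_W * 0; fc$gb <- numeric(2)
  fc$pnames <- c("W", "b")
  blocks_all <- c(list(stem, stem_in, stem_relu), unlist(stages), list(fc))
  structure(list(width_mult = width_mult, in_channels = in_channels,
                 reduced_kernels = reduced_kernels,
                 block_counts = block_counts,
                 stem = stem, stem_in = stem_in, stem_relu = stem_relu,
                 stages = stages, fc = fc, feat_ch = cin,
                 blocks = blocks_all),
            class = "cls_network")
}

cls_forward <- function(model, f, training = TRUE) {
  stride_prod <- c(4L, 8L, 8L)
  if (any(f$sp < stride_prod)) {
    stop(sprintf("input %s smaller than the total stride product (4, 8, 8); provide at least a 4x8x8 volume",
                 paste(f$sp, collapse = "x")))
  }
  f <- model$stem_relu$forward(model$stem_in$forward(
    model$stem$forward(f, training), training), training)
  for (s in 1:4) for (b in model$stages[[s]]) f <- b$forward(f, training)
  gap <- rowMeans(f$x)
  z <- drop(model$fc$W %*% gap + model$fc$b)
  lse <- max(z) + log(sum(exp(z - max(z))))
  logp <- z - lse
  if (training) {
    model$fc$gap <- gap
    model$fc$n_vox <- ncol(f$x)
    model$fc$feat_sp <- f$sp
    model$fc$logp <- logp
  }
  logp
}

# dlogp: gradient w.r.t. the log-probabilities
cls_backward <- function(model, dlogp) {
  fc <- model$fc
  dz <- dlogp - exp(fc$logp) * sum(dlogp)
  fc$gW <- fc$gW + outer(dz, fc$gap)
  fc$gb <- fc$gb + dz
  dgap <- drop(crossprod(fc$W, dz))
  df <- feat(matrix(dgap / fc$n_vox, length(dgap), fc$n_vox), fc$feat_sp)
  for (s in 4:1) for (j in rev(seq_along(model$stages[[s]]))) {
    df <- model$stages[[s]][[j]]$backward(df)
  }
  model$stem$backward(model$stem_in$backward(model$stem_relu$backward(df)))
}

#' Classify a nodule ROI as benign or malignant
#'
#' @param model a `cls_network`.
#' @param roi 3D array, normally 16 x 48 x 48, windowed to `[0, 1]`.
#' @return list with `p_benign`, `p_malignant`, `label` (ties resolve to
#'   malignant, the conservative call).
#' @export
classify_roi <- function(model, roi) {
  stopifnot(inherits(model, "cls_network"))
  sp <- dim(roi)
  if (is.null(sp) || length(sp) != 3L) stop("roi must be a 3D array")
  logp <- cls_forward(model, feat(matrix(as.numeric(roi), nrow = 1), sp),
                      training = FALSE)
  p <- exp(logp)
  p <- p / sum(p)
  label <- if (p[2] >= p[1]) "malignant" else "benign"
  list(p_benign = p[1], p_malignant = p[2], label = label)
}

#' Count max-pooling layers in a model
#'
#' The modified classifier must contain none (the final global average pool
#' is not a layer object); the segmentation encoder has four.
#'
#' @param model a network object.
#' @return integer count.
#' @export
n_maxpool_layers <- function(model) {
  sum(vapply(collect_layers(model$blocks),
             function(l) identical(l$type, "maxpool"), FALSE))
}
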