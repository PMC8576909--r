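# 3D Res U-Net: four down-sampling modules (residual unit + 2x2x2 max
# pool), a bottleneck residual unit, four up-sampling modules (2x2x2
# transposed conv + IN + ReLU, skip concatenation, residual unit halving the
# channels) and a 1x1x1 sigmoid output head.

#' Build the 3D Res U-Net segmentation network
#'
#' The default channel ladder (8, 16, 32, 64) with bottleneck 128 is the
#' reference architecture; scaled-down variants shrink the ladder but keep
#' the topology. Weights are Xavier-initialized from the current RNG state
#' (seed with [set.seed()] for reproducibility).
#'
#' @param channels encoder channel ladder (4 stages).
#' @param bottleneck bottleneck channels.
#' @param in_channels input channels (1 for windowed CT).
#' @return A `seg_network` object.
#' @export
build_segmentation_network <- function(channels = c(8, 16, 32, 64),
                                       bottleneck = 128, in_channels = 1) {
  stopifnot(length(channels) == 4, all(channels >= 1))
  enc <- vector("list", 4)
  pool <- vector("list", 4)
  cin <- in_channels
  for (i in 1:4) {
    enc[[i]] <- res_unit(cin, channels[i])
    pool[[i]] <- maxpool_layer()
    cin <- channels[i]
  }
  bott <- res_unit(channels[4], bottleneck)
  up <- vector("list", 4)
  upin <- vector("list", 4)
  uprelu <- vector("list", 4)
  dec <- vector("list", 4)
  prev <- bottleneck
  for (i in 1:4) {
    skip_ch <- channels[5 - i]
    up[[i]] <- tconv3d_layer(prev, skip_ch)
    upin[[i]] <- inorm_layer(skip_ch)
    uprelu[[i]] <- relu_layer()
    dec[[i]] <- res_unit(2 * skip_ch, skip_ch)
    prev <- skip_ch
  }
  outconv <- conv3d_layer(channels[1], 1, k = 1L, pad = 0L)
  # bias the head toward background (sigmoid(-4) ~ 0.018): nodules occupy a
  # tiny voxel fraction, and starting from an almost-empty prediction removes
  # the unstable early-Dice plateau instead of relying on the BCE warm start
  # to suppress the background
  outconv$b[] <- -4
  outsig <- sigmoid_layer()
  blocks <- c(enc, pool, list(bott), up, upin, uprelu, dec,
              list(outconv, outsig))
  structure(list(channels = channels, bottleneck = bottleneck,
                 in_channels = in_channels,
                 enc = enc, pool = pool, bott = bott, up = up, upin = upin,
                 uprelu = uprelu, dec = dec, outconv = outconv,
                 outsig = outsig, blocks = blocks),
            class = "seg_network")
}

check_seg_input <- function(model, sp) {
  if (any(sp %% 16L != 0L)) {
    need <- (16L - sp %% 16L) %% 16L
    stop(sprintf(paste0("input shape %s not divisible by 2^4; pad by ",
                        "(%d, %d, %d) voxels"),
                 paste(sp, collapse = "x"), need[1], need[2], need[3]))
  }
}

# Full forward pass; returns the sigmoid output feature and (training mode)
# keeps every cache needed for seg_backward.
seg_forward <- function(model, f, training = TRUE) {
  check_seg_input(model, f$sp)
  skips <- vector("list", 4)
  for (i in 1:4) {
    f <- model$enc[[i]]$forward(f, training)
    skips[[i]] <- f
    f <- model$pool[[i]]$forward(f, training)
  }
  f <- model$bott$forward(f, training)
  for (i in 1:4) {
    f <- model$uprelu[[i]]$forward(
      model$upin[[i]]$forward(model$up[[i]]$forward(f, training), training),
      training)
    sk <- skips[[5 - i]]
    f <- feat(rbind(sk$x, f$x), f$sp)
    f <- model$dec[[i]]$forward(f, training)
  }
  model$outsig$forward(model$outconv$forward(f, training), training)
}

seg_backward <- function(model, dprob, sp) {
  df <- model$outconv$backward(model$outsig$backward(feat(dprob, sp)))
  dskips <- vector("list", 4)
  for (i in 4:1) {
    df <- model$dec[[i]]$backward(df)
    skip_ch <- model$channels[5 - i]
    dskips[[5 - i]] <- feat(df$x[seq_len(skip_ch), , drop = FALSE], df$sp)
    dup <- feat(df$x[skip_ch + seq_len(skip_ch), , drop = FALSE], df$sp)
    df <- model$up[[i]]$backward(model$upin[[i]]$backward(
      model$uprelu[[i]]$backward(dup)))
  }
  df <- model$bott$backward(df)
  for (i in 4:1) {
    df <- model$pool[[i]]$backward(df)
    df <- feat(df$x + dskips[[i]]$x, df$sp)
    df <- model$enc[[i]]$backward(df)
  }
  df
}

#' Segment a volume with a 3D Res U-Net
#'
#' @param model a `seg_network`.
#' @param volume 3D array in `[0, 1]` (lung-window grayscale) whose shape is
#'   divisible by 16 along every axis.
#' @return 3D probability array of the same shape, values in (0, 1).
#' @export
forward_segment <- function(model, volume) {
  stopifnot(inherits(model, "seg_network"))
  sp <- dim(volume)
  if (is.null(sp) || length(sp) != 3L) stop("volume must be a 3D array")
  out <- seg_forward(model, feat(matrix(as.numeric(volume), nrow = 1), sp),
                     training = FALSE)
  array(out$x, dim = sp)
}

#' Binarize a probability volume
#'
#' Voxels with probability greater than or equal to the threshold (ties
#' included) become foreground.
#'
#' @param prob 3D array in `[0, 1]`.
#' @param threshold scalar in `[0, 1]`.
#' @return [binary_mask()].
#' @export
predict_mask <- function(prob, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  binary_mask(prob >= threshold)
}

#' Stage-by-stage shape table of a segmentation network
#'
#' Symbolic shape pass over the architecture: one row per named stage
#' (Input, Encoder0-3, Bottle, Decoder0-3, OutputConv) with output channels
#' and spatial size, suitable for exact comparison against the reference
#' architecture table.
#'
#' @param model a `seg_network`.
#' @param input_shape spatial triple divisible by 16.
#' @return data.frame with columns stage, channels, axial, coronal,
#'   sagittal.
#' @export
shape_table <- function(model, input_shape = c(48, 192, 192)) {
  stopifnot(inherits(model, "seg_network"))
  sp <- as.integer(input_shape)
  check_seg_input(model, sp)
  rows <- list(list("Input", model$in_channels, sp))
  for (i in 1:4) {
    rows[[length(rows) + 1]] <- list(sprintf("Encoder%d", i - 1),
                                     model$channels[i], sp %/% 2L^i)
  }
  rows[[length(rows) + 1]] <- list("Bottle", model$bottleneck, sp %/% 16L)
  for (i in 1:4) {
    rows[[length(rows) + 1]] <- list(sprintf("Decoder%d", i - 1),
                                     model$channels[5 - i], sp %/% 2L^(4 - i))
  }
  rows[[length(rows) + 1]] <- list("OutputConv", 1L, sp)
  data.frame(stage = vapply(rows, `[[`, "", 1),
             channels = vapply(rows, function(r) as.integer(r[[2]]), 0L),
             axial = vapply(rows, function(r) as.integer(r[[3]][1]), 0L),
             coronal = vapply(rows, function(r) as.integer(r[[3]][2]), 0L),
             sagittal = vapply(rows, function(r) as.integer(r[[3]][3]), 0L))
}
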