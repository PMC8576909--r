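# Every layer's backward pass is validated against central finite
# differences on tiny tensors (the independent differentiation oracle).

check_layer_grads <- function(layer, cin, sp, tol = 1e-7) {
  x <- matrix(rnorm(cin * prod(sp)), cin)
  y <- layer$forward(nn$feat(x, sp))
  wt <- matrix(rnorm(length(y$x)), nrow(y$x))   # random linear functional
  nn$zero_grads(list(layer))
  dx <- layer$backward(nn$feat(wt, y$sp))
  fx <- function(v) sum(layer$forward(nn$feat(matrix(v, cin), sp),
                                      training = FALSE)$x * wt)
  expect_lt(max(abs(dx$x - matrix(num_grad(fx, as.numeric(x)), cin))), tol)
  for (p in layer$pnames) {
    p0 <- get(p, layer)
    fp <- function(v) {
      assign(p, if (is.matrix(p0)) matrix(v, nrow(p0)) else v, layer)
      out <- sum(layer$forward(nn$feat(x, sp), training = FALSE)$x * wt)
      assign(p, p0, layer)
      out
    }
    expect_lt(max(abs(get(paste0("g", p), layer) - num_grad(fp, as.numeric(p0)))),
              tol)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("convolution layers backpropagate exactly", {
  set.seed(42)
  check_layer_grads(nn$conv3d_layer(2, 3, k = 3, pad = 1), 2, c(4, 4, 4))
  check_layer_grads(nn$conv3d_layer(3, 2, k = 1, pad = 0), 3, c(3, 4, 5))
  check_layer_grads(nn$conv3d_layer(2, 2, k = 3, stride = 2, pad = 1),
                    2, c(6, 6, 6))
  check_layer_grads(nn$conv3d_layer(2, 2, k = c(1, 3, 3), pad = c(0, 1, 1)),
                    2, c(3, 6, 6))
  check_layer_grads(nn$tconv3d_layer(3, 2), 3, c(2, 3, 2))
})

test_that("normalization, activation and pooling layers backpropagate exactly", {
  set.seed(43)
  l <- nn$inorm_layer(2)
  l$gamma <- runif(2, 0.5, 1.5); l$beta <- rnorm(2)
  check_layer_grads(l, 2, c(3, 3, 3))
  check_layer_grads(nn$relu_layer(), 2, c(3, 3, 3))
  check_layer_grads(nn$sigmoid_layer(), 2, c(3, 3, 3))
  check_layer_grads(nn$maxpool_layer(), 2, c(4, 4, 4))
})

test_that("the assembled networks backpropagate to their inputs exactly", {
  set.seed(44)
  m <- tiny_seg_net(44)
  sp <- c(16, 16, 16)
  xv <- array(runif(prod(sp)), sp)
  Tm <- array(0, sp); Tm[6:10, 6:10, 6:10] <- 1
  layers <- nn$collect_layers(m$blocks)
  nn$zero_grads(layers)
  out <- nn$seg_forward(m, nn$feat(matrix(as.numeric(xv), 1), sp))
  dP <- nn$dice_loss_grad(as.numeric(out$x), as.numeric(Tm))
  din <- nn$seg_backward(m, matrix(dP, 1), sp)
  for (idx in c(1, 500, 2048, 4000)) {
    f <- function(v) {
      xx <- xv; xx[idx] <- v
      o <- nn$seg_forward(m, nn$feat(matrix(as.numeric(xx), 1), sp),
                          training = FALSE)
      dice_loss(as.numeric(o$x), as.numeric(Tm))
    }
    ng <- (f(xv[idx] + 1e-5) - f(xv[idx] - 1e-5)) / 2e-5
    expect_lt(abs(ng - din$x[idx]), 1e-6)
  }

  set.seed(45)
  cm <- build_classifier(width_mult = 1 / 16)
  roi <- array(runif(8 * 16 * 16), c(8, 16, 16))
  nn$zero_grads(nn$collect_layers(cm$blocks))
  nn$cls_forward(cm, nn$feat(matrix(as.numeric(roi), 1), c(8, 16, 16)))
  din <- nn$cls_backward(cm, c(-1, 0))
  for (idx in c(1, 100, 1000)) {
    f <- function(v) {
      rr <- roi; rr[idx] <- v
      -nn$cls_forward(cm, nn$feat(matrix(as.numeric(rr), 1), c(8, 16, 16)),
                      training = FALSE)[1]
    }
    ng <- (f(roi[idx] + 1e-7) - f(roi[idx] - 1e-7)) / 2e-7
    expect_lt(abs(ng - din$x[idx]) / max(abs(ng), 1e-4), 1e-3)
  }
})

test_that("inference is deterministic and Adam at zero rate is a no-op", {
  set.seed(46)
  m <- tiny_seg_net(46)
  x <- array(runif(16^3), c(16, 16, 16))
  expect_identical(forward_segment(m, x), forward_segment(m, x))

  layers <- nn$collect_layers(m$blocks)
  opt <- nn$adam_optimizer(layers)
  w_before <- lapply(layers, function(l) lapply(l$pnames, get, l))
  out <- nn$seg_forward(m, nn$feat(matrix(as.numeric(x), 1), dim(x)))
  nn$seg_backward(m, matrix(rnorm(length(out$x)), 1), dim(x))
  nn$adam_step(opt, 0)
  w_after <- lapply(layers, function(l) lapply(l$pnames, get, l))
  expect_identical(w_before, w_after)
})
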