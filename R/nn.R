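# A compact 3D conv-net engine. Feature maps travel as C x N matrices
# (channels in rows, voxels in columns, column-major voxel order d + D*(h +
# H*w)) together with their spatial dims. Convolutions are im2col + GEMM;
# every layer implements an explicit backward pass and gradient buffers, and
# Adam updates parameters in place. Layers are environments, so models are
# mutable objects trained in place.

feat <- function(x, sp) list(x = x, sp = as.integer(sp))

conv_out_sp <- function(sp, k, s, p) (sp + 2L * p - k) %/% s + 1L

xavier_mat <- function(nrow, ncol, fan_in, fan_out) {
  a <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nrow * ncol, -a, a), nrow, ncol)
}

#' @noRd
conv3d_layer <- function(cin, cout, k = 3L, stride = 1L, pad = 1L) {
  e <- new.env(parent = emptyenv())
  e$type <- "conv3d"
  e$k <- rep(as.integer(k), length.out = 3)
  e$s <- rep(as.integer(stride), length.out = 3)
  e$p <- rep(as.integer(pad), length.out = 3)
  e$cin <- cin; e$cout <- cout
  K <- cin * prod(e$k)
  e$W <- xavier_mat(cout, K, K, cout * prod(e$k))
  e$b <- numeric(cout)
  e$gW <- e$W * 0; e$gb <- e$b * 0
  e$pnames <- c("W", "b")
  pointwise <- all(e$k == 1L) && all(e$s == 1L)
  # direct convolution beats im2col + BLAS for small channel products;
  # above ~32x32 channels the GEMM path wins (measured crossover)
  direct <- !pointwise && all(e$s == 1L) && cin * cout < 1024
  if (direct) {
    # index permutation turning W into the flipped/transposed kernel used
    # by the backward-data pass (a stride-1 convolution of dy)
    K3 <- prod(e$k)
    off <- as.matrix(expand.grid(kd = 0:(e$k[1] - 1), kh = 0:(e$k[2] - 1),
                                 kw = 0:(e$k[3] - 1)))
    offr <- (e$k[1] - 1 - off[, 1]) + e$k[1] * ((e$k[2] - 1 - off[, 2]) +
              e$k[2] * (e$k[3] - 1 - off[, 3]))
    idx <- integer(cin * cout * K3)
    for (o in seq_len(K3)) for (co in seq_len(cout)) for (ci in seq_len(cin)) {
      fl <- (ci - 1) + cin * ((co - 1) + cout * offr[o])
      idx[fl + 1L] <- (co - 1) + cout * ((ci - 1) + cin * (o - 1)) + 1L
    }
    e$flip_idx <- idx
    e$pflip <- e$k - 1L - e$p
  }
  e$forward <- function(f, training = TRUE) {
    if (pointwise) {
      y <- e$W %*% f$x + e$b
      if (training) { e$xin <- f$x; e$in_sp <- f$sp }
      return(feat(y, f$sp))
    }
    if (direct) {
      y <- conv3s1_fwd(f$x, f$sp, e$W, e$cout, e$k, e$p) + e$b
      if (training) { e$xin <- f$x; e$in_sp <- f$sp }
      return(feat(y, conv_out_sp(f$sp, e$k, e$s, e$p)))
    }
    cols <- im2col3(f$x, f$sp, e$k, e$s, e$p)
    y <- e$W %*% cols + e$b
    if (training) { e$cols <- cols; e$in_sp <- f$sp }
    feat(y, conv_out_sp(f$sp, e$k, e$s, e$p))
  }
  e$backward <- function(df) {
    e$gb <- e$gb + .rowSums(df$x, e$cout, ncol(df$x))
    if (pointwise) {
      e$gW <- e$gW + tcrossprod(df$x, e$xin)
      dx <- crossprod(e$W, df$x)
      e$xin <- NULL
      return(feat(dx, e$in_sp))
    }
    if (direct) {
      e$gW <- e$gW + conv3s1_dw(e$xin, e$in_sp, df$x, e$k, e$p)
      Wf <- matrix(e$W[e$flip_idx], e$cin, e$cout * prod(e$k))
      dx <- conv3s1_fwd(df$x, df$sp, Wf, e$cin, e$k, e$pflip)
      e$xin <- NULL
      return(feat(dx, e$in_sp))
    }
    e$gW <- e$gW + tcrossprod(df$x, e$cols)
    dx <- col2im3(crossprod(e$W, df$x), e$cin, e$in_sp, e$k, e$s, e$p)
    e$cols <- NULL
    feat(dx, e$in_sp)
  }
  e
}

#' @noRd
tconv3d_layer <- function(cin, cout, k = 2L, stride = 2L) {
  e <- new.env(parent = emptyenv())
  e$type <- "tconv3d"
  e$k <- rep(as.integer(k), length.out = 3)
  e$s <- rep(as.integer(stride), length.out = 3)
  e$cin <- cin; e$cout <- cout
  K <- cout * prod(e$k)
  e$W <- xavier_mat(K, cin, cin * prod(e$k), cout * prod(e$k))
  e$b <- numeric(cout)
  e$gW <- e$W * 0; e$gb <- e$b * 0
  e$pnames <- c("W", "b")
  e$forward <- function(f, training = TRUE) {
    big_sp <- f$sp * e$s
    y <- col2im3(e$W %*% f$x, e$cout, big_sp, e$k, e$s, c(0L, 0L, 0L)) + e$b
    if (training) { e$xin <- f$x; e$in_sp <- f$sp }
    feat(y, big_sp)
  }
  e$backward <- function(df) {
    dZ <- im2col3(df$x, df$sp, e$k, e$s, c(0L, 0L, 0L))
    e$gW <- e$gW + tcrossprod(dZ, e$xin)
    e$gb <- e$gb + .rowSums(df$x, e$cout, ncol(df$x))
    dx <- crossprod(e$W, dZ)
    e$xin <- NULL
    feat(dx, e$in_sp)
  }
  e
}

#' @noRd
inorm_layer <- function(C, eps = 1e-5) {
  e <- new.env(parent = emptyenv())
  e$type <- "inorm"
  e$gamma <- rep(1, C); e$beta <- numeric(C)
  e$ggamma <- numeric(C); e$gbeta <- numeric(C)
  e$pnames <- c("gamma", "beta")
  e$forward <- function(f, training = TRUE) {
    r <- inorm_fwd(f$x, e$gamma, e$beta, eps, training)
    if (training) { e$xhat <- r$xhat; e$inv <- r$inv }
    feat(r$y, f$sp)
  }
  e$backward <- function(df) {
    r <- inorm_bwd(df$x, e$xhat, e$inv, e$gamma)
    e$ggamma <- e$ggamma + r$dgamma
    e$gbeta <- e$gbeta + r$dbeta
    e$xhat <- NULL; e$inv <- NULL
    feat(r$dx, df$sp)
  }
  e
}

#' @noRd
relu_layer <- function() {
  e <- new.env(parent = emptyenv())
  e$type <- "relu"
  e$pnames <- character(0)
  e$forward <- function(f, training = TRUE) {
    y <- f$x * (f$x > 0)
    if (training) e$mask <- f$x > 0
    feat(y, f$sp)
  }
  e$backward <- function(df) {
    dx <- df$x * e$mask
    e$mask <- NULL
    feat(dx, df$sp)
  }
  e
}

#' @noRd
sigmoid_layer <- function() {
  e <- new.env(parent = emptyenv())
  e$type <- "sigmoid"
  e$pnames <- character(0)
  e$forward <- function(f, training = TRUE) {
    y <- 1 / (1 + exp(-f$x))
    if (training) e$y <- y
    feat(y, f$sp)
  }
  e$backward <- function(df) {
    dx <- df$x * e$y * (1 - e$y)
    e$y <- NULL
    feat(dx, df$sp)
  }
  e
}

#' @noRd
maxpool_layer <- function() {
  e <- new.env(parent = emptyenv())
  e$type <- "maxpool"
  e$pnames <- character(0)
  e$forward <- function(f, training = TRUE) {
    r <- maxpool3_fwd(f$x, f$sp)
    if (training) { e$idx <- r$idx; e$n_in <- ncol(f$x) }
    feat(r$y, f$sp %/% 2L)
  }
  e$backward <- function(df) {
    dx <- maxpool3_bwd(df$x, e$idx, e$n_in)
    sp <- df$sp * 2L
    e$idx <- NULL
    feat(dx, sp)
  }
  e
}

# Residual unit: main path Conv3(k3,p1)->IN->ReLU->Conv3(k3,p1)->IN;
# identity path Conv1(k1,p0)->IN->ReLU (present in every unit); elementwise
# sum then ReLU. Spatial shape is preserved.
#' @noRd
res_unit <- function(cin, cout) {
  u <- new.env(parent = emptyenv())
  u$type <- "res_unit"
  u$conv_id <- conv3d_layer(cin, cout, k = 1L, pad = 0L)
  u$in_id <- inorm_layer(cout)
  u$relu_id <- relu_layer()
  u$conv1 <- conv3d_layer(cin, cout, k = 3L, pad = 1L)
  u$in1 <- inorm_layer(cout)
  u$relu1 <- relu_layer()
  u$conv2 <- conv3d_layer(cout, cout, k = 3L, pad = 1L)
  u$in2 <- inorm_layer(cout)
  u$relu_out <- relu_layer()
  u$layers <- list(u$conv_id, u$in_id, u$relu_id, u$conv1, u$in1, u$relu1,
                   u$conv2, u$in2, u$relu_out)
  u$forward <- function(f, training = TRUE) {
    idp <- u$relu_id$forward(u$in_id$forward(u$conv_id$forward(f, training),
                                             training), training)
    m <- u$relu1$forward(u$in1$forward(u$conv1$forward(f, training),
                                       training), training)
    m <- u$in2$forward(u$conv2$forward(m, training), training)
    u$relu_out$forward(feat(m$x + idp$x, m$sp), training)
  }
  u$backward <- function(df) {
    ds <- u$relu_out$backward(df)
    dmain <- u$conv1$backward(u$in1$backward(u$relu1$backward(
      u$conv2$backward(u$in2$backward(ds)))))
    did <- u$conv_id$backward(u$in_id$backward(u$relu_id$backward(ds)))
    feat(dmain$x + did$x, dmain$sp)
  }
  u
}

collect_layers <- function(x) {
  if (is.environment(x) && !is.null(x$layers)) {
    unlist(lapply(x$layers, collect_layers), use.names = FALSE)
  } else if (is.environment(x)) {
    list(x)
  } else if (is.list(x)) {
    unlist(lapply(x, collect_layers), use.names = FALSE)
  } else {
    list()
  }
}

zero_grads <- function(layers) {
  for (l in layers) for (p in l$pnames) assign(paste0("g", p), get(p, l) * 0, l)
  invisible(NULL)
}

#' Number of trainable parameters of a model
#' @param model a segmentation or classification network.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(collect_layers(model$blocks),
             function(l) sum(vapply(l$pnames, function(p) length(get(p, l)), 0)),
             0))
}

# Adam -------------------------------------------------------------------

#' @noRd
adam_optimizer <- function(layers, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$layers <- layers
  opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  for (l in layers) for (p in l$pnames) {
    assign(paste0("m_", p), get(p, l) * 0, l)
    assign(paste0("v_", p), get(p, l) * 0, l)
  }
  opt
}

#' @noRd
adam_step <- function(opt, lr) {
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$beta1^opt$t
  c2 <- 1 - opt$beta2^opt$t
  for (l in opt$layers) for (p in l$pnames) {
    g <- get(paste0("g", p), l)
    m <- opt$beta1 * get(paste0("m_", p), l) + (1 - opt$beta1) * g
    v <- opt$beta2 * get(paste0("v_", p), l) + (1 - opt$beta2) * g * g
    assign(paste0("m_", p), m, l)
    assign(paste0("v_", p), v, l)
    assign(p, get(p, l) - lr * (m / c1) / (sqrt(v / c2) + opt$eps), l)
  }
  invisible(NULL)
}
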