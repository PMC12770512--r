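# Minimal dense/convolutional network engine used by the hybrid classifier.
#
# Layers are environments holding parameters, gradients and Adam state;
# nn_forward()/nn_backward() implement manual reverse-mode differentiation.
# Batches are arrays of dim (N, H, W, C); matrix(x, ncol = C) flattens the
# (N, H, W) dims column-major, which every channel-wise op relies on.

new_layer <- function(.kind, ...) {
  e <- new.env(parent = emptyenv())
  e$kind <- .kind
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e$params <- character(0)
  e$opt <- list()
  class(e) <- c(paste0("nn_", .kind), "nn_layer")
  e
}

he_init <- function(fan_in, n) rnorm(n, sd = sqrt(2 / fan_in))

# ---- conv2d ------------------------------------------------------------

nn_conv2d <- function(in_c, out_c, k = 3L, stride = 1L, bias = TRUE) {
  l <- new_layer("conv2d", in_c = as.integer(in_c), out_c = as.integer(out_c),
                 k = as.integer(k), stride = as.integer(stride),
                 use_bias = bias)
  l$W <- matrix(he_init(k * k * in_c, k * k * in_c * out_c), ncol = out_c)
  l$b <- numeric(out_c)
  l$params <- if (bias) c("W", "b") else "W"
  l$geom <- list()
  l
}

conv_geometry <- function(l, n, h, w) {
  key <- paste(n, h, w, sep = "x")
  g <- l$geom[[key]]
  if (!is.null(g)) return(g)
  k <- l$k; s <- l$stride
  oh <- as.integer(ceiling(h / s)); ow <- as.integer(ceiling(w / s))
  pad_h <- max((oh - 1L) * s + k - h, 0L)
  pad_w <- max((ow - 1L) * s + k - w, 0L)
  pt <- pad_h %/% 2L; pl <- pad_w %/% 2L
  hp <- h + pad_h; wp <- w + pad_w

  # rows: n fastest, then output row, then output col;
  # cols: kernel row, kernel col, channel
  or_ <- rep(seq_len(oh), times = ow)
  oc_ <- rep(seq_len(ow), each = oh)
  base_r <- (or_ - 1L) * s          # 0-based row of kernel origin in padded img
  base_c <- (oc_ - 1L) * s
  kr <- rep(seq_len(k), times = k)
  kc <- rep(seq_len(k), each = k)
  # per-channel offset added later; positions for channel 1, sample 1
  pos0 <- matrix(0L, oh * ow, k * k)
  for (j in seq_len(k * k)) {
    pos0[, j] <- (base_r + kr[j] - 1L) + hp * (base_c + kc[j] - 1L)
  }
  # expand over channels
  ch_off <- (seq_len(l$in_c) - 1L) * hp * wp
  pos <- matrix(0L, oh * ow, k * k * l$in_c)
  for (ch in seq_len(l$in_c)) {
    pos[, (ch - 1L) * k * k + seq_len(k * k)] <- pos0 + ch_off[ch]
  }
  # expand over batch: linear index = n + N * pos (pos 0-based over H*W*C grid)
  nv <- rep(seq_len(n), times = oh * ow)
  idx_cols <- lapply(seq_len(ncol(pos)), function(j) {
    nv + n * rep(pos[, j], each = n)
  })
  g <- list(oh = oh, ow = ow, hp = hp, wp = wp, pt = pt, pl = pl,
            idx_cols = idx_cols,
            idx_vec = unlist(idx_cols, use.names = FALSE))
  l$geom[[key]] <- g
  g
}

fwd_conv2d <- function(l, x, training = FALSE) {
  d <- dim(x)
  n <- d[1]; h <- d[2]; w <- d[3]
  if (l$k == 1L && l$stride == 1L) {
    # 1x1 stride-1 convolution is a pure channel mixing: no gather needed
    xcol <- x
    dim(xcol) <- c(n * h * w, l$in_c)
    out <- xcol %*% l$W
    if (l$use_bias) out <- out + rep(l$b, each = nrow(out))
    l$cache <- list(xcol = xcol, n = n, h = h, w = w, g = NULL)
    dim(out) <- c(n, h, w, l$out_c)
    return(out)
  }
  g <- conv_geometry(l, n, h, w)
  p <- array(0, c(n, g$hp, g$wp, l$in_c))
  p[, g$pt + seq_len(h), g$pl + seq_len(w), ] <- x
  xcol <- p[g$idx_vec]
  dim(xcol) <- c(n * g$oh * g$ow, length(g$idx_cols))
  out <- xcol %*% l$W
  if (l$use_bias) out <- out + rep(l$b, each = nrow(out))
  l$cache <- list(xcol = xcol, n = n, h = h, w = w, g = g)
  dim(out) <- c(n, g$oh, g$ow, l$out_c)
  out
}

bwd_conv2d <- function(l, dy) {
  cc <- l$cache
  dmat <- dy
  dim(dmat) <- c(length(dy) %/% l$out_c, l$out_c)
  l$gW <- crossprod(cc$xcol, dmat)
  if (l$use_bias) l$gb <- colSums(dmat)
  dxcol <- tcrossprod(dmat, l$W)
  if (is.null(cc$g)) {
    dim(dxcol) <- c(cc$n, cc$h, cc$w, l$in_c)
    return(dxcol)
  }
  g <- cc$g
  dp <- numeric(cc$n * g$hp * g$wp * l$in_c)
  for (j in seq_along(g$idx_cols)) {
    ii <- g$idx_cols[[j]]
    dp[ii] <- dp[ii] + dxcol[, j]
  }
  dim(dp) <- c(cc$n, g$hp, g$wp, l$in_c)
  dp[, g$pt + seq_len(cc$h), g$pl + seq_len(cc$w), , drop = FALSE]
}

# ---- batch norm --------------------------------------------------------

nn_batchnorm <- function(channels, momentum = 0.9, eps = 1e-5) {
  l <- new_layer("batchnorm", channels = as.integer(channels),
                 momentum = momentum, eps = eps)
  l$gamma <- rep(1, channels)
  l$beta <- rep(0, channels)
  l$run_mean <- rep(0, channels)
  l$run_var <- rep(1, channels)
  l$params <- c("gamma", "beta")
  l
}

fwd_batchnorm <- function(l, x, training = FALSE) {
  d <- dim(x)
  m <- matrix(x, ncol = l$channels)
  if (training) {
    mu <- colMeans(m)
    v <- colMeans(m^2) - mu^2
    l$run_mean <- l$momentum * l$run_mean + (1 - l$momentum) * mu
    l$run_var <- l$momentum * l$run_var + (1 - l$momentum) * v
  } else {
    mu <- l$run_mean
    v <- l$run_var
  }
  ivar <- 1 / sqrt(v + l$eps)
  xhat <- sweep(sweep(m, 2, mu, "-"), 2, ivar, "*")
  out <- sweep(sweep(xhat, 2, l$gamma, "*"), 2, l$beta, "+")
  l$cache <- list(xhat = xhat, ivar = ivar, d = d, training = training)
  array(out, d)
}

bwd_batchnorm <- function(l, dy) {
  cc <- l$cache
  dm <- matrix(dy, ncol = l$channels)
  l$ggamma <- colSums(dm * cc$xhat)
  l$gbeta <- colSums(dm)
  dxhat <- sweep(dm, 2, l$gamma, "*")
  if (cc$training) {
    m <- nrow(dm)
    t1 <- sweep(dxhat, 2, colSums(dxhat) / m, "-")
    t2 <- sweep(cc$xhat, 2, colSums(dxhat * cc$xhat) / m, "*")
    dx <- sweep(t1 - t2, 2, cc$ivar, "*")
  } else {
    dx <- sweep(dxhat, 2, cc$ivar, "*")
  }
  array(dx, cc$d)
}

# ---- activations / dropout --------------------------------------------

nn_relu <- function() new_layer("relu")

fwd_relu <- function(l, x, training = FALSE) {
  l$cache <- x > 0
  x * l$cache
}

bwd_relu <- function(l, dy) dy * l$cache

nn_dropout <- function(rate) new_layer("dropout", rate = rate)

fwd_dropout <- function(l, x, training = FALSE) {
  if (!training || l$rate <= 0) {
    l$cache <- NULL
    return(x)
  }
  keep <- array(runif(length(x)) >= l$rate, dim(x) %||% length(x))
  l$cache <- keep / (1 - l$rate)
  x * l$cache
}

bwd_dropout <- function(l, dy) {
  if (is.null(l$cache)) dy else dy * l$cache
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- pooling / resampling ---------------------------------------------

nn_maxpool2 <- function() new_layer("maxpool2")

fwd_maxpool2 <- function(l, x, training = FALSE) {
  d <- dim(x)
  if (d[2] %% 2L != 0L || d[3] %% 2L != 0L) {
    abort_config("maxpool requires even spatial dims")
  }
  ro <- seq(1L, d[2], 2L); re <- seq(2L, d[2], 2L)
  co <- seq(1L, d[3], 2L); ce <- seq(2L, d[3], 2L)
  a <- x[, ro, co, , drop = FALSE]
  b <- x[, re, co, , drop = FALSE]
  cc <- x[, ro, ce, , drop = FALSE]
  e <- x[, re, ce, , drop = FALSE]
  out <- pmax(a, b, cc, e)
  ma <- a == out
  mb <- (b == out) & !ma
  mc <- (cc == out) & !(ma | mb)
  me <- !(ma | mb | mc)
  l$cache <- list(d = d, ma = ma, mb = mb, mc = mc, me = me)
  out
}

bwd_maxpool2 <- function(l, dy) {
  cc <- l$cache
  d <- cc$d
  dx <- array(0, d)
  ro <- seq(1L, d[2], 2L); re <- seq(2L, d[2], 2L)
  co <- seq(1L, d[3], 2L); ce <- seq(2L, d[3], 2L)
  dx[, ro, co, ] <- dy * cc$ma
  dx[, re, co, ] <- dy * cc$mb
  dx[, ro, ce, ] <- dy * cc$mc
  dx[, re, ce, ] <- dy * cc$me
  dx
}

nn_upsample2 <- function() new_layer("upsample2")

fwd_upsample2 <- function(l, x, training = FALSE) {
  d <- dim(x)
  l$cache <- d
  x[, rep(seq_len(d[2]), each = 2), rep(seq_len(d[3]), each = 2), , drop = FALSE]
}

bwd_upsample2 <- function(l, dy) {
  d <- l$cache
  ro <- seq(1L, 2L * d[2], 2L); re <- seq(2L, 2L * d[2], 2L)
  co <- seq(1L, 2L * d[3], 2L); ce <- seq(2L, 2L * d[3], 2L)
  dy[, ro, co, , drop = FALSE] + dy[, re, co, , drop = FALSE] +
    dy[, ro, ce, , drop = FALSE] + dy[, re, ce, , drop = FALSE]
}

nn_gap <- function() new_layer("gap")

fwd_gap <- function(l, x, training = FALSE) {
  d <- dim(x)
  l$cache <- d
  dim(x) <- c(d[1], d[2] * d[3], d[4])
  out <- matrix(0, d[1], d[4])
  for (ch in seq_len(d[4])) out[, ch] <- rowMeans(x[, , ch, drop = FALSE])
  out
}

bwd_gap <- function(l, dy) {
  d <- l$cache
  hw <- d[2] * d[3]
  dx <- array(0, c(d[1], hw, d[4]))
  for (ch in seq_len(d[4])) {
    dx[, , ch] <- matrix(dy[, ch] / hw, d[1], hw)
  }
  array(dx, d)
}

# ---- dense -------------------------------------------------------------

nn_dense <- function(in_dim, out_dim, l2 = 0) {
  l <- new_layer("dense", in_dim = as.integer(in_dim),
                 out_dim = as.integer(out_dim), l2 = l2)
  l$W <- matrix(he_init(in_dim, in_dim * out_dim), ncol = out_dim)
  l$b <- numeric(out_dim)
  l$params <- c("W", "b")
  l
}

fwd_dense <- function(l, x, training = FALSE) {
  l$cache <- x
  sweep(x %*% l$W, 2, l$b, "+")
}

bwd_dense <- function(l, dy) {
  l$gW <- crossprod(l$cache, dy) + 2 * l$l2 * l$W
  l$gb <- colSums(dy)
  tcrossprod(dy, l$W)
}

# ---- generic dispatch --------------------------------------------------

nn_forward <- function(l, x, training = FALSE) {
  switch(l$kind,
         conv2d = fwd_conv2d(l, x, training),
         batchnorm = fwd_batchnorm(l, x, training),
         relu = fwd_relu(l, x, training),
         dropout = fwd_dropout(l, x, training),
         maxpool2 = fwd_maxpool2(l, x, training),
         upsample2 = fwd_upsample2(l, x, training),
         gap = fwd_gap(l, x, training),
         dense = fwd_dense(l, x, training),
         seq = fwd_seq(l, x, training),
         residual_block = fwd_residual_block(l, x, training),
         attn_gate = fwd_attn_gate(l, x, training),
         abort_config(sprintf("unknown layer kind '%s'", l$kind)))
}

nn_backward <- function(l, dy) {
  switch(l$kind,
         conv2d = bwd_conv2d(l, dy),
         batchnorm = bwd_batchnorm(l, dy),
         relu = bwd_relu(l, dy),
         dropout = bwd_dropout(l, dy),
         maxpool2 = bwd_maxpool2(l, dy),
         upsample2 = bwd_upsample2(l, dy),
         gap = bwd_gap(l, dy),
         dense = bwd_dense(l, dy),
         seq = bwd_seq(l, dy),
         residual_block = bwd_residual_block(l, dy),
         attn_gate = bwd_attn_gate(l, dy),
         abort_config(sprintf("unknown layer kind '%s'", l$kind)))
}

# sequential container
nn_seq <- function(layers) new_layer("seq", layers = layers)

fwd_seq <- function(l, x, training = FALSE) {
  for (sub in l$layers) x <- nn_forward(sub, x, training)
  x
}

bwd_seq <- function(l, dy) {
  for (sub in rev(l$layers)) dy <- nn_backward(sub, dy)
  dy
}

# collect every parameter-bearing layer, recursing through containers
nn_collect <- function(l) {
  out <- list()
  if (l$kind %in% c("seq")) {
    for (sub in l$layers) out <- c(out, nn_collect(sub))
  } else if (l$kind == "residual_block") {
    for (nm in c("conv1", "bn1", "conv2", "bn2", "conv3", "bn3",
                 "proj_conv", "proj_bn")) {
      if (!is.null(l[[nm]])) out <- c(out, nn_collect(l[[nm]]))
    }
  } else if (l$kind == "attn_gate") {
    out <- c(out, nn_collect(l$theta), nn_collect(l$phi), nn_collect(l$psi))
  } else if (length(l$params) > 0L) {
    out <- c(out, list(l))
  }
  out
}

# ---- residual bottleneck block ----------------------------------------

#' Bottleneck residual block
#'
#' `1x1 reduce -> 3x3 (stride) -> 1x1 expand`, each followed by batch
#' normalisation, ReLU after the first two; the block input (identity, or a
#' strided 1x1 projection when shape changes) is added before the final
#' ReLU.
#'
#' @param in_c,mid_c,out_c Channel widths.
#' @param stride Spatial stride of the 3x3 convolution.
#' @return A residual-block layer object usable with the internal network
#'   engine.
#' @export
residual_block <- function(in_c, mid_c, out_c, stride = 1L) {
  l <- new_layer("residual_block", stride = as.integer(stride))
  l$conv1 <- nn_conv2d(in_c, mid_c, 1L, 1L)
  l$bn1 <- nn_batchnorm(mid_c)
  l$conv2 <- nn_conv2d(mid_c, mid_c, 3L, stride)
  l$bn2 <- nn_batchnorm(mid_c)
  l$conv3 <- nn_conv2d(mid_c, out_c, 1L, 1L)
  l$bn3 <- nn_batchnorm(out_c)
  if (in_c != out_c || stride != 1L) {
    l$proj_conv <- nn_conv2d(in_c, out_c, 1L, stride)
    l$proj_bn <- nn_batchnorm(out_c)
  } else {
    l$proj_conv <- NULL
    l$proj_bn <- NULL
  }
  l$relu1 <- nn_relu(); l$relu2 <- nn_relu(); l$relu_out <- nn_relu()
  l
}

fwd_residual_block <- function(l, x, training = FALSE) {
  y <- nn_forward(l$relu1, nn_forward(l$bn1, nn_forward(l$conv1, x, training), training), training)
  y <- nn_forward(l$relu2, nn_forward(l$bn2, nn_forward(l$conv2, y, training), training), training)
  y <- nn_forward(l$bn3, nn_forward(l$conv3, y, training), training)
  s <- if (is.null(l$proj_conv)) x else {
    nn_forward(l$proj_bn, nn_forward(l$proj_conv, x, training), training)
  }
  nn_forward(l$relu_out, y + s, training)
}

bwd_residual_block <- function(l, dy) {
  dsum <- nn_backward(l$relu_out, dy)
  dmain <- nn_backward(l$conv1,
    nn_backward(l$bn1,
      nn_backward(l$relu1,
        nn_backward(l$conv2,
          nn_backward(l$bn2,
            nn_backward(l$relu2,
              nn_backward(l$conv3, nn_backward(l$bn3, dsum))))))))
  dshort <- if (is.null(l$proj_conv)) dsum else {
    nn_backward(l$proj_conv, nn_backward(l$proj_bn, dsum))
  }
  dmain + dshort
}

# ---- additive attention gate ------------------------------------------

# x: skip features (N,H,W,Cx); g: gating features at the same spatial size
# (N,H,W,Cg). alpha = sigmoid(psi(relu(theta(x) + phi(g)))), out = x * alpha.
nn_attn_gate <- function(cx, cg, ci) {
  l <- new_layer("attn_gate", cx = cx, cg = cg, ci = ci)
  l$theta <- nn_conv2d(cx, ci, 1L, 1L, bias = FALSE)
  l$phi <- nn_conv2d(cg, ci, 1L, 1L, bias = TRUE)
  l$psi <- nn_conv2d(ci, 1L, 1L, 1L, bias = TRUE)
  l
}

fwd_attn_gate <- function(l, xg, training = FALSE) {
  x <- xg$x; g <- xg$g
  q <- nn_forward(l$theta, x, training) + nn_forward(l$phi, g, training)
  qr <- q * (q > 0)
  z <- nn_forward(l$psi, qr, training)
  alpha <- 1 / (1 + exp(-z))
  d <- dim(x)
  alpha_b <- array(alpha[, , , rep(1L, d[4])], d)
  l$cache <- list(x = x, q_mask = q > 0, alpha = alpha, d = d)
  list(out = x * alpha_b, alpha = alpha)
}

bwd_attn_gate <- function(l, dy) {
  cc <- l$cache
  d <- cc$d
  alpha_b <- array(cc$alpha[, , , rep(1L, d[4])], d)
  dx_direct <- dy * alpha_b
  # d(alpha): sum over channels of dy * x
  prod_ <- dy * cc$x
  dalpha <- array(rowSums(matrix(prod_, ncol = d[4])), c(d[1], d[2], d[3], 1L))
  dz <- dalpha * cc$alpha * (1 - cc$alpha)
  dqr <- nn_backward(l$psi, dz)
  dq <- dqr * cc$q_mask
  dx_theta <- nn_backward(l$theta, dq)
  dg <- nn_backward(l$phi, dq)
  list(dx = dx_direct + dx_theta, dg = dg)
}

# ---- loss & optimiser --------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# returns list(loss, probs, dlogits); y is an integer class index vector
softmax_ce <- function(logits, y) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  eps <- 1e-12
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y)], eps)))
  onehot <- matrix(0, n, ncol(logits))
  onehot[cbind(seq_len(n), y)] <- 1
  list(loss = loss, probs = p, dlogits = (p - onehot) / n)
}

adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in layers) {
    for (nm in l$params) {
      g <- l[[paste0("g", nm)]]
      if (is.null(g)) next
      st <- l$opt[[nm]]
      if (is.null(st)) st <- list(m = g * 0, v = g * 0)
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      l$opt[[nm]] <- st
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      l[[nm]] <- l[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(NULL)
}

# snapshot / restore all trainable parameters and BN running stats
nn_state_get <- function(layers) {
  lapply(layers, function(l) {
    st <- lapply(l$params, function(nm) l[[nm]])
    names(st) <- l$params
    if (l$kind == "batchnorm") {
      st$run_mean <- l$run_mean
      st$run_var <- l$run_var
    }
    st
  })
}

nn_state_set <- function(layers, state) {
  for (i in seq_along(layers)) {
    for (nm in names(state[[i]])) layers[[i]][[nm]] <- state[[i]][[nm]]
  }
  invisible(NULL)
}

l2_penalty <- function(layers) {
  s <- 0
  for (l in layers) {
    if (l$kind == "dense" && l$l2 > 0) s <- s + l$l2 * sum(l$W^2)
  }
  s
}
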