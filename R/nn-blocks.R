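# Composite network blocks. Every block implements four methods:
#   gm_forward / gm_backward  - numeric execution with cached activations
#   gm_count(m, fused)        - learnable scalar count; fused = deploy-time
#                               batch-norm folding (conv keeps a bias)
#   gm_profile(m, shape)      - shape inference + FLOPs at batch 1, counted
#                               as 2 x multiply-accumulates over conv layers
#                               (pointwise/pool/activation layers are free)

gm_count <- function(m, fused = FALSE) UseMethod("gm_count")
gm_profile <- function(m, shape) UseMethod("gm_profile")

gm_count.default <- function(m, fused = FALSE) {
  own <- sum(vapply(m$param_names, function(p) length(m[[p]]), numeric(1)))
  own + sum(vapply(m$children, gm_count, numeric(1), fused = fused))
}

gm_profile.default <- function(m, shape) list(shape = shape, flops = 0)

conv_flops <- function(Ho, Wo, cout, cin_per_group, k) {
  2 * Ho * Wo * cout * cin_per_group * k * k
}

## ---- Conv unit: conv (+/- depthwise) + BN + activation --------------------

nn_conv_unit <- function(cin, cout, k, stride = 1L, act = "silu",
                         depthwise = FALSE) {
  if (depthwise) {
    stopifnot(cin == cout)
    conv <- nn_dwconv2d(cin, k, stride)
  } else {
    conv <- nn_conv2d(cin, cout, k, stride)
  }
  new_module("conv_unit",
    cin = as.integer(cin), cout = as.integer(cout), k = as.integer(k),
    stride = as.integer(stride), depthwise = depthwise,
    children = list(conv = conv, bn = nn_batchnorm(cout), act = nn_act(act)))
}

gm_forward.gm_conv_unit <- function(m, x, training = FALSE) {
  y <- gm_forward(m$children$conv, x, training)
  y <- gm_forward(m$children$bn, y, training)
  gm_forward(m$children$act, y, training)
}

gm_backward.gm_conv_unit <- function(m, dy) {
  dy <- gm_backward(m$children$act, dy)
  dy <- gm_backward(m$children$bn, dy)
  gm_backward(m$children$conv, dy)
}

gm_count.gm_conv_unit <- function(m, fused = FALSE) {
  wlen <- length(m$children$conv$w)
  if (fused) wlen + m$cout else wlen + 2L * m$cout
}

gm_profile.gm_conv_unit <- function(m, shape) {
  Ho <- conv_out_size(shape[1L], m$k, m$stride, (m$k - 1L) %/% 2L)
  Wo <- conv_out_size(shape[2L], m$k, m$stride, (m$k - 1L) %/% 2L)
  cin_g <- if (m$depthwise) 1L else m$cin
  list(shape = c(Ho, Wo, m$cout),
       flops = conv_flops(Ho, Wo, m$cout, cin_g, m$k))
}

## ---- plain conv with bias (prediction layers) ------------------------------

gm_count.gm_conv2d <- function(m, fused = FALSE) {
  length(m$w) + length(m$b %||% numeric(0))
}

gm_profile.gm_conv2d <- function(m, shape) {
  Ho <- conv_out_size(shape[1L], m$k, m$stride, m$pad)
  Wo <- conv_out_size(shape[2L], m$k, m$stride, m$pad)
  list(shape = c(Ho, Wo, m$cout),
       flops = conv_flops(Ho, Wo, m$cout, m$cin, m$k))
}

## ---- GhostConv -------------------------------------------------------------
# Primary dense k x k convolution produces cout/2 channels; the remaining
# half are cheap depthwise d x d transforms of the primary output (BN, no
# activation), concatenated channel-wise. Ratio s = 2 throughout the network.

nn_ghost_conv <- function(cin, cout, k = 3L, stride = 1L, d = 5L) {
  stopifnot(cout %% 2L == 0L)
  ch <- cout %/% 2L
  new_module("ghost_conv",
    cin = as.integer(cin), cout = as.integer(cout), half = as.integer(ch),
    children = list(
      primary = nn_conv_unit(cin, ch, k, stride, act = "silu"),
      cheap_dw = nn_dwconv2d(ch, d),
      cheap_bn = nn_batchnorm(ch)))
}

gm_forward.gm_ghost_conv <- function(m, x, training = FALSE) {
  y1 <- gm_forward(m$children$primary, x, training)
  y2 <- gm_forward(m$children$cheap_bn,
                   gm_forward(m$children$cheap_dw, y1, training), training)
  map_concat(list(y1, y2))
}

gm_backward.gm_ghost_conv <- function(m, dy) {
  parts <- map_concat_split(dy, c(m$half, m$half))
  d1 <- gm_backward(m$children$cheap_dw,
                    gm_backward(m$children$cheap_bn, parts[[2L]]))
  gm_backward(m$children$primary, parts[[1L]] + d1)
}

gm_count.gm_ghost_conv <- function(m, fused = FALSE) {
  cheap <- length(m$children$cheap_dw$w) +
    (if (fused) m$half else 2L * m$half)
  gm_count(m$children$primary, fused) + cheap
}

gm_profile.gm_ghost_conv <- function(m, shape) {
  p <- gm_profile(m$children$primary, shape)
  dk <- m$children$cheap_dw$k
  cheap <- conv_flops(p$shape[1L], p$shape[2L], m$half, 1L, dk)
  list(shape = c(p$shape[1L], p$shape[2L], m$cout), flops = p$flops + cheap)
}

## ---- channel concat / split helpers ----------------------------------------

map_concat <- function(xs) {
  xs <- lapply(xs, as_map)
  d0 <- dim(xs[[1L]])
  ctot <- sum(vapply(xs, function(x) dim(x)[3L], integer(1)))
  y <- array(0, c(d0[1L], d0[2L], ctot, d0[4L]))
  at <- 0L
  for (x in xs) {
    cc <- dim(x)[3L]
    y[, , at + seq_len(cc), ] <- x
    at <- at + cc
  }
  y
}

map_concat_split <- function(dy, sizes) {
  out <- vector("list", length(sizes))
  at <- 0L
  for (i in seq_along(sizes)) {
    out[[i]] <- dy[, , at + seq_len(sizes[i]), , drop = FALSE]
    at <- at + sizes[i]
  }
  out
}

## ---- Bottleneck (optionally carrying an MLCA gate) -------------------------

nn_bottleneck <- function(c, shortcut = TRUE, mlca = FALSE, mlca_grid = 5L) {
  ch <- list(
    cv1 = nn_conv_unit(c, c, 3L),
    cv2 = nn_conv_unit(c, c, 3L))
  if (mlca) ch$att <- nn_mlca(c, grid = mlca_grid)
  new_module("bottleneck", c = as.integer(c), shortcut = shortcut,
             has_mlca = mlca, children = ch)
}

gm_forward.gm_bottleneck <- function(m, x, training = FALSE) {
  y <- gm_forward(m$children$cv2,
                  gm_forward(m$children$cv1, x, training), training)
  if (m$has_mlca) y <- gm_forward(m$children$att, y, training)
  if (m$shortcut) x + y else y
}

gm_backward.gm_bottleneck <- function(m, dy) {
  d <- dy
  if (m$has_mlca) d <- gm_backward(m$children$att, d)
  d <- gm_backward(m$children$cv1, gm_backward(m$children$cv2, d))
  if (m$shortcut) dy + d else d
}

gm_profile.gm_bottleneck <- function(m, shape) {
  p1 <- gm_profile(m$children$cv1, shape)
  p2 <- gm_profile(m$children$cv2, p1$shape)
  fl <- p1$flops + p2$flops
  if (m$has_mlca) fl <- fl + gm_profile(m$children$att, p2$shape)$flops
  list(shape = shape, flops = fl)
}

## ---- C2f / CM block ---------------------------------------------------------
# cv1 projects to 2c hidden channels, the second half runs through n
# bottlenecks whose outputs are all concatenated with both halves before the
# cv2 projection. With mlca = TRUE each bottleneck carries an MLCA gate (the
# "CM" variant used in the neck of the attention model).

nn_c2f <- function(cin, cout, n = 1L, shortcut = FALSE, mlca = FALSE) {
  c <- cout %/% 2L
  blocks <- lapply(seq_len(n), function(i) nn_bottleneck(c, shortcut, mlca))
  names(blocks) <- paste0("b", seq_len(n))
  ch <- c(list(cv1 = nn_conv_unit(cin, 2L * c, 1L),
               cv2 = nn_conv_unit((2L + n) * c, cout, 1L)), blocks)
  new_module("c2f", cin = as.integer(cin), cout = as.integer(cout),
             c = as.integer(c), n = as.integer(n), children = ch)
}

gm_forward.gm_c2f <- function(m, x, training = FALSE) {
  y <- gm_forward(m$children$cv1, x, training)
  parts <- map_concat_split(y, c(m$c, m$c))
  keep <- parts
  cur <- parts[[2L]]
  for (i in seq_len(m$n)) {
    cur <- gm_forward(m$children[[paste0("b", i)]], cur, training)
    keep <- c(keep, list(cur))
  }
  gm_forward(m$children$cv2, map_concat(keep), training)
}

gm_backward.gm_c2f <- function(m, dy) {
  d <- gm_backward(m$children$cv2, dy)
  sizes <- rep(m$c, 2L + m$n)
  dparts <- map_concat_split(d, sizes)
  dcur <- dparts[[2L + m$n]]
  for (i in rev(seq_len(m$n))) {
    dcur <- gm_backward(m$children[[paste0("b", i)]], dcur)
    if (i > 1L) dcur <- dcur + dparts[[1L + i]]
  }
  dsplit <- list(dparts[[1L]], dparts[[2L]] + dcur)
  gm_backward(m$children$cv1, map_concat(dsplit))
}

gm_profile.gm_c2f <- function(m, shape) {
  p1 <- gm_profile(m$children$cv1, shape)
  fl <- p1$flops
  bshape <- c(p1$shape[1L], p1$shape[2L], m$c)
  for (i in seq_len(m$n))
    fl <- fl + gm_profile(m$children[[paste0("b", i)]], bshape)$flops
  p2 <- gm_profile(m$children$cv2,
                   c(shape[1L], shape[2L], (2L + m$n) * m$c))
  list(shape = p2$shape, flops = fl + p2$flops)
}

## ---- SPPF -------------------------------------------------------------------

nn_sppf <- function(cin, cout, k = 5L) {
  ch <- cin %/% 2L
  new_module("sppf", cin = as.integer(cin), cout = as.integer(cout),
    c = as.integer(ch), k = as.integer(k),
    children = list(cv1 = nn_conv_unit(cin, ch, 1L),
                    cv2 = nn_conv_unit(4L * ch, cout, 1L)))
}

gm_forward.gm_sppf <- function(m, x, training = FALSE) {
  y <- gm_forward(m$children$cv1, x, training)
  d <- map_dims(y)
  pad <- (m$k - 1L) %/% 2L
  p1 <- cpp_maxpool_fwd(y, d$H, d$W, d$C, d$N, m$k, pad)
  p2 <- cpp_maxpool_fwd(p1$y, d$H, d$W, d$C, d$N, m$k, pad)
  p3 <- cpp_maxpool_fwd(p2$y, d$H, d$W, d$C, d$N, m$k, pad)
  if (training) m$cache <- list(d = d, i1 = p1$idx, i2 = p2$idx, i3 = p3$idx,
                                Ho = p1$Ho, Wo = p1$Wo)
  gm_forward(m$children$cv2, map_concat(list(y, p1$y, p2$y, p3$y)), training)
}

gm_backward.gm_sppf <- function(m, dy) {
  cc <- m$cache
  d <- gm_backward(m$children$cv2, dy)
  parts <- map_concat_split(d, rep(m$c, 4L))
  g3 <- cpp_maxpool_bwd(parts[[4L]], cc$i3, cc$d$H, cc$d$W, cc$d$C, cc$d$N,
                        cc$Ho, cc$Wo)
  g2 <- cpp_maxpool_bwd(parts[[3L]] + g3, cc$i2, cc$d$H, cc$d$W, cc$d$C,
                        cc$d$N, cc$Ho, cc$Wo)
  g1 <- cpp_maxpool_bwd(parts[[2L]] + g2, cc$i1, cc$d$H, cc$d$W, cc$d$C,
                        cc$d$N, cc$Ho, cc$Wo)
  m$cache <- NULL
  gm_backward(m$children$cv1, parts[[1L]] + g1)
}

gm_profile.gm_sppf <- function(m, shape) {
  p1 <- gm_profile(m$children$cv1, shape)
  p2 <- gm_profile(m$children$cv2,
                   c(shape[1L], shape[2L], 4L * m$c))
  list(shape = p2$shape, flops = p1$flops + p2$flops)
}

## ---- Ghost HGBlock ----------------------------------------------------------
# n successive GhostConvs; the input and every intermediate output are
# concatenated, squeezed by a 1x1 conv to cout/2 and excited back to cout.
# Residual connection when the channel count is preserved.

nn_hgblock <- function(cin, cm, cout, n = 3L, k = 3L) {
  convs <- list()
  prev <- cin
  for (i in seq_len(n)) {
    convs[[paste0("g", i)]] <- nn_ghost_conv(prev, cm, k)
    prev <- cm
  }
  ch <- c(convs, list(
    sc = nn_conv_unit(cin + n * cm, cout %/% 2L, 1L),
    ec = nn_conv_unit(cout %/% 2L, cout, 1L)))
  new_module("hgblock", cin = as.integer(cin), cm = as.integer(cm),
             cout = as.integer(cout), n = as.integer(n),
             shortcut = cin == cout, children = ch)
}

gm_forward.gm_hgblock <- function(m, x, training = FALSE) {
  x <- as_map(x)
  keep <- list(x)
  cur <- x
  for (i in seq_len(m$n)) {
    cur <- gm_forward(m$children[[paste0("g", i)]], cur, training)
    keep <- c(keep, list(cur))
  }
  y <- gm_forward(m$children$sc, map_concat(keep), training)
  y <- gm_forward(m$children$ec, y, training)
  if (m$shortcut) x + y else y
}

gm_backward.gm_hgblock <- function(m, dy) {
  d <- gm_backward(m$children$sc, gm_backward(m$children$ec, dy))
  sizes <- c(m$cin, rep(m$cm, m$n))
  dparts <- map_concat_split(d, sizes)
  dcur <- dparts[[1L + m$n]]
  for (i in rev(seq_len(m$n))) {
    dcur <- gm_backward(m$children[[paste0("g", i)]], dcur)
    if (i > 1L) dcur <- dcur + dparts[[i]]
  }
  dx <- dparts[[1L]] + dcur
  if (m$shortcut) dx + dy else dx
}

gm_profile.gm_hgblock <- function(m, shape) {
  fl <- 0
  cur <- shape
  for (i in seq_len(m$n)) {
    p <- gm_profile(m$children[[paste0("g", i)]], cur)
    fl <- fl + p$flops
    cur <- p$shape
  }
  psc <- gm_profile(m$children$sc,
                    c(shape[1L], shape[2L], m$cin + m$n * m$cm))
  pec <- gm_profile(m$children$ec, psc$shape)
  list(shape = pec$shape, flops = fl + psc$flops + pec$flops)
}

## ---- depthwise downsample ----------------------------------------------------

nn_dwdown <- function(c) nn_conv_unit(c, c, 3L, stride = 2L, act = "none",
                                      depthwise = TRUE)

## ---- SimAM (parameter-free) --------------------------------------------------
# Exact per-neuron energy with leave-one-out channel statistics; the gate is
# treated as constant in the backward pass (stop-gradient on the attention
# map), so the operator contributes zero learnable parameters and a cheap
# gradient path.

nn_simam <- function(lambda = 1e-4) new_module("simam", lambda = lambda)

gm_forward.gm_simam <- function(m, x, training = FALSE) {
  x <- as_map(x)
  w <- simam_weights(x, m$lambda)
  if (training) m$cache <- w
  w * x
}

gm_backward.gm_simam <- function(m, dy) {
  w <- m$cache
  m$cache <- NULL
  w * dy
}

## ---- MLCA ---------------------------------------------------------------------
# Local branch: adaptive average pooling to a g x g grid followed by a 1-D
# convolution across channels at every grid cell. Global branch: global
# average pooling followed by its own 1-D channel convolution. The two
# branches are averaged, squashed by a sigmoid and resampled back to the
# input resolution as a multiplicative gate.

eca_kernel_size <- function(c, gamma = 2, b = 1) {
  t <- as.integer(abs((log2(c) + b) / gamma))
  if (t %% 2L == 1L) t else t + 1L
}

nn_mlca <- function(c, grid = 5L, k = eca_kernel_size(c)) {
  new_module("mlca", c = as.integer(c), grid = as.integer(grid),
    k = as.integer(k),
    w_local = stats::rnorm(k, sd = 0.1),
    w_global = stats::rnorm(k, sd = 0.1),
    param_names = c("w_local", "w_global"))
}

# 1-D convolution across the channel axis of a (h, w, C, N) array,
# zero-padded, single input/output channel, kernel length k (odd).
conv1d_channels <- function(x, w) {
  k <- length(w)
  half <- (k - 1L) %/% 2L
  d <- dim(x)
  C <- d[3L]
  y <- array(0, d)
  for (j in seq_len(k)) {
    off <- j - 1L - half
    src <- seq_len(C) + off
    ok <- src >= 1L & src <= C
    y[, , ok, ] <- y[, , ok, , drop = FALSE] +
      w[j] * x[, , src[ok], , drop = FALSE]
  }
  y
}

conv1d_channels_bwd <- function(x, w, dy) {
  k <- length(w)
  half <- (k - 1L) %/% 2L
  d <- dim(x)
  C <- d[3L]
  dx <- array(0, d)
  dw <- numeric(k)
  for (j in seq_len(k)) {
    off <- j - 1L - half
    src <- seq_len(C) + off
    ok <- src >= 1L & src <= C
    dw[j] <- sum(dy[, , ok, , drop = FALSE] * x[, , src[ok], , drop = FALSE])
    dx[, , src[ok], ] <- dx[, , src[ok], , drop = FALSE] +
      w[j] * dy[, , ok, , drop = FALSE]
  }
  list(dx = dx, dw = dw)
}

gm_forward.gm_mlca <- function(m, x, training = FALSE) {
  x <- as_map(x)
  d <- map_dims(x)
  # clamp the local grid to the map size (deep scales of small inputs)
  g <- min(m$grid, d$H, d$W)
  lap <- cpp_avgpool_adapt_fwd(x, d$H, d$W, d$C, d$N, g, g)
  gap <- cpp_avgpool_adapt_fwd(x, d$H, d$W, d$C, d$N, 1L, 1L)
  yl <- conv1d_channels(lap, m$w_local)
  yg <- conv1d_channels(gap, m$w_global)
  fused <- 0.5 * (yl + cpp_upsample_nearest_fwd(yg, 1L, 1L, d$C, d$N, g, g))
  gate_small <- sigmoid_(fused)
  gate <- cpp_upsample_nearest_fwd(gate_small, g, g, d$C, d$N, d$H, d$W)
  if (training) m$cache <- list(x = x, d = d, g = g, lap = lap, gap = gap,
                                gate_small = gate_small, gate = gate)
  gate * x
}

gm_backward.gm_mlca <- function(m, dy) {
  cc <- m$cache
  d <- cc$d
  g <- cc$g
  dx <- cc$gate * dy
  # gate path
  dgate <- dy * cc$x
  dgs <- cpp_upsample_nearest_bwd(dgate, g, g, d$C, d$N, d$H, d$W)
  dfused <- dgs * cc$gate_small * (1 - cc$gate_small)
  dyl <- 0.5 * dfused
  dyg <- 0.5 * cpp_upsample_nearest_bwd(dfused, 1L, 1L, d$C, d$N, g, g)
  bl <- conv1d_channels_bwd(cc$lap, m$w_local, dyl)
  bg <- conv1d_channels_bwd(cc$gap, m$w_global, dyg)
  m$g_w_local <- m$g_w_local + bl$dw
  m$g_w_global <- m$g_w_global + bg$dw
  dx <- dx + cpp_avgpool_adapt_bwd(bl$dx, d$H, d$W, d$C, d$N, g, g)
  dx <- dx + cpp_avgpool_adapt_bwd(bg$dx, d$H, d$W, d$C, d$N, 1L, 1L)
  m$cache <- NULL
  dx
}

gm_profile.gm_mlca <- function(m, shape) {
  C <- shape[3L]
  list(shape = shape,
       flops = 2 * m$k * C * (m$grid^2 + 1))
}

## ---- graph-level primitives ----------------------------------------------------

nn_upsample2x <- function() new_module("upsample2x")

gm_forward.gm_upsample2x <- function(m, x, training = FALSE) {
  x <- as_map(x)
  d <- map_dims(x)
  if (training) m$cache <- d
  cpp_upsample_nearest_fwd(x, d$H, d$W, d$C, d$N, 2L * d$H, 2L * d$W)
}

gm_backward.gm_upsample2x <- function(m, dy) {
  d <- m$cache
  m$cache <- NULL
  cpp_upsample_nearest_bwd(dy, d$H, d$W, d$C, d$N, 2L * d$H, 2L * d$W)
}

gm_profile.gm_upsample2x <- function(m, shape) {
  list(shape = c(2L * shape[1L], 2L * shape[2L], shape[3L]), flops = 0)
}

nn_concat <- function() new_module("concat")

gm_forward.gm_concat <- function(m, x, training = FALSE) {
  # x is a list of maps
  if (training) m$cache <- vapply(x, function(v) dim(as_map(v))[3L], integer(1))
  map_concat(x)
}

gm_backward.gm_concat <- function(m, dy) {
  sizes <- m$cache
  m$cache <- NULL
  map_concat_split(dy, sizes)
}

gm_profile.gm_concat <- function(m, shape) {
  # shape is a list of shapes here
  cs <- sum(vapply(shape, function(s) s[3L], numeric(1)))
  list(shape = c(shape[[1L]][1L], shape[[1L]][2L], cs), flops = 0)
}

## ---- Detect head -----------------------------------------------------------------
# Anchor-free decoupled head over three scales. Per scale the box branch
# predicts 4 * reg_max distribution logits and the class branch nc logits;
# outputs are concatenated per scale. The distribution-expectation decode
# is done by the loss, not the head.

nn_detect <- function(nc, ch, reg_max = 16L, input_ref = 640L) {
  nc <- as.integer(nc)
  c2 <- max(16L, ch[1L] %/% 4L, 4L * reg_max)
  c3 <- max(ch[1L], min(nc, 100L))
  strides <- c(8L, 16L, 32L)
  box <- list(); cls <- list()
  for (i in seq_along(ch)) {
    box[[paste0("b", i, "_1")]] <- nn_conv_unit(ch[i], c2, 3L)
    box[[paste0("b", i, "_2")]] <- nn_conv_unit(c2, c2, 3L)
    bf <- nn_conv2d(c2, 4L * reg_max, 1L, bias = TRUE)
    bf$b[] <- 1
    box[[paste0("b", i, "_3")]] <- bf
    cls[[paste0("c", i, "_1")]] <- nn_conv_unit(ch[i], c3, 3L)
    cls[[paste0("c", i, "_2")]] <- nn_conv_unit(c3, c3, 3L)
    cf <- nn_conv2d(c3, nc, 1L, bias = TRUE)
    cf$b[] <- log(5 / nc / (input_ref / strides[i])^2)
    cls[[paste0("c", i, "_3")]] <- cf
  }
  new_module("detect", nc = nc, ch = as.integer(ch), reg_max = reg_max,
             c2 = c2, c3 = c3, strides = strides, children = c(box, cls))
}

gm_forward.gm_detect <- function(m, x, training = FALSE) {
  # x: list of three scale maps; returns list of three (4*reg_max + nc) maps
  out <- vector("list", length(x))
  for (i in seq_along(x)) {
    b <- gm_forward(m$children[[paste0("b", i, "_1")]], x[[i]], training)
    b <- gm_forward(m$children[[paste0("b", i, "_2")]], b, training)
    b <- gm_forward(m$children[[paste0("b", i, "_3")]], b, training)
    cl <- gm_forward(m$children[[paste0("c", i, "_1")]], x[[i]], training)
    cl <- gm_forward(m$children[[paste0("c", i, "_2")]], cl, training)
    cl <- gm_forward(m$children[[paste0("c", i, "_3")]], cl, training)
    out[[i]] <- map_concat(list(b, cl))
  }
  out
}

gm_backward.gm_detect <- function(m, dy) {
  # dy: list of per-scale gradients; returns list of input gradients
  dx <- vector("list", length(dy))
  for (i in seq_along(dy)) {
    parts <- map_concat_split(dy[[i]], c(4L * m$reg_max, m$nc))
    db <- gm_backward(m$children[[paste0("b", i, "_3")]], parts[[1L]])
    db <- gm_backward(m$children[[paste0("b", i, "_2")]], db)
    db <- gm_backward(m$children[[paste0("b", i, "_1")]], db)
    dc <- gm_backward(m$children[[paste0("c", i, "_3")]], parts[[2L]])
    dc <- gm_backward(m$children[[paste0("c", i, "_2")]], dc)
    dc <- gm_backward(m$children[[paste0("c", i, "_1")]], dc)
    dx[[i]] <- db + dc
  }
  dx
}

gm_profile.gm_detect <- function(m, shape) {
  # shape: list of three scale shapes
  fl <- 0
  for (i in seq_along(shape)) {
    s0 <- shape[[i]]
    sb <- c(s0[1L], s0[2L], m$c2)
    sc <- c(s0[1L], s0[2L], m$c3)
    fl <- fl + gm_profile(m$children[[paste0("b", i, "_1")]], s0)$flops +
      gm_profile(m$children[[paste0("b", i, "_2")]], sb)$flops +
      gm_profile(m$children[[paste0("b", i, "_3")]], sb)$flops +
      gm_profile(m$children[[paste0("c", i, "_1")]], s0)$flops +
      gm_profile(m$children[[paste0("c", i, "_2")]], sc)$flops +
      gm_profile(m$children[[paste0("c", i, "_3")]], sc)$flops
  }
  list(shape = NULL, flops = fl)
}
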