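# Minimal define-by-graph conv-net engine.
#
# Feature maps are double arrays with dim (H, W, C, N). Modules are
# environments carrying parameters ("w", "b", ...), accumulated gradients
# ("g_w", ...) and SGD momentum buffers ("v_w", ...). Dense convolution is
# im2col + BLAS GEMM; depthwise convolution, pooling and resampling run in
# compiled code. Each module caches what its backward pass needs; a module
# instance appears exactly once in a model graph, so a single cache slot
# suffices.

new_module <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  if (is.null(e$param_names)) e$param_names <- character(0)
  if (is.null(e$children)) e$children <- list()
  class(e) <- c(paste0("gm_", type), "gm_module")
  e
}

gm_forward <- function(m, x, training = FALSE) UseMethod("gm_forward")
gm_backward <- function(m, dy) UseMethod("gm_backward")

#' @noRd
gm_modules <- function(m) {
  out <- list(m)
  for (ch in m$children) out <- c(out, gm_modules(ch))
  out
}

gm_zero_grad <- function(m) {
  for (mod in gm_modules(m)) {
    for (p in mod$param_names) {
      g <- paste0("g_", p)
      assign(g, array(0, dim(mod[[p]]) %||% length(mod[[p]])), envir = mod)
    }
  }
  invisible(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_map <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature map must be an array", call. = FALSE)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  if (length(dim(x)) != 4L) stop("feature map must have 3 or 4 dims", call. = FALSE)
  x
}

map_dims <- function(x) {
  d <- dim(x)
  list(H = d[1L], W = d[2L], C = d[3L], N = d[4L])
}

sigmoid_ <- function(x) 1 / (1 + exp(-x))
silu_ <- function(x) x * sigmoid_(x)
silu_grad_ <- function(x) {
  s <- sigmoid_(x)
  s * (1 + x * (1 - s))
}

conv_out_size <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

## ---- dense convolution -------------------------------------------------

nn_conv2d <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L,
                      bias = FALSE) {
  m <- new_module("conv2d",
    cin = as.integer(cin), cout = as.integer(cout), k = as.integer(k),
    stride = as.integer(stride), pad = as.integer(pad),
    w = he_init(c(k, k, cin, cout), fan_in = k * k * cin),
    param_names = "w")
  if (bias) {
    m$b <- numeric(cout)
    m$param_names <- c("w", "b")
  }
  m
}

gm_forward.gm_conv2d <- function(m, x, training = FALSE) {
  x <- as_map(x)
  d <- map_dims(x)
  stopifnot(d$C == m$cin)
  cols <- cpp_im2col(x, d$H, d$W, d$C, d$N, m$k, m$stride, m$pad)
  Ho <- conv_out_size(d$H, m$k, m$stride, m$pad)
  Wo <- conv_out_size(d$W, m$k, m$stride, m$pad)
  wmat <- matrix(m$w, nrow = m$k * m$k * m$cin)
  ymat <- crossprod(cols, wmat)
  if (!is.null(m$b)) ymat <- sweep(ymat, 2L, m$b, "+")
  y <- aperm(array(ymat, c(Ho, Wo, d$N, m$cout)), c(1L, 2L, 4L, 3L))
  if (training) m$cache <- list(cols = cols, d = d, Ho = Ho, Wo = Wo)
  y
}

gm_backward.gm_conv2d <- function(m, dy) {
  cc <- m$cache
  dymat <- matrix(aperm(dy, c(1L, 2L, 4L, 3L)), ncol = m$cout)
  m$g_w <- m$g_w + array(cc$cols %*% dymat, dim(m$w))
  if (!is.null(m$b)) m$g_b <- m$g_b + colSums(dymat)
  wmat <- matrix(m$w, nrow = m$k * m$k * m$cin)
  dcols <- tcrossprod(wmat, dymat)
  dx <- cpp_col2im(dcols, cc$d$H, cc$d$W, cc$d$C, cc$d$N, m$k, m$stride, m$pad)
  m$cache <- NULL
  dx
}

## ---- depthwise convolution ----------------------------------------------

nn_dwconv2d <- function(c, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  new_module("dwconv2d",
    c = as.integer(c), k = as.integer(k), stride = as.integer(stride),
    pad = as.integer(pad),
    w = he_init(c(k, k, c), fan_in = k * k),
    param_names = "w")
}

gm_forward.gm_dwconv2d <- function(m, x, training = FALSE) {
  x <- as_map(x)
  d <- map_dims(x)
  stopifnot(d$C == m$c)
  y <- cpp_dwconv_fwd(x, d$H, d$W, d$C, d$N, m$w, m$k, m$stride, m$pad)
  if (training) m$cache <- list(x = x, d = d)
  y
}

gm_backward.gm_dwconv2d <- function(m, dy) {
  cc <- m$cache
  r <- cpp_dwconv_bwd(cc$x, cc$d$H, cc$d$W, cc$d$C, cc$d$N,
                      m$w, m$k, m$stride, m$pad, dy)
  m$g_w <- m$g_w + r$dw
  m$cache <- NULL
  r$dx
}

## ---- batch normalisation -------------------------------------------------

nn_batchnorm <- function(c, eps = 1e-3, momentum = 0.03) {
  new_module("batchnorm",
    c = as.integer(c), eps = eps, momentum = momentum,
    w = rep(1, c), b = numeric(c),
    running_mean = numeric(c), running_var = rep(1, c),
    param_names = c("w", "b"))
}

# Channels-as-columns view: rows run over (H, W, N).
bn_channel_mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1L, 2L, 4L, 3L)), ncol = d[3L])
}

bn_channel_unmat <- function(xm, d) {
  aperm(array(xm, c(d[1L], d[2L], d[4L], d[3L])), c(1L, 2L, 4L, 3L))
}

gm_forward.gm_batchnorm <- function(m, x, training = FALSE) {
  x <- as_map(x)
  d <- dim(x)
  xm <- bn_channel_mat(x)
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    v <- colMeans(xc * xc)
    m$running_mean <- (1 - m$momentum) * m$running_mean + m$momentum * mu
    m$running_var <- (1 - m$momentum) * m$running_var + m$momentum * v
    inv <- 1 / sqrt(v + m$eps)
    xhat <- sweep(xc, 2L, inv, "*")
    ym <- sweep(sweep(xhat, 2L, m$w, "*"), 2L, m$b, "+")
    m$cache <- list(xhat = xhat, inv = inv, d = d)
  } else {
    inv <- 1 / sqrt(m$running_var + m$eps)
    ym <- sweep(sweep(sweep(xm, 2L, m$running_mean), 2L, inv * m$w, "*"),
                2L, m$b, "+")
  }
  bn_channel_unmat(ym, d)
}

gm_backward.gm_batchnorm <- function(m, dy) {
  cc <- m$cache
  dym <- bn_channel_mat(dy)
  n <- nrow(dym)
  m$g_w <- m$g_w + colSums(dym * cc$xhat)
  m$g_b <- m$g_b + colSums(dym)
  dxhat <- sweep(dym, 2L, m$w, "*")
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cc$xhat)
  dxm <- sweep(dxhat, 2L, s1 / n) - sweep(cc$xhat, 2L, s2 / n, "*")
  dxm <- sweep(dxm, 2L, cc$inv, "*")
  m$cache <- NULL
  bn_channel_unmat(dxm, cc$d)
}

## ---- activations -----------------------------------------------------------

nn_act <- function(kind = c("silu", "sigmoid", "none")) {
  new_module("act", kind = match.arg(kind))
}

gm_forward.gm_act <- function(m, x, training = FALSE) {
  y <- switch(m$kind,
    silu = silu_(x),
    sigmoid = sigmoid_(x),
    none = x)
  if (training) m$cache <- switch(m$kind, silu = x, sigmoid = y, none = NULL)
  y
}

gm_backward.gm_act <- function(m, dy) {
  dx <- switch(m$kind,
    silu = dy * silu_grad_(m$cache),
    sigmoid = dy * m$cache * (1 - m$cache),
    none = dy)
  m$cache <- NULL
  dx
}

## ---- SGD with momentum ----------------------------------------------------

#' @noRd
gm_sgd_step <- function(model, lr, momentum = 0.937, weight_decay = 5e-4) {
  mods <- if (inherits(model, "gma_model"))
    unlist(lapply(model$nodes, function(nd) gm_modules(nd$m)),
           recursive = FALSE)
  else gm_modules(model)
  for (mod in mods) {
    for (p in mod$param_names) {
      g <- mod[[paste0("g_", p)]] + weight_decay * mod[[p]]
      vname <- paste0("v_", p)
      v <- mod[[vname]] %||% array(0, dim(mod[[p]]) %||% length(mod[[p]]))
      v <- momentum * v - lr * g
      assign(vname, v, envir = mod)
      assign(p, mod[[p]] + v, envir = mod)
    }
  }
  invisible(model)
}
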