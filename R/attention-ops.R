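# Closed-form, shape-preserving feature operators: GhostConv bookkeeping
# and application, the SimAM minimal-energy attention, and mixed local
# channel attention (MLCA).

#' Specification of a Ghost convolution
#'
#' A Ghost convolution produces `out_channels / ratio` channels with an
#' ordinary dense `primary_kernel` convolution and generates the remaining
#' channels by cheap depthwise `cheap_kernel` transforms of the primary
#' output, cutting parameters and FLOPs by a factor approaching `ratio`.
#'
#' @param in_channels,out_channels Channel counts of input and output maps.
#' @param ratio Integer ratio `s >= 1`; `out_channels` must be divisible by
#'   it. `ratio = 1` degenerates to a plain dense convolution.
#' @param primary_kernel,cheap_kernel Odd kernel sizes of the dense and the
#'   cheap depthwise branch.
#' @param stride Stride of the primary convolution.
#' @return An object of class `ghost_conv_spec`.
#' @export
ghost_conv_spec <- function(in_channels, out_channels, ratio = 2L,
                            primary_kernel = 3L, cheap_kernel = 3L,
                            stride = 1L) {
  if (in_channels < 1L || out_channels < 1L)
    stop("channel counts must be positive", call. = FALSE)
  if (ratio < 1L) stop("ratio must be >= 1", call. = FALSE)
  if (out_channels %% ratio != 0L)
    stop("out_channels must be divisible by ratio", call. = FALSE)
  if (primary_kernel %% 2L == 0L || cheap_kernel %% 2L == 0L)
    stop("kernel sizes must be odd", call. = FALSE)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 ratio = as.integer(ratio),
                 primary_kernel = as.integer(primary_kernel),
                 cheap_kernel = as.integer(cheap_kernel),
                 stride = as.integer(stride)),
            class = "ghost_conv_spec")
}

#' Kernel-weight count of an ordinary dense convolution
#'
#' @param in_channels,out_channels Channel counts.
#' @param kernel Kernel size.
#' @return Number of kernel weights (bias and normalisation excluded).
#' @export
conv_param_count <- function(in_channels, out_channels, kernel) {
  in_channels * out_channels * kernel^2
}

#' Kernel-weight count of a Ghost convolution
#'
#' @param spec A [ghost_conv_spec()].
#' @return Number of kernel weights across both branches.
#' @export
ghost_param_count <- function(spec) {
  stopifnot(inherits(spec, "ghost_conv_spec"))
  prim <- spec$out_channels %/% spec$ratio
  spec$in_channels * prim * spec$primary_kernel^2 +
    (spec$out_channels - prim) * spec$cheap_kernel^2
}

#' Speed-up and compression ratios of a Ghost convolution
#'
#' Ratios of an ordinary dense convolution to the Ghost formulation with
#' the same output size: `R_C = s c k^2 / (c k^2 + (s - 1) d^2)` and the
#' matching FLOP ratio (identical for shape-preserving branches). Both
#' approach `s` as the input channel count grows.
#'
#' @param spec A [ghost_conv_spec()].
#' @param out_height,out_width Output spatial size (the FLOP ratio is
#'   independent of it; accepted for completeness).
#' @return List with elements `speedup` and `compression`.
#' @export
ghost_ratios <- function(spec, out_height = 1L, out_width = 1L) {
  stopifnot(inherits(spec, "ghost_conv_spec"))
  if (out_height < 1L || out_width < 1L)
    stop("output spatial size must be >= 1", call. = FALSE)
  s <- spec$ratio
  c <- spec$in_channels
  k <- spec$primary_kernel
  d <- spec$cheap_kernel
  rc <- (s * c * k^2) / (c * k^2 + (s - 1) * d^2)
  list(speedup = rc, compression = rc)
}

#' Apply a Ghost convolution to a feature map
#'
#' Builds the two branches with weights drawn from the current RNG state
#' (He initialisation) and applies them in inference mode: the first
#' `out_channels / ratio` output channels come from the dense primary
#' convolution, the remaining ones from per-channel depthwise transforms
#' of the primary output. Intended for structural experiments, not
#' training; inside a detector graph the trainable block version is used.
#'
#' @param x Feature map array, dim `(H, W, C)` or `(H, W, C, N)`.
#' @param spec A [ghost_conv_spec()]; `in_channels` must equal `dim(x)[3]`.
#' @return Feature map with `out_channels` channels; attribute
#'   `param_count` carries the kernel-weight count actually allocated.
#' @export
ghost_conv <- function(x, spec) {
  stopifnot(inherits(spec, "ghost_conv_spec"))
  x <- as_map(x)
  d <- map_dims(x)
  if (d$C != spec$in_channels)
    stop("input has ", d$C, " channels; spec expects ", spec$in_channels,
         call. = FALSE)
  prim_ch <- spec$out_channels %/% spec$ratio
  prim <- nn_conv2d(spec$in_channels, prim_ch, spec$primary_kernel,
                    stride = spec$stride)
  y1 <- gm_forward(prim, x)
  nparam <- length(prim$w)
  if (spec$ratio == 1L) {
    out <- y1
  } else {
    pieces <- list(y1)
    for (i in seq_len(spec$ratio - 1L)) {
      dw <- nn_dwconv2d(prim_ch, spec$cheap_kernel)
      pieces[[i + 1L]] <- gm_forward(dw, y1)
      nparam <- nparam + length(dw$w)
    }
    out <- map_concat(pieces)
  }
  attr(out, "param_count") <- nparam
  out
}

## ---- SimAM -----------------------------------------------------------------

#' Per-channel statistics feeding the SimAM energy
#'
#' @param mean,variance Mean and variance of the non-target neurons of a
#'   channel (variance with the count of those neurons as denominator).
#' @param lambda Positive energy regulariser; default `1e-4`.
#' @return An object of class `simam_stats`.
#' @export
simam_stats <- function(mean, variance, lambda = 1e-4) {
  if (any(variance < 0)) stop("variance must be >= 0", call. = FALSE)
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  structure(list(mean = mean, variance = variance, lambda = lambda),
            class = "simam_stats")
}

#' Minimal SimAM energy of a neuron
#'
#' Closed form of the per-neuron minimal energy
#' `e* = 4 (sigma^2 + lambda) / ((t - mu)^2 + 2 sigma^2 + 2 lambda)`,
#' the analytical minimum of the binary-label energy that separates the
#' target neuron from the remaining neurons of its channel. A neuron at
#' the channel mean attains `e* = 2` exactly; the energy decreases
#' strictly with `(t - mu)^2`, so distinctive neurons receive larger
#' attention weights `sigmoid(1 / e*)`.
#'
#' @param t Neuron value(s).
#' @param stats A [simam_stats()] object.
#' @return Minimal energy, same length as `t`; strictly positive.
#' @export
simam_energy <- function(t, stats) {
  stopifnot(inherits(stats, "simam_stats"))
  4 * (stats$variance + stats$lambda) /
    ((t - stats$mean)^2 + 2 * stats$variance + 2 * stats$lambda)
}

# Attention weights for a (H, W, C, N) map using exact leave-one-out
# channel statistics: for neuron t, mu and sigma^2 are mean and variance
# of the other M - 1 spatial positions of its channel.
simam_weights <- function(x, lambda = 1e-4) {
  d <- map_dims(x)
  M <- d$H * d$W
  if (M < 2L) {
    warning("simam: single-pixel channel, returning unit weights")
    return(array(1, dim(x)))
  }
  xm <- matrix(x, nrow = M)             # columns run over (channel, sample)
  S <- colSums(xm)
  SS <- colSums(xm * xm)
  mu <- sweep(-xm, 2L, S, "+") / (M - 1)
  ex2 <- sweep(-xm * xm, 2L, SS, "+") / (M - 1)
  v <- pmax(ex2 - mu * mu, 0)
  e <- 4 * (v + lambda) / ((xm - mu)^2 + 2 * v + 2 * lambda)
  array(sigmoid_(1 / e), dim(x))
}

#' SimAM attention over a feature map
#'
#' Scales every neuron by `sigmoid(1 / e*)`, where `e*` is the closed-form
#' minimal energy computed from the neuron's deviation from its channel's
#' spatial statistics. The operator has no learnable parameters and
#' preserves the input shape. Single-pixel channels are returned unchanged
#' with a warning (their statistics are degenerate).
#'
#' @param x Feature map array, dim `(H, W, C)` or `(H, W, C, N)`.
#' @param lambda Positive regulariser of the energy; default `1e-4`.
#' @return Array of the same shape as `x`.
#' @export
simam_attention <- function(x, lambda = 1e-4) {
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  x4 <- as_map(x)
  y <- simam_weights(x4, lambda) * x4
  dim(y) <- dim(x)
  y
}

## ---- MLCA ---------------------------------------------------------------------

#' Specification of a mixed local channel attention gate
#'
#' @param channels Channel count of the gated feature map.
#' @param local_grid Side of the local average-pooling grid; default 5.
#' @param conv1d_kernel Odd length of the 1-D channel convolutions; by
#'   default derived from the channel count with the usual efficient
#'   channel attention rule (nearest odd to `(log2(C) + 1) / 2`).
#' @return An object of class `mlca_spec`.
#' @export
mlca_spec <- function(channels, local_grid = 5L,
                      conv1d_kernel = eca_kernel_size(channels)) {
  if (local_grid < 1L) stop("local_grid must be >= 1", call. = FALSE)
  if (conv1d_kernel %% 2L == 0L)
    stop("conv1d_kernel must be odd", call. = FALSE)
  structure(list(channels = as.integer(channels),
                 local_grid = as.integer(local_grid),
                 conv1d_kernel = as.integer(conv1d_kernel)),
            class = "mlca_spec")
}

#' Mixed local channel attention over a feature map
#'
#' Forms a multiplicative gate in (0, 1) from two branches: the feature map
#' average-pooled to a `local_grid^2` grid with a 1-D convolution across
#' channels at each cell (local), and the globally average-pooled channel
#' vector with its own 1-D convolution (global). The branch outputs are
#' averaged, squashed by a sigmoid and resampled to the input resolution.
#' The only learnable weights are the two 1-D kernels.
#'
#' @param x Feature map array, dim `(H, W, C)` or `(H, W, C, N)`.
#' @param spec An [mlca_spec()]; `channels` must match `dim(x)[3]`.
#' @param weights Optional list with numeric vectors `local` and `global`
#'   of length `conv1d_kernel`; drawn from the current RNG if omitted.
#' @return Gated array of the same shape as `x`; attributes `n_params`
#'   (learnable weight count) and `gate` (the broadcast gate).
#' @export
mlca_attention <- function(x, spec = mlca_spec(dim(as_map(x))[3L]),
                           weights = NULL) {
  stopifnot(inherits(spec, "mlca_spec"))
  x4 <- as_map(x)
  d <- map_dims(x4)
  if (d$C != spec$channels)
    stop("input has ", d$C, " channels; spec expects ", spec$channels,
         call. = FALSE)
  if (d$H < spec$local_grid || d$W < spec$local_grid)
    stop("spatial size smaller than the local pooling grid", call. = FALSE)
  m <- nn_mlca(spec$channels, grid = spec$local_grid, k = spec$conv1d_kernel)
  if (!is.null(weights)) {
    m$w_local <- as.numeric(weights$local)
    m$w_global <- as.numeric(weights$global)
    stopifnot(length(m$w_local) == spec$conv1d_kernel,
              length(m$w_global) == spec$conv1d_kernel)
  }
  y <- gm_forward(m, x4, training = TRUE)
  gate <- m$cache$gate
  m$cache <- NULL
  dim(y) <- dim(x)
  attr(y, "n_params") <- 2L * spec$conv1d_kernel
  attr(y, "gate") <- gate
  y
}
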