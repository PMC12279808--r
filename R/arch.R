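# Detector assembly and profiling.
#
# Two variants are provided: a YOLOv8n-style single-class baseline and the
# lightweight variant with a Ghost-HGNetV2 backbone (depthwise-conv
# downsampling between stages), SimAM after the SPPF block at the P5
# position, a FPN+PAN neck whose C2f blocks carry MLCA gates in their
# bottlenecks ("CM" blocks), and an optional auxiliary detection head used
# only during training.

#' Detector architecture configuration
#'
#' @param variant `"gma"` (Ghost-HGNetV2 backbone + attention neck) or
#'   `"baseline_v8n"` (standard YOLOv8n graph).
#' @param num_classes Number of object classes; default 1 (the corn whorl
#'   "center leaf" class is the only class in this problem).
#' @param input_size Nominal square input side in pixels; must be divisible
#'   by 32.
#' @param include_aux_head Attach the auxiliary training head (gma only;
#'   ignored for the baseline). The auxiliary head never contributes to
#'   deploy-mode parameter or FLOP figures.
#' @param width_multiple Baseline channel scaling factor (YOLOv8 "W");
#'   0.25 reproduces the nano model.
#' @param stem_channels,stage_mid,stage_out,hg_layers Ghost backbone stage
#'   widths: stem width, the per-stage GhostConv widths (length 4), the
#'   per-stage output widths (length 4, the last three are the P3/P4/P5
#'   widths fed to the neck), and the number of GhostConvs per block. The
#'   defaults are calibrated so that the deploy-mode footprint matches the
#'   published complexity of the architecture (2.3 M parameters, 6.8 GFLOPs
#'   at 640).
#' @param simam_lambda Energy regulariser of the SimAM layer.
#' @return An object of class `arch_config`.
#' @export
arch_config <- function(variant = c("gma", "baseline_v8n"),
                        num_classes = 1L,
                        input_size = 640L,
                        include_aux_head = TRUE,
                        width_multiple = 0.25,
                        stem_channels = 16L,
                        stage_mid = c(24L, 48L, 56L, 112L),
                        stage_out = c(48L, 64L, 128L, 256L),
                        hg_layers = 3L,
                        simam_lambda = 1e-4) {
  variant <- match.arg(variant)
  if (num_classes < 1L) stop("num_classes must be >= 1", call. = FALSE)
  if (input_size %% 32L != 0L)
    stop("input_size must be divisible by 32", call. = FALSE)
  if (length(stage_mid) != 4L || length(stage_out) != 4L)
    stop("stage_mid and stage_out must have length 4", call. = FALSE)
  if (any(stage_mid < 1L) || any(stage_out < 1L) || stem_channels < 1L)
    stop("stage widths must be positive", call. = FALSE)
  structure(list(variant = variant,
                 num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 include_aux_head = isTRUE(include_aux_head) &&
                   variant == "gma",
                 width_multiple = width_multiple,
                 stem_channels = as.integer(stem_channels),
                 stage_mid = as.integer(stage_mid),
                 stage_out = as.integer(stage_out),
                 hg_layers = as.integer(hg_layers),
                 simam_lambda = simam_lambda),
            class = "arch_config")
}

#' Read an architecture configuration from YAML
#'
#' Recognised keys mirror the arguments of [arch_config()].
#'
#' @param path Path to a YAML file.
#' @return An `arch_config` object.
#' @export
read_arch_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(arch_config)))]
  do.call(arch_config, args)
}

## ---- graph assembly ---------------------------------------------------------

graph_add <- function(g, from, m) {
  g$nodes[[length(g$nodes) + 1L]] <- list(from = as.integer(from), m = m)
  length(g$nodes)
}

build_baseline_graph <- function(cfg) {
  w <- function(c) max(1L, as.integer(round(c * cfg$width_multiple)))
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  c1 <- w(64); c2 <- w(128); c3 <- w(256); c4 <- w(512); c5 <- w(1024)
  n1 <- graph_add(g, 0L, nn_conv_unit(3L, c1, 3L, 2L))
  n2 <- graph_add(g, n1, nn_conv_unit(c1, c2, 3L, 2L))
  n3 <- graph_add(g, n2, nn_c2f(c2, c2, 1L, shortcut = TRUE))
  n4 <- graph_add(g, n3, nn_conv_unit(c2, c3, 3L, 2L))
  n5 <- graph_add(g, n4, nn_c2f(c3, c3, 2L, shortcut = TRUE))
  n6 <- graph_add(g, n5, nn_conv_unit(c3, c4, 3L, 2L))
  n7 <- graph_add(g, n6, nn_c2f(c4, c4, 2L, shortcut = TRUE))
  n8 <- graph_add(g, n7, nn_conv_unit(c4, c5, 3L, 2L))
  n9 <- graph_add(g, n8, nn_c2f(c5, c5, 1L, shortcut = TRUE))
  n10 <- graph_add(g, n9, nn_sppf(c5, c5))
  list(g = g, p3 = n5, p4 = n7, p5 = n10,
       ch = c(c3, c4, c5))
}

build_gma_graph <- function(cfg) {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  s0 <- cfg$stem_channels
  cm <- cfg$stage_mid
  co <- cfg$stage_out
  nL <- cfg$hg_layers
  n1 <- graph_add(g, 0L, nn_conv_unit(3L, s0, 3L, 2L))
  n2 <- graph_add(g, n1, nn_conv_unit(s0, s0, 3L, 2L))
  n3 <- graph_add(g, n2, nn_hgblock(s0, cm[1L], co[1L], nL))
  n4 <- graph_add(g, n3, nn_dwdown(co[1L]))
  n5 <- graph_add(g, n4, nn_hgblock(co[1L], cm[2L], co[2L], nL))   # P3
  n6 <- graph_add(g, n5, nn_dwdown(co[2L]))
  n7 <- graph_add(g, n6, nn_hgblock(co[2L], cm[3L], co[3L], nL))   # P4
  n8 <- graph_add(g, n7, nn_dwdown(co[3L]))
  n9 <- graph_add(g, n8, nn_hgblock(co[3L], cm[4L], co[4L], nL))
  n10 <- graph_add(g, n9, nn_sppf(co[4L], co[4L]))
  n11 <- graph_add(g, n10, nn_simam(cfg$simam_lambda))             # P5
  list(g = g, p3 = n5, p4 = n7, p5 = n11,
       ch = c(co[2L], co[3L], co[4L]))
}

# FPN + PAN neck shared by both variants; `mlca = TRUE` turns the C2f
# blocks into CM blocks.
append_neck_head <- function(bb, cfg, mlca) {
  g <- bb$g
  ch <- bb$ch  # (P3, P4, P5) widths
  u1 <- graph_add(g, bb$p5, nn_upsample2x())
  cat1 <- graph_add(g, c(u1, bb$p4), nn_concat())
  t1 <- graph_add(g, cat1, nn_c2f(ch[3L] + ch[2L], ch[2L], 1L, mlca = mlca))
  u2 <- graph_add(g, t1, nn_upsample2x())
  cat2 <- graph_add(g, c(u2, bb$p3), nn_concat())
  t2 <- graph_add(g, cat2, nn_c2f(ch[2L] + ch[1L], ch[1L], 1L, mlca = mlca))
  d1 <- graph_add(g, t2, nn_conv_unit(ch[1L], ch[1L], 3L, 2L))
  cat3 <- graph_add(g, c(d1, t1), nn_concat())
  t3 <- graph_add(g, cat3, nn_c2f(ch[1L] + ch[2L], ch[2L], 1L, mlca = mlca))
  d2 <- graph_add(g, t3, nn_conv_unit(ch[2L], ch[2L], 3L, 2L))
  cat4 <- graph_add(g, c(d2, bb$p5), nn_concat())
  t4 <- graph_add(g, cat4, nn_c2f(ch[2L] + ch[3L], ch[3L], 1L, mlca = mlca))
  head <- graph_add(g, c(t2, t3, t4),
                    nn_detect(cfg$num_classes, ch,
                              input_ref = cfg$input_size))
  aux <- NA_integer_
  if (cfg$include_aux_head)
    aux <- graph_add(g, c(t2, t3, t4),
                     nn_detect(cfg$num_classes, ch,
                               input_ref = cfg$input_size))
  list(g = g, head = head, aux = aux)
}

#' Build a detector model
#'
#' @param config An [arch_config()].
#' @param seed Integer seed for the weight initialisation RNG, so that two
#'   builds with the same seed are identical.
#' @return A model handle of class `gma_model`.
#' @export
build_model <- function(config, seed = 0L) {
  stopifnot(inherits(config, "arch_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  bb <- switch(config$variant,
    baseline_v8n = build_baseline_graph(config),
    gma = build_gma_graph(config))
  nh <- append_neck_head(bb, config, mlca = config$variant == "gma")
  model <- new.env(parent = emptyenv())
  model$nodes <- nh$g$nodes
  model$head <- nh$head
  model$aux <- nh$aux
  model$config <- config
  model$strides <- c(8L, 16L, 32L)
  class(model) <- "gma_model"
  model
}

#' @export
print.gma_model <- function(x, ...) {
  cat(sprintf("<gma_model> variant=%s nc=%d nodes=%d aux_head=%s\n",
              x$config$variant, x$config$num_classes, length(x$nodes),
              ifelse(is.na(x$aux), "no", "yes")))
  invisible(x)
}

## ---- execution -----------------------------------------------------------------

#' Run a detector forward pass
#'
#' @param model A `gma_model`.
#' @param x Input image array, dim `(H, W, 3)` or `(H, W, 3, N)`, values in
#'   any real range (callers normally pass \\[0, 1\\]).
#' @param training Keep activation caches and use batch statistics in the
#'   normalisation layers.
#' @param with_aux Also evaluate the auxiliary head (training-time only
#'   structure; ignored when the model has none).
#' @return List with `lead` (list of three per-scale prediction maps of
#'   spatial size input/8, input/16, input/32 and `4 * 16 + num_classes`
#'   channels) and `aux` (same layout or `NULL`).
#' @export
model_forward <- function(model, x, training = FALSE, with_aux = FALSE) {
  x <- as_map(x)
  outs <- vector("list", length(model$nodes))
  for (i in seq_along(model$nodes)) {
    if (identical(i, model$aux) && !with_aux) next
    node <- model$nodes[[i]]
    inp <- if (length(node$from) == 1L) {
      if (node$from == 0L) x else outs[[node$from]]
    } else {
      lapply(node$from, function(j) if (j == 0L) x else outs[[j]])
    }
    outs[[i]] <- gm_forward(node$m, inp, training)
  }
  model$.outs <- if (training) outs else NULL
  list(lead = outs[[model$head]],
       aux = if (!is.na(model$aux)) outs[[model$aux]] else NULL)
}

# Backward pass from per-head gradients; grads_lead/grads_aux are lists of
# three per-scale arrays (aux may be NULL).
model_backward <- function(model, grads_lead, grads_aux = NULL) {
  n <- length(model$nodes)
  gbuf <- vector("list", n)
  add_grad <- function(idx, g) {
    if (idx == 0L) return(invisible(NULL))
    gbuf[[idx]] <<- if (is.null(gbuf[[idx]])) g else gbuf[[idx]] + g
  }
  seed_head <- function(idx, grads) {
    node <- model$nodes[[idx]]
    dxs <- gm_backward(node$m, grads)
    for (k in seq_along(node$from)) add_grad(node$from[k], dxs[[k]])
  }
  seed_head(model$head, grads_lead)
  if (!is.null(grads_aux) && !is.na(model$aux)) seed_head(model$aux, grads_aux)
  for (i in rev(seq_len(n))) {
    if (i == model$head || identical(i, model$aux)) next
    if (is.null(gbuf[[i]])) next
    node <- model$nodes[[i]]
    dx <- gm_backward(node$m, gbuf[[i]])
    if (length(node$from) == 1L) {
      add_grad(node$from, dx)
    } else {
      for (k in seq_along(node$from)) add_grad(node$from[k], dx[[k]])
    }
    gbuf[[i]] <- NULL
  }
  model$.outs <- NULL
  invisible(model)
}

## ---- profiling -------------------------------------------------------------------

model_module_list <- function(model, include_aux = TRUE) {
  idx <- seq_along(model$nodes)
  if (!include_aux && !is.na(model$aux)) idx <- setdiff(idx, model$aux)
  unlist(lapply(idx, function(i) gm_modules(model$nodes[[i]]$m)),
         recursive = FALSE)
}

#' Count learnable parameters of a model
#'
#' Deploy mode folds every batch-normalisation layer into its convolution
#' (the conv keeps a bias) and excludes the auxiliary head, matching how a
#' fused single-class checkpoint is profiled; train mode counts every
#' learnable scalar of the full training graph.
#'
#' @param model A `gma_model`.
#' @param mode `"deploy"` or `"train"`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model, mode = c("deploy", "train")) {
  mode <- match.arg(mode)
  fused <- mode == "deploy"
  idx <- seq_along(model$nodes)
  if (fused && !is.na(model$aux)) idx <- setdiff(idx, model$aux)
  total <- 0
  for (i in idx) total <- total + gm_count(model$nodes[[i]]$m, fused = fused)
  total
}

#' Estimate FLOPs of a deploy-mode forward pass
#'
#' Counted as 2 floating-point operations per multiply-accumulate over
#' convolution layers (dense, depthwise and 1-D), at batch size 1; biases,
#' normalisation, activations, pooling and resampling are not counted.
#'
#' @param model A `gma_model`.
#' @param input_size Square input side, divisible by 32; defaults to the
#'   config's input size.
#' @return FLOPs in units of 1e9 (GFLOPs), unrounded.
#' @export
estimate_flops <- function(model, input_size = model$config$input_size) {
  if (input_size %% 32L != 0L)
    stop("input_size must be divisible by 32", call. = FALSE)
  shapes <- vector("list", length(model$nodes))
  total <- 0
  for (i in seq_along(model$nodes)) {
    if (identical(i, model$aux)) next
    node <- model$nodes[[i]]
    shp <- if (length(node$from) == 1L) {
      if (node$from == 0L) c(input_size, input_size, 3L) else shapes[[node$from]]
    } else {
      lapply(node$from, function(j)
        if (j == 0L) c(input_size, input_size, 3L) else shapes[[j]])
    }
    p <- gm_profile(node$m, shp)
    shapes[[i]] <- p$shape
    total <- total + p$flops
  }
  total / 1e9
}

#' Build, profile and summarise a detector configuration
#'
#' @param config An [arch_config()].
#' @return A list of class `complexity_report` with `parameter_count`
#'   (deploy mode), `gflops` (at the config's input size) and `size_mb`
#'   (half-precision serialisation estimate, `parameters * 2 / 2^20`;
#'   approximate since container formats add overhead).
#' @export
complexity_report <- function(config) {
  model <- build_model(config)
  p <- count_parameters(model, "deploy")
  structure(list(parameter_count = p,
                 gflops = estimate_flops(model),
                 size_mb = p * 2 / 2^20),
            class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("parameters: %d (%.1f M)\ngflops: %.1f\nsize: %.1f MB (fp16 estimate)\n",
              x$parameter_count, x$parameter_count / 1e6, x$gflops, x$size_mb))
  invisible(x)
}
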