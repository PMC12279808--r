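# Shared fixtures: scaled-down architectures, synthetic datasets, toy
# prediction maps and independent numerical oracles.

# A narrow variant of the attention model for fast training tests.
tiny_gma_config <- function(aux = TRUE) {
  arch_config("gma", num_classes = 1L, include_aux_head = aux,
              stem_channels = 8L, stage_mid = c(8L, 8L, 8L, 16L),
              stage_out = c(16L, 16L, 32L, 64L), hg_layers = 1L)
}

make_scene_dataset <- function(n, size = 96L, n_plants = 1L, seed = 0L) {
  cfg <- scene_config(size = size, n_plants = n_plants)
  lapply(seq_len(n), function(i) {
    s <- generate_scene(cfg, seed = seed + i)
    s[c("image", "boxes")]
  })
}

# Random toy prediction maps for a 64 x 64 input (scales 8/4/2) plus
# random ground-truth boxes.
make_toy_predictions <- function(seed) {
  set.seed(seed)
  list(array(rnorm(8 * 8 * 65), c(8, 8, 65, 1)),
       array(rnorm(4 * 4 * 65), c(4, 4, 65, 1)),
       array(rnorm(2 * 2 * 65), c(2, 2, 65, 1)))
}

make_toy_gts <- function(seed, n = 2L, size = 64) {
  set.seed(seed + 1000L)
  w <- runif(n, 10, 28)
  h <- runif(n, 10, 28)
  data.frame(cls = 0L,
             cx = runif(n, w / 2, size - w / 2),
             cy = runif(n, h / 2, size - h / 2),
             w = w, h = h)
}

# Independent numerical minimisation of the binary-label neuron energy
# over (weight, bias); the closed form must match its minimum.
simam_energy_oracle <- function(t, others, lambda) {
  f <- function(par) {
    w <- par[1L]; b <- par[2L]
    mean((-1 - (w * others + b))^2) + (1 - (w * t + b))^2 + lambda * w^2
  }
  stats::optim(c(0, 0), f, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))$value
}

# The nine field-trial groups of the study (plants tested / identified /
# successfully treated).
field_groups <- function() {
  tab <- rbind(c(45, 42, 40), c(50, 45, 43), c(50, 46, 42), c(50, 44, 41),
               c(50, 46, 40), c(50, 47, 44), c(50, 45, 40), c(50, 46, 43),
               c(50, 45, 41))
  apply(tab, 1L, function(r) field_trial_counts(r[1L], r[2L], r[3L]))
}

# Threshold-enumeration AP oracle: step integration of the interpolated
# precision over the recall levels of every ranked prefix.
ap_oracle <- function(detections, gts, iou_threshold = 0.5) {
  ord <- order(-detections$conf, seq_len(nrow(detections)))
  d <- detections[ord, , drop = FALSE]
  used <- logical(nrow(gts))
  tp <- integer(nrow(d))
  for (k in seq_len(nrow(d))) {
    best <- 0; bj <- 0
    for (j in seq_len(nrow(gts))) {
      if (used[j]) next
      v <- iou(c(d$cx[k], d$cy[k], d$w[k], d$h[k]),
               c(gts$cx[j], gts$cy[j], gts$w[j], gts$h[j]))
      if (v > best) { best <- v; bj <- j }
    }
    if (bj > 0 && best >= iou_threshold) { tp[k] <- 1L; used[bj] <- TRUE }
  }
  P <- cumsum(tp) / seq_along(tp)
  R <- cumsum(tp) / nrow(gts)
  ap <- 0; prev <- 0
  for (r in unique(R[tp == 1L])) {
    ap <- ap + (r - prev) * max(P[R >= r])
    prev <- r
  }
  ap
}
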