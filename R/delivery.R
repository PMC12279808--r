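# Front-camera / rear-funnel (FCRF) timing chain and per-plant granule
# delivery simulation.
#
# The camera rides a distance L1 ahead of the release funnel. A plant is
# detected when the camera passes it; the granules are released after the
# signal delay T1 plus a programmable extra delay T4 and fall for T2 =
# sqrt(2 dH / g) (drag-free; wind was measured to be negligible for solid
# granules). The platform needs T3 = L1 / V1 to carry the funnel over the
# plant, so exact delivery requires T1 + T2 + T4 = T3.

#' FCRF timing configuration
#'
#' @param L1 Camera-to-funnel distance along the row (m).
#' @param H1 Funnel release height (m).
#' @param H2 Target (whorl) height (m); `H1 > H2 >= 0`.
#' @param V1 Platform speed (m/s).
#' @param T1 Signal processing/transmission delay (s).
#' @param T4 Programmable extra delay (s); see [required_delay()] for the
#'   value that closes the timing chain.
#' @param g Gravitational acceleration (m/s^2).
#' @return List of class `timing_config`.
#' @export
timing_config <- function(L1, H1, H2, V1, T1 = 0, T4 = 0, g = 9.81) {
  if (L1 <= 0) stop("L1 must be > 0", call. = FALSE)
  if (!(H1 > H2 && H2 >= 0)) stop("need H1 > H2 >= 0", call. = FALSE)
  if (V1 <= 0) stop("V1 must be > 0", call. = FALSE)
  if (T1 < 0 || T4 < 0) stop("delays must be >= 0", call. = FALSE)
  structure(list(L1 = L1, H1 = H1, H2 = H2, V1 = V1, T1 = T1, T4 = T4,
                 g = g),
            class = "timing_config")
}

#' Granule fall time
#'
#' `T2 = sqrt(2 (H1 - H2) / g)`, drag-free vertical fall through the
#' height difference.
#'
#' @param cfg A [timing_config()].
#' @return Fall time in seconds.
#' @export
fall_time <- function(cfg) {
  stopifnot(inherits(cfg, "timing_config"))
  if (cfg$H1 <= cfg$H2) stop("H1 must exceed H2", call. = FALSE)
  sqrt(2 * (cfg$H1 - cfg$H2) / cfg$g)
}

#' Platform travel time over the camera-funnel offset
#'
#' `T3 = L1 / V1`.
#'
#' @param cfg A [timing_config()].
#' @return Travel time in seconds.
#' @export
travel_time <- function(cfg) {
  stopifnot(inherits(cfg, "timing_config"))
  if (cfg$V1 <= 0) stop("V1 must be > 0", call. = FALSE)
  cfg$L1 / cfg$V1
}

#' Extra delay closing the timing chain
#'
#' Solves `T1 + T2 + T4 = T3` for T4. A negative solution means the
#' platform is too fast for the camera-funnel offset (the granules cannot
#' arrive in time) and raises an error.
#'
#' @param cfg A [timing_config()].
#' @return The required `T4` in seconds.
#' @export
required_delay <- function(cfg) {
  t4 <- travel_time(cfg) - cfg$T1 - fall_time(cfg)
  if (t4 < 0)
    stop("infeasible speed: T1 + T2 exceeds the travel time T3 ",
         "(platform too fast for L1)", call. = FALSE)
  t4
}

#' Row layout of target plants
#'
#' @param positions Plant positions along the row (m), strictly
#'   increasing.
#' @param detectable Logical per plant: can the vision model see the whorl
#'   at all (occluded plants are never detected).
#' @param tolerance Landing tolerance radius (m): a delivery counts as
#'   successful when the granules land within this distance of the whorl.
#' @return List of class `field_layout`.
#' @export
field_layout <- function(positions, detectable = TRUE, tolerance = 0.05) {
  if (any(diff(positions) <= 0))
    stop("positions must be strictly increasing", call. = FALSE)
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  detectable <- rep_len(detectable, length(positions))
  structure(list(positions = positions, detectable = detectable,
                 tolerance = tolerance),
            class = "field_layout")
}

#' Simulate one delivery run over a row
#'
#' Each plant is detected with probability `p_detect` (and only if its
#' layout flag allows); for detected plants the release is scheduled
#' `T1 + T2 + T4` after the camera crossing, with Gaussian timing jitter
#' and optional per-plant speed variation. When `compensate = TRUE` the
#' controller re-solves T4 from its (noisy) speed estimate, emulating the
#' dynamic delay adjustment. The landing offset under zero noise is
#' `V1 (T1 + T2 + T4) - L1`, i.e. exactly zero for a chain-closing T4.
#'
#' @param layout A [field_layout()].
#' @param cfg A [timing_config()]; its `T4` is used as the programmed
#'   delay unless `compensate = TRUE`.
#' @param detector List with `p_detect` (detection probability) and
#'   `center_sd` (metres of trigger-position error from the detected
#'   centre).
#' @param timing_jitter_sd Gaussian jitter (s) on the release instant.
#' @param speed_sd Per-plant Gaussian perturbation of the platform speed
#'   (m/s).
#' @param speed_est_sd Error (m/s) of the speed estimate used by the
#'   compensation.
#' @param compensate Recompute T4 per plant from the estimated speed.
#' @param seed Integer seed; outcomes are deterministic given it.
#' @return Data frame with one row per plant: `plant`, `position`,
#'   `detected`, `delivered`, `offset` (m, `NA` when undetected).
#' @export
simulate_run <- function(layout, cfg,
                         detector = list(p_detect = 1, center_sd = 0),
                         timing_jitter_sd = 0, speed_sd = 0,
                         speed_est_sd = 0, compensate = FALSE,
                         seed = 0L) {
  stopifnot(inherits(layout, "field_layout"),
            inherits(cfg, "timing_config"))
  set.seed(seed)
  n <- length(layout$positions)
  detected <- layout$detectable &
    (stats::rbinom(n, 1L, detector$p_detect) == 1L)
  offset <- rep(NA_real_, n)
  delivered <- logical(n)
  for (i in seq_len(n)) {
    if (!detected[i]) next
    v <- cfg$V1 + if (speed_sd > 0) stats::rnorm(1, 0, speed_sd) else 0
    v <- max(v, 1e-6)
    t4 <- cfg$T4
    if (compensate) {
      v_est <- v + if (speed_est_sd > 0) stats::rnorm(1, 0, speed_est_sd)
        else 0
      t4 <- max(0, cfg$L1 / max(v_est, 1e-6) - cfg$T1 - fall_time(cfg))
    }
    dt <- if (timing_jitter_sd > 0) stats::rnorm(1, 0, timing_jitter_sd)
      else 0
    trig_err <- if (detector$center_sd > 0)
      stats::rnorm(1, 0, detector$center_sd) else 0
    offset[i] <- v * (cfg$T1 + fall_time(cfg) + t4 + dt) - cfg$L1 + trig_err
    delivered[i] <- abs(offset[i]) <= layout$tolerance
  }
  data.frame(plant = seq_len(n), position = layout$positions,
             detected = detected, delivered = delivered, offset = offset)
}

#' Summarise a simulated run as field-trial counts and metrics
#'
#' @param outcomes Data frame from [simulate_run()] (or several rbind-ed
#'   runs).
#' @return List with the `counts` ([field_trial_counts()]) and the
#'   percentage `metrics` ([delivery_metrics()]).
#' @export
delivery_outcome_summary <- function(outcomes) {
  counts <- field_trial_counts(n_total = nrow(outcomes),
                               n_identified = sum(outcomes$detected),
                               n_success = sum(outcomes$delivered))
  list(counts = counts, metrics = delivery_metrics(counts))
}
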