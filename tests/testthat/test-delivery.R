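test_that("fall time follows the free-fall law", {
  cfg <- timing_config(L1 = 1, H1 = 0.9905, H2 = 0.5, V1 = 0.5)
  expect_equal(fall_time(cfg), sqrt(0.1))          # dH = 0.4905 m
  expect_equal(round(fall_time(cfg), 4), 0.3162)
  # sqrt law: quadrupling the height difference doubles the time
  cfg4 <- timing_config(L1 = 1, H1 = 0.5 + 4 * 0.4905, H2 = 0.5, V1 = 0.5)
  expect_equal(fall_time(cfg4), 2 * fall_time(cfg))
  # vanishing height difference
  cfg0 <- timing_config(L1 = 1, H1 = 0.5 + 1e-9, H2 = 0.5, V1 = 0.5)
  expect_lt(fall_time(cfg0), 1e-4)
  expect_error(timing_config(L1 = 1, H1 = 0.4, H2 = 0.5, V1 = 1), "H1 > H2")
})

test_that("travel time and the compensating delay close the chain", {
  cfg <- timing_config(L1 = 1, H1 = 1, H2 = 0.5, V1 = 0.5)
  expect_equal(travel_time(cfg), 2)
  # doubling the speed halves the travel time
  cfg2 <- timing_config(L1 = 1, H1 = 1, H2 = 0.5, V1 = 1)
  expect_equal(travel_time(cfg2), travel_time(cfg) / 2)
  # T4 = T3 - T1 - T2 exactly
  cfgA <- timing_config(L1 = 0.5, H1 = 0.9905, H2 = 0.5, V1 = 0.5,
                        T1 = 0.2)
  t4 <- required_delay(cfgA)
  expect_equal(cfgA$T1 + fall_time(cfgA) + t4, travel_time(cfgA))
  # nominal condition T1 + T2 = T3 gives T4 = 0
  v_nom <- cfgA$L1 / (cfgA$T1 + fall_time(cfgA))
  cfgN <- timing_config(L1 = 0.5, H1 = 0.9905, H2 = 0.5, V1 = v_nom,
                        T1 = 0.2)
  expect_equal(required_delay(cfgN), 0, tolerance = 1e-12)
  # too fast: infeasible
  cfgF <- timing_config(L1 = 0.5, H1 = 0.9905, H2 = 0.5, V1 = 5, T1 = 0.2)
  expect_error(required_delay(cfgF), "infeasible")
  expect_error(timing_config(L1 = 0, H1 = 1, H2 = 0.5, V1 = 1), "L1")
})

test_that("noise-free simulation delivers every detected plant exactly", {
  cfg <- timing_config(L1 = 1, H1 = 0.9905, H2 = 0.5, V1 = 0.5, T1 = 0.2)
  cfg$T4 <- required_delay(cfg)
  lay <- field_layout(seq(0.3, by = 0.25, length.out = 30))
  out <- simulate_run(lay, cfg, seed = 1)
  expect_true(all(out$detected))
  expect_true(all(out$delivered))
  expect_equal(max(abs(out$offset)), 0)            # chain conservation
  # degenerate detector
  out0 <- simulate_run(lay, cfg, detector = list(p_detect = 0,
                                                 center_sd = 0), seed = 1)
  expect_false(any(out0$detected))
  expect_false(any(out0$delivered))
})

test_that("delivery counts respect detected >= delivered on every run", {
  cfg <- timing_config(L1 = 1, H1 = 0.9905, H2 = 0.5, V1 = 0.5, T1 = 0.2)
  cfg$T4 <- required_delay(cfg)
  lay <- field_layout(seq(0.3, by = 0.25, length.out = 45),
                      tolerance = 0.04)
  for (s in 1:20) {
    out <- simulate_run(lay, cfg,
                        detector = list(p_detect = 0.9, center_sd = 0.02),
                        timing_jitter_sd = 0.05, speed_sd = 0.05,
                        compensate = TRUE, speed_est_sd = 0.02, seed = s)
    expect_true(all(out$delivered[out$delivered] ==
                      out$detected[out$delivered]))
    sm <- delivery_outcome_summary(out)
    expect_lte(sm$counts$n_success, sm$counts$n_identified)
    expect_lte(sm$counts$n_identified, sm$counts$n_total)
    # product identity on unrounded metrics
    m <- delivery_metrics(sm$counts, digits = NULL)
    expect_equal(m[["delivery_rate"]],
                 m[["detection_accuracy"]] * m[["delivery_precision"]] / 100)
  }
  # identical runs for identical seeds
  o1 <- simulate_run(lay, cfg, detector = list(p_detect = 0.8,
                                               center_sd = 0.01), seed = 3)
  o2 <- simulate_run(lay, cfg, detector = list(p_detect = 0.8,
                                               center_sd = 0.01), seed = 3)
  expect_identical(o1, o2)
})

test_that("simulated field campaign reproduces rate = accuracy x precision", {
  # study-sized campaign: 445 plants, detector and delivery noise tuned to
  # the field operating point; the identity must hold on simulated counts
  cfg <- timing_config(L1 = 1, H1 = 0.9905, H2 = 0.5, V1 = 0.5, T1 = 0.2)
  cfg$T4 <- required_delay(cfg)
  lay <- field_layout(seq(0.3, by = 0.25, length.out = 445),
                      tolerance = 0.05)
  rates <- sapply(1:20, function(s) {
    out <- simulate_run(lay, cfg,
                        detector = list(p_detect = 0.912, center_sd = 0.02),
                        timing_jitter_sd = 0.055, seed = s)
    m <- delivery_metrics(delivery_outcome_summary(out)$counts,
                          digits = NULL)
    c(m, prod = m[["detection_accuracy"]] * m[["delivery_precision"]] / 100)
  })
  expect_equal(unname(rates["delivery_rate", ]), unname(rates["prod", ]))
  # the mean delivery rate sits near the product of the two factors
  expect_lt(abs(mean(rates["delivery_rate", ]) -
                  mean(rates["detection_accuracy", ]) *
                  mean(rates["delivery_precision", ]) / 100), 1.5)
})
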