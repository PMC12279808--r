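test_that("ghost ratio calculators reproduce the closed-form counts", {
  # s = 1 degenerates to an ordinary convolution
  s1 <- ghost_conv_spec(64, 64, ratio = 1, primary_kernel = 3)
  r1 <- ghost_ratios(s1)
  expect_equal(r1$speedup, 1)
  expect_equal(r1$compression, 1)
  expect_equal(ghost_param_count(s1), conv_param_count(64, 64, 3))

  # worked example: c = 64, n = 64, k = d = 3, s = 2
  sp <- ghost_conv_spec(64, 64, ratio = 2, primary_kernel = 3,
                        cheap_kernel = 3)
  expect_equal(conv_param_count(64, 64, 3), 36864)
  expect_equal(ghost_param_count(sp), 18720)
  expect_equal(ghost_ratios(sp)$compression, 1152 / 585)
  expect_equal(conv_param_count(64, 64, 3) / ghost_param_count(sp),
               ghost_ratios(sp)$compression)

  # compression approaches the ratio s as channels grow
  big <- ghost_conv_spec(1e6, 2, ratio = 2, primary_kernel = 3,
                         cheap_kernel = 3)
  expect_lt(abs(ghost_ratios(big)$compression - 2), 1e-3)
  for (c in c(16L, 64L, 256L, 1024L)) {
    rc <- ghost_ratios(ghost_conv_spec(c, 2L * c, ratio = 2))$compression
    expect_lt(rc, 2)
    if (c >= 256L) expect_lt(abs(rc - 2) / 2, 0.05)
  }
})

test_that("ghost spec validation rejects inconsistent configurations", {
  expect_error(ghost_conv_spec(16, 15, ratio = 2), "divisible")
  expect_error(ghost_conv_spec(16, 16, ratio = 0), "ratio")
  expect_error(ghost_conv_spec(16, 16, primary_kernel = 4), "odd")
})

test_that("ghost convolution produces the stated output structure", {
  set.seed(1)
  x <- array(rnorm(12 * 12 * 8), c(12, 12, 8, 1))
  sp <- ghost_conv_spec(8, 16, ratio = 2)
  y <- ghost_conv(x, sp)
  expect_equal(dim(y)[3L], 16L)
  expect_equal(dim(y)[1:2], c(12L, 12L))
  expect_lt(attr(y, "param_count"), conv_param_count(8, 16, 3))
  # s = 1: structurally a single dense convolution
  y1 <- ghost_conv(x, ghost_conv_spec(8, 16, ratio = 1))
  expect_equal(attr(y1, "param_count"), conv_param_count(8, 16, 3))
  expect_error(ghost_conv(array(0, c(4, 4, 3, 1)), sp), "channels")
})

test_that("simam closed-form energy matches numerical minimisation", {
  # the zero-deviation neuron always attains energy exactly 2
  expect_equal(simam_energy(0.7, simam_stats(0.7, 1.3)), 2)
  expect_identical(simam_energy(-4, simam_stats(-4, 0)), 2)
  # dominant regulariser forces the energy to 2 for any neuron
  expect_lt(abs(simam_energy(5, simam_stats(0, 1, lambda = 1e9)) - 2), 1e-6)
  # frozen worked value
  expect_lt(abs(simam_energy(2, simam_stats(0, 1, 1e-4)) -
                  4.0004 / 6.0002), 1e-6)

  set.seed(11)
  for (i in 1:100) {
    M <- sample(3:40, 1)
    others <- rnorm(M - 1, sd = runif(1, 0.5, 3))
    t <- rnorm(1, sd = 2)
    lam <- 10^runif(1, -4, -1)
    closed <- simam_energy(t, simam_stats(mean(others),
                                          mean((others - mean(others))^2),
                                          lam))
    expect_lt(abs(closed - simam_energy_oracle(t, others, lam)), 1e-4)
  }
})

test_that("simam energy decreases strictly with the deviation from the mean", {
  st <- simam_stats(0, 0.8, 1e-4)
  dev <- seq(0, 4, by = 0.25)
  e <- simam_energy(dev, st)
  expect_true(all(diff(e) < 0))
  expect_true(all(e > 0))
  # hence the attention weight sigmoid(1/e) increases with the deviation
  expect_true(all(diff(1 / (1 + exp(-1 / e))) > 0))
})

test_that("simam attention preserves shape, scales constants by sigmoid(0.5)", {
  x <- array(3.7, c(6, 5, 4, 2))
  y <- simam_attention(x)
  expect_equal(dim(y), dim(x))
  expect_equal(y, x * (1 / (1 + exp(-0.5))), tolerance = 1e-12)
  # no learnable parameters in the network operator
  expect_equal(gmacorn:::gm_count(gmacorn:::nn_simam()), 0)
  # arbitrary input: shape preserved
  set.seed(2)
  z <- array(rnorm(7 * 9 * 3), c(7, 9, 3))
  expect_equal(dim(simam_attention(z)), dim(z))
  expect_warning(simam_attention(array(1, c(1, 1, 2, 1))), "single-pixel")
})

test_that("simam two-neuron weights match brute-force energy minimisation", {
  x <- array(c(0, 2), c(2, 1, 1, 1))
  w <- gmacorn:::simam_weights(x, 1e-4)
  e0 <- simam_energy_oracle(0, 2, 1e-4)
  e2 <- simam_energy_oracle(2, 0, 1e-4)
  expect_lt(abs(w[1] - 1 / (1 + exp(-1 / e0))), 1e-6)
  expect_lt(abs(w[2] - 1 / (1 + exp(-1 / e2))), 1e-6)
})

test_that("mlca gate preserves shape, stays in (0,1), uses two 1-D kernels", {
  set.seed(3)
  x <- array(rnorm(10 * 10 * 8), c(10, 10, 8, 1))
  sp <- mlca_spec(8)
  y <- mlca_attention(x, sp)
  expect_equal(dim(y), dim(x))
  gate <- attr(y, "gate")
  expect_true(all(gate > 0 & gate < 1))
  expect_lte(attr(y, "n_params"), 2L * sp$conv1d_kernel)
  expect_lte(attr(y, "n_params"), 6L)  # kernel 3 at 8 channels
  expect_error(mlca_attention(array(0, c(3, 3, 8, 1)), sp), "grid")
  expect_error(mlca_attention(x, mlca_spec(16)), "channels")
})
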