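test_that("config validation catches inconsistent architectures", {
  expect_error(arch_config("gma", input_size = 100), "divisible")
  expect_error(arch_config("gma", num_classes = 0), "num_classes")
  expect_error(arch_config("gma", stage_mid = c(8L, 8L)), "length 4")
  expect_error(arch_config("gma", stage_out = c(0L, 8L, 8L, 8L)),
               "positive")
})

test_that("prediction maps follow stride arithmetic and drop the aux head in deploy", {
  m <- build_model(tiny_gma_config())
  x <- array(runif(96 * 96 * 3), c(96, 96, 3, 1))
  out <- model_forward(m, x)
  expect_null(out$aux)                       # deploy: no aux outputs
  expect_equal(vapply(out$lead, function(s) dim(s)[1L], integer(1)),
               c(12L, 6L, 3L))               # 96 / {8, 16, 32}
  expect_equal(dim(out$lead[[1L]])[3L], 4L * 16L + 1L)
  out_aux <- model_forward(m, x, with_aux = TRUE)
  expect_length(out_aux$aux, 3L)
  # both variants accept identical input and emit identically shaped maps
  mb <- build_model(arch_config("baseline_v8n"))
  outb <- model_forward(mb, x)
  expect_equal(lapply(outb$lead, dim), lapply(out$lead, dim))
  # eval-mode forward is deterministic
  expect_identical(out$lead, model_forward(m, x)$lead)
})

test_that("full-size models reproduce the published complexity figures", {
  mb <- build_model(arch_config("baseline_v8n", num_classes = 1))
  mg <- build_model(arch_config("gma", num_classes = 1))
  pb <- count_parameters(mb, "deploy")
  pg <- count_parameters(mg, "deploy")
  expect_equal(round(pb / 1e6, 1), 3.0)
  expect_equal(round(pg / 1e6, 1), 2.3)
  expect_equal(round(estimate_flops(mb, 640), 1), 8.1)
  expect_equal(round(estimate_flops(mg, 640), 1), 6.8)
  # training graph adds the aux head parameters
  expect_gt(count_parameters(mg, "train"), pg)
  expect_gte(count_parameters(mb, "train"), pb)
})

test_that("FLOPs scale quadratically with resolution, params do not", {
  m <- build_model(tiny_gma_config())
  p0 <- count_parameters(m, "deploy")
  f320 <- estimate_flops(m, 320)
  f640 <- estimate_flops(m, 640)
  expect_lt(f320, f640)
  expect_lt(abs(f640 / f320 - 4) / 4, 0.05)
  # profiling at any resolution leaves the parameter count untouched
  expect_identical(count_parameters(m, "deploy"), p0)
})

test_that("CM blocks differ from plain C2f by the MLCA kernels only", {
  plain <- gmacorn:::nn_c2f(32L, 32L, n = 2L, mlca = FALSE)
  cm <- gmacorn:::nn_c2f(32L, 32L, n = 2L, mlca = TRUE)
  diff <- gmacorn:::gm_count(cm) - gmacorn:::gm_count(plain)
  expect_gt(diff, 0)
  expect_lte(diff, 40)  # a few 1-D kernels, tens of scalars at most
})

test_that("complexity report summarises the footprint and flags errors", {
  rep <- complexity_report(arch_config("gma", num_classes = 1))
  expect_equal(round(rep$parameter_count / 1e6, 1), 2.3)
  expect_equal(round(rep$gflops, 1), 6.8)
  expect_equal(rep$size_mb, rep$parameter_count * 2 / 2^20)
  expect_error(arch_config("gma", stage_out = c(16L, 32L, 64L, 0L)))
})

test_that("architecture configs round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(variant = "gma", num_classes = 1,
                        stem_channels = 8, stage_mid = c(8, 8, 8, 16),
                        stage_out = c(16, 16, 32, 64), hg_layers = 1),
                   path)
  cfg <- read_arch_config(path)
  expect_s3_class(cfg, "arch_config")
  expect_equal(cfg$stage_out, c(16L, 16L, 32L, 64L))
  m <- build_model(cfg)
  expect_equal(count_parameters(m, "deploy"),
               count_parameters(build_model(tiny_gma_config()), "deploy"))
})
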