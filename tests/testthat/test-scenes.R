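test_that("scene generation is seeded, one whorl box per plant", {
  cfg <- scene_config(size = 160, n_plants = 3)
  sc <- generate_scene(cfg, seed = 1)
  expect_equal(nrow(sc$boxes), 3L)
  expect_true(all(sc$boxes$cls == 0L))
  expect_equal(dim(sc$image), c(160L, 160L, 3L))
  expect_true(all(sc$image >= 0 & sc$image <= 1))
  # bit-identical regeneration
  sc2 <- generate_scene(cfg, seed = 1)
  expect_identical(sc$image, sc2$image)
  expect_identical(sc$boxes, sc2$boxes)
  # every annotation centre sits inside its plant's whorl disk
  d <- sqrt((sc$boxes$cx - sc$plants$x)^2 + (sc$boxes$cy - sc$plants$y)^2)
  expect_true(all(d <= sc$plants$r))
  expect_error(scene_config(size = 100, n_plants = 10, row_spacing_m = 0.25,
                            px_per_m = 200), "overcrowded")
})

test_that("labels honour the YOLO format contract", {
  cfg <- scene_config(size = 128, n_plants = 2)
  sc <- generate_scene(cfg, seed = 3)
  path <- tempfile(fileext = ".txt")
  write_yolo_labels(sc$boxes, path, cfg$size)
  lines <- readLines(path)
  expect_length(lines, 2L)
  fields <- strsplit(lines, " ")
  expect_true(all(lengths(fields) == 5L))
  vals <- vapply(fields, function(f) as.numeric(f[-1L]), numeric(4L))
  expect_true(all(vals >= 0 & vals <= 1))
  back <- read_yolo_labels(path, cfg$size)
  expect_equal(back$cx, sc$boxes$cx, tolerance = 1e-4)
  expect_equal(back$w, sc$boxes$w, tolerance = 1e-4)
})

test_that("identity augmentation is a no-op and brightness scales intensity", {
  cfg <- scene_config(size = 96, n_plants = 1)
  sc <- generate_scene(cfg, seed = 2)
  id <- augment_scene(sc$image, sc$boxes, augment_params())
  expect_identical(id$image, sc$image)
  expect_identical(id$boxes, sc$boxes)
  # +25% on a mid-gray image raises the mean by exactly 25% (no clipping)
  gray <- array(0.4, c(32, 32, 3))
  br <- augment_scene(gray, sc$boxes[0, ],
                      augment_params(brightness = 0.25))
  expect_equal(mean(br$image), 0.5)
  expect_error(augment_params(brightness = 0.3), "25")
})

test_that("a quarter rotation maps normalised centres as (cx,cy) -> (1-cy,cx)", {
  cfg <- scene_config(size = 100, n_plants = 1)
  sc <- generate_scene(cfg, seed = 4)
  rot <- augment_scene(sc$image, sc$boxes, augment_params(rotation = 90))
  expect_equal(rot$boxes$cx / 100, 1 - sc$boxes$cy / 100, tolerance = 1e-6)
  expect_equal(rot$boxes$cy / 100, sc$boxes$cx / 100, tolerance = 1e-6)
  # square boxes keep their extents under quarter turns
  expect_equal(rot$boxes$w, sc$boxes$h, tolerance = 1e-6)
  # a box pushed fully out of frame is dropped with a log message
  far <- data.frame(cls = 0L, cx = 98, cy = 2, w = 3, h = 3)
  expect_message(out <- augment_scene(sc$image, far,
                                      augment_params(rotation = 45)),
                 "dropped")
})

test_that("motion blur preserves shape and annotations", {
  cfg <- scene_config(size = 64, n_plants = 1)
  sc <- generate_scene(cfg, seed = 6)
  bl <- augment_scene(sc$image, sc$boxes,
                      augment_params(blur_len = 5, blur_angle = 30))
  expect_equal(dim(bl$image), dim(sc$image))
  expect_identical(bl$boxes, sc$boxes)
  expect_false(identical(bl$image, sc$image))
})

test_that("dataset generation applies the augmentation multiplicity", {
  cfg <- scene_config(size = 64, n_plants = 1)
  out_dir <- tempfile()
  ds <- generate_dataset(cfg, n = 2, seed = 1, multiplicity = 3,
                         out_dir = out_dir)
  expect_length(ds, 2L * (1L + 3L))
  expect_length(list.files(file.path(out_dir, "images")), 8L)
  expect_length(list.files(file.path(out_dir, "labels")), 8L)
  expect_true(file.exists(file.path(out_dir, "manifest.yaml")))
})

test_that("detection streams move plants linearly and honour dropouts", {
  cfg <- scene_config(size = 160, n_plants = 1)
  st <- generate_detection_stream(cfg, speed_px = 3, frames = 120, seed = 1)
  # the plant centre crosses a fixed band in one contiguous frame interval
  inside <- vapply(st, function(fr)
    nrow(fr$boxes) > 0 && any(fr$boxes$x >= 70 & fr$boxes$x <= 90),
    logical(1))
  runs <- rle(inside)
  expect_equal(sum(runs$values), 1L)
  # dropout 1 silences the stream
  st0 <- generate_detection_stream(cfg, frames = 30, seed = 1,
                                   noise = list(center_sd = 0, dropout = 1))
  expect_true(all(vapply(st0, function(fr) nrow(fr$boxes) == 0L,
                         logical(1))))
  # JSON-lines round trip
  path <- tempfile(fileext = ".jsonl")
  write_detection_stream(st, path)
  back <- read_detection_stream(path)
  expect_length(back, length(st))
  nonempty <- which(vapply(st, function(fr) nrow(fr$boxes) > 0, logical(1)))
  i <- nonempty[1L]
  expect_equal(back[[i]]$boxes$x, st[[i]]$boxes$x, tolerance = 1e-9)
})

test_that("zero-noise stream triggers exactly one packet per plant", {
  cfg <- scene_config(size = 160, n_plants = 3)
  st <- generate_detection_stream(cfg, speed_px = 3, frames = 200, seed = 4)
  log <- run_asds(st, decision_region(76, 0, 84, 160))
  expect_equal(nrow(log), 3L)
})
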