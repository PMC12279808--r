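test_that("precision and recall follow the confusion counts", {
  expect_equal(precision_recall(confusion_counts(10, 0, 0)),
               c(precision = 1, recall = 1))
  expect_warning(pr <- precision_recall(confusion_counts(0, 0, 5)),
                 "precision")
  expect_equal(unname(pr), c(0, 0))
  expect_equal(precision_recall(confusion_counts(3, 1, 2)),
               c(precision = 0.75, recall = 0.6))
  pr0 <- suppressWarnings(precision_recall(confusion_counts(0, 5, 5)))
  expect_equal(unname(pr0), c(0, 0))
  expect_error(confusion_counts(-1, 0, 0), ">= 0")
})

test_that("average precision integrates the interpolated PR curve", {
  gts <- data.frame(cx = c(10, 30), cy = c(10, 30), w = c(6, 6),
                    h = c(6, 6))
  # ranked [TP, FP, TP] over 2 ground truths -> AP = 5/6
  dets <- data.frame(cx = c(10, 50, 30), cy = c(10, 50, 30),
                     w = 6, h = 6, conf = c(0.9, 0.8, 0.7))
  expect_equal(average_precision(dets, gts), 5 / 6)
  # perfect ranking covering all ground truths
  perfect <- data.frame(cx = c(10, 30), cy = c(10, 30), w = 6, h = 6,
                        conf = c(0.9, 0.8))
  expect_equal(average_precision(perfect, gts), 1)
  # uniform confidence rescaling leaves AP unchanged
  dets2 <- dets; dets2$conf <- dets2$conf * 0.31
  expect_equal(average_precision(dets2, gts), average_precision(dets, gts))
  # equal-confidence ties use the deterministic index tie-break
  ties <- dets; ties$conf <- 0.5
  expect_equal(average_precision(ties, gts),
               average_precision(ties, gts))
  expect_error(average_precision(dets, gts[0, ]), "undefined")
})

test_that("average precision agrees with a threshold-enumeration oracle", {
  set.seed(14)
  for (i in 1:100) {
    n_gt <- sample(1:5, 1)
    gts <- data.frame(cx = runif(n_gt, 10, 90), cy = runif(n_gt, 10, 90),
                      w = runif(n_gt, 5, 15), h = runif(n_gt, 5, 15))
    nd <- sample(1:10, 1)
    pick <- sample(n_gt, nd, replace = TRUE)
    dets <- data.frame(cx = gts$cx[pick] + rnorm(nd, 0, 4),
                       cy = gts$cy[pick] + rnorm(nd, 0, 4),
                       w = gts$w[pick] * runif(nd, 0.7, 1.3),
                       h = gts$h[pick] * runif(nd, 0.7, 1.3),
                       conf = runif(nd))
    ap <- average_precision(dets, gts)
    expect_lt(abs(ap - ap_oracle(dets, gts)), 1e-9)
    expect_gte(ap, 0); expect_lte(ap, 1)
  }
})

test_that("mAP@0.5 averages class APs", {
  expect_equal(map50(0.73), 0.73)          # single class, the study setting
  expect_equal(map50(c(1, 0)), 0.5)
  set.seed(15)
  aps <- runif(5)
  expect_equal(map50(aps), sum(aps) / 5)
  expect_error(map50(numeric(0)), "classes")
})

test_that("field metrics reproduce the published trial table", {
  expect_equal(unname(delivery_metrics(field_trial_counts(45, 42, 40))),
               c(88.9, 93.3, 95.2))
  expect_equal(unname(delivery_metrics(field_trial_counts(445, 406, 374))),
               c(84.0, 91.2, 92.1))
  expect_equal(unname(delivery_metrics(field_trial_counts(50, 50, 50))),
               c(100.0, 100.0, 100.0))
  expect_error(field_trial_counts(50, 40, 45), "n_success")
  expect_error(delivery_metrics(field_trial_counts(5, 0, 0)), "undefined")
})

test_that("group summary matches the published mean +/- sample SD", {
  s <- summarize_trials(field_groups())
  expect_equal(unname(s$mean),
               c(84.1, 91.3, 92.2))
  expect_equal(unname(s$sd), c(3.3, 1.9, 2.9))
  expect_true(all(s$mean >= apply(s$per_group, 2, min) &
                    s$mean <= apply(s$per_group, 2, max)))
  # identical groups have zero spread
  same <- replicate(3, field_trial_counts(50, 45, 40), simplify = FALSE)
  expect_equal(unname(summarize_trials(same)$sd), c(0, 0, 0))
  expect_error(summarize_trials(field_groups()[1]), "2 groups")
})

test_that("the delivery identity holds exactly for any counts", {
  set.seed(16)
  for (i in 1:50) {
    nt <- sample(5:500, 1)
    ni <- sample(1:nt, 1)
    ns <- sample(0:ni, 1)
    m <- delivery_metrics(field_trial_counts(nt, ni, ns), digits = NULL)
    expect_equal(m[["delivery_rate"]],
                 m[["detection_accuracy"]] * m[["delivery_precision"]] / 100)
  }
})

test_that("field counts round-trip through CSV", {
  path <- tempfile(fileext = ".csv")
  df <- data.frame(group = 1:3, n_total = c(45, 50, 50),
                   n_identified = c(42, 45, 46), n_success = c(40, 43, 42))
  utils::write.csv(df, path, row.names = FALSE)
  groups <- read_field_counts(path)
  expect_length(groups, 3L)
  expect_equal(unname(delivery_metrics(groups[[1]])), c(88.9, 93.3, 95.2))
})
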