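test_that("iou handles the canonical geometries", {
  expect_equal(iou(c(5, 5, 4, 4), c(5, 5, 4, 4)), 1)
  expect_equal(iou(c(0, 0, 2, 2), c(10, 10, 2, 2)), 0)
  # unit squares offset by half a side: inter 0.5, union 1.5
  expect_equal(iou(c(0.5, 0.5, 1, 1), c(1.0, 0.5, 1, 1)), 1 / 3)
  # corner format agrees with the centre format on the same geometry
  expect_equal(iou(c(0, 0, 1, 1), c(0.5, 0, 1.5, 1), format = "xyxy"),
               iou(c(0.5, 0.5, 1, 1), c(1.0, 0.5, 1, 1)))
  expect_error(iou(c(0, 0, 0, 1), c(0, 0, 1, 1)), "zero-area")
})

test_that("simota assigns dynamic-k lowest-cost candidates uniquely", {
  # forced match
  r <- simota_assign(matrix(0.3, 1, 1), matrix(0.9, 1, 1))
  expect_true(r$positive)
  expect_equal(r$matched, 1L)
  # shared best candidate goes to the cheaper ground truth only
  costs <- rbind(c(0.1, 5, 5), c(0.2, 5, 5))
  ious <- rbind(c(0.9, 0.01, 0.01), c(0.8, 0.01, 0.01))
  r <- simota_assign(costs, ious)
  expect_equal(r$matched[1L], 1L)
  expect_lte(sum(r$positive), 3L)
  # empty input
  r0 <- simota_assign(matrix(numeric(0), 0, 0), matrix(numeric(0), 0, 0))
  expect_length(r0$matched, 0L)
})

test_that("simota matches an exhaustive minimum-cost oracle on a fixed instance", {
  nG <- 3L; nC <- 8L
  # fixed 3 x 8 instance; the IoU row sums fix dynamic k at (2, 1, 3)
  ious <- rbind(c(0.9, 0.8, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0),
                c(0.0, 0.0, 0.6, 0.3, 0.0, 0.0, 0.0, 0.0),
                c(0.0, 0.0, 0.0, 0.0, 0.9, 0.9, 0.8, 0.3))
  costs <- rbind(c(0.2, 0.4, 3.0, 3.1, 3.2, 3.3, 3.4, 3.5),
                 c(3.0, 3.1, 0.5, 1.4, 3.2, 3.3, 3.4, 3.5),
                 c(3.0, 3.1, 3.2, 3.3, 0.3, 0.4, 0.6, 2.5))
  r <- simota_assign(costs, ious, topq = 10L)
  k <- pmin(pmax(1L, as.integer(round(rowSums(ious)))), nC)
  expect_equal(k, c(2L, 1L, 3L))
  # exhaustive search over all candidate -> {none, g} maps with the same k
  states <- as.matrix(expand.grid(rep(list(0:nG), nC)))
  feasible <- apply(states, 1L, function(s)
    all(vapply(seq_len(nG), function(g) sum(s == g), integer(1)) == k))
  best <- NULL; bestc <- Inf
  for (i in which(feasible)) {
    s <- states[i, ]
    cost <- sum(costs[cbind(s[s > 0], which(s > 0))])
    if (cost < bestc) { bestc <- cost; best <- s }
  }
  expect_equal(unname(ifelse(is.na(r$matched), 0L, r$matched)),
               unname(best))
})

test_that("simota never double-assigns and bounds total positives", {
  set.seed(21)
  for (i in 1:20) {
    nG <- sample(1:4, 1); nC <- sample(2:10, 1)
    ious <- matrix(runif(nG * nC), nG, nC)
    costs <- matrix(runif(nG * nC, 0, 4), nG, nC)
    r <- simota_assign(costs, ious)
    expect_lte(sum(r$positive), nC)
    expect_true(all(table(r$matched[!is.na(r$matched)]) <= nC))
    expect_equal(sum(r$positive), sum(!is.na(r$matched)))
  }
})

test_that("lead assignment is local and handles the empty case", {
  preds <- make_toy_predictions(5)
  # single centred ground truth: positives lie in cells containing it
  gt <- data.frame(cls = 0L, cx = 32, cy = 32, w = 20, h = 20)
  asn <- assign_lead(gt, preds)
  expect_true(any(asn$positive))
  pos <- which(asn$positive)
  a <- asn$flat$anchors
  s <- c(8, 16, 32)[a$scale]
  ax <- a$x * s; ay <- a$y * s
  expect_true(all(abs(ax[pos] - 32) <= 10 & abs(ay[pos] - 32) <= 10))
  # no ground truth: everything background
  asn0 <- assign_lead(NULL, preds)
  expect_false(any(asn0$positive))
  expect_true(all(asn0$target_scores == 0))
  # deterministic
  expect_identical(assign_lead(gt, preds)$matched, asn$matched)
})

test_that("lead assignment equals an independent re-ranking oracle", {
  preds <- make_toy_predictions(6)
  gt <- make_toy_gts(6, n = 1L)
  asn <- assign_lead(gt, preds, alpha = 0.5, beta = 6, topk = 10L)
  # independent implementation of the ranking rule for one ground truth
  flat <- gmacorn:::flatten_predictions(preds, nc = 1L)
  dec <- gmacorn:::decode_boxes(flat)
  g <- c(gt$cx - gt$w / 2, gt$cy - gt$h / 2, gt$cx + gt$w / 2,
         gt$cy + gt$h / 2)
  ious <- sapply(seq_len(nrow(dec$xyxy)), function(i) {
    a <- dec$xyxy[i, ]
    iw <- max(0, min(a[3], g[3]) - max(a[1], g[1]))
    ih <- max(0, min(a[4], g[4]) - max(a[2], g[2]))
    inter <- iw * ih
    inter / max((a[3] - a[1]) * (a[4] - a[2]) +
                  (g[3] - g[1]) * (g[4] - g[2]) - inter, 1e-12)
  })
  score <- 1 / (1 + exp(-flat$cls[, 1L]))
  metric <- sqrt(score) * ious^6
  inside <- dec$ax >= g[1] & dec$ax <= g[3] & dec$ay >= g[2] & dec$ay <= g[4]
  cand <- which(inside)
  expected <- cand[order(metric[cand], decreasing = TRUE)][1:min(10, length(cand))]
  expect_setequal(which(asn$positive), expected)
})

test_that("aux positives are a superset of lead positives on random scenes", {
  for (i in 1:100) {
    preds <- make_toy_predictions(i)
    gts <- make_toy_gts(i, n = sample(1:3, 1))
    lead <- assign_lead(gts, preds)
    aux <- assign_aux(gts, preds)
    expect_true(all(which(lead$positive) %in% which(aux$positive)))
    expect_gte(sum(aux$positive), sum(lead$positive))
  }
  # empty case
  expect_false(any(assign_aux(NULL, make_toy_predictions(1))$positive))
})

test_that("border ground truths only claim anchors inside the frame", {
  preds <- make_toy_predictions(9)
  gt <- data.frame(cls = 0L, cx = 2, cy = 2, w = 30, h = 30)
  asn <- assign_aux(gt, preds)
  a <- asn$flat$anchors
  s <- c(8, 16, 32)[a$scale]
  expect_true(all(a$x[asn$positive] * s[asn$positive] <= 64))
  expect_true(all(a$y[asn$positive] * s[asn$positive] >= 0))
})
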