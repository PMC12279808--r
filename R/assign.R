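# Training-time label assignment for the anchor-free heads.
#
# The lead head uses a task-aligned assigner (alignment metric
# score^alpha * IoU^beta, top-k candidates restricted to anchors whose
# cell centre lies inside the ground-truth box). The auxiliary head reuses
# the lead positives and relaxes the constraints (candidate region doubled
# about the box centre, top-k doubled), so its positive set is a superset
# of the lead set by construction. SimOTA is available as an alternative
# assigner on an explicit cost matrix.

#' Intersection over union of two boxes
#'
#' @param boxA,boxB Length-4 numeric vectors. `format = "cxcywh"`
#'   (centre/size, the annotation convention) or `"xyxy"` (corners).
#' @param format Box coordinate convention.
#' @return IoU in \\[0, 1\\].
#' @export
iou <- function(boxA, boxB, format = c("cxcywh", "xyxy")) {
  format <- match.arg(format)
  if (format == "cxcywh") {
    boxA <- cxcywh_to_xyxy(boxA)
    boxB <- cxcywh_to_xyxy(boxB)
  }
  if (boxA[3L] <= boxA[1L] || boxA[4L] <= boxA[2L] ||
      boxB[3L] <= boxB[1L] || boxB[4L] <= boxB[2L])
    stop("zero-area box", call. = FALSE)
  iw <- max(0, min(boxA[3L], boxB[3L]) - max(boxA[1L], boxB[1L]))
  ih <- max(0, min(boxA[4L], boxB[4L]) - max(boxA[2L], boxB[2L]))
  inter <- iw * ih
  areaA <- (boxA[3L] - boxA[1L]) * (boxA[4L] - boxA[2L])
  areaB <- (boxB[3L] - boxB[1L]) * (boxB[4L] - boxB[2L])
  inter / (areaA + areaB - inter)
}

cxcywh_to_xyxy <- function(b) {
  if (is.matrix(b))
    cbind(b[, 1L] - b[, 3L] / 2, b[, 2L] - b[, 4L] / 2,
          b[, 1L] + b[, 3L] / 2, b[, 2L] + b[, 4L] / 2)
  else
    c(b[1L] - b[3L] / 2, b[2L] - b[4L] / 2,
      b[1L] + b[3L] / 2, b[2L] + b[4L] / 2)
}

# IoU between rows of two xyxy matrices -> (nrow(a) x nrow(b)) matrix.
iou_matrix <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  out <- matrix(0, na, nb)
  for (j in seq_len(nb)) {
    iw <- pmax(0, pmin(a[, 3L], b[j, 3L]) - pmax(a[, 1L], b[j, 1L]))
    ih <- pmax(0, pmin(a[, 4L], b[j, 4L]) - pmax(a[, 2L], b[j, 2L]))
    inter <- iw * ih
    areaA <- (a[, 3L] - a[, 1L]) * (a[, 4L] - a[, 2L])
    areaB <- (b[j, 3L] - b[j, 1L]) * (b[j, 4L] - b[j, 2L])
    out[, j] <- inter / pmax(areaA + areaB - inter, 1e-12)
  }
  out
}

#' Anchor points of the three detection scales
#'
#' Cell centres `(i + 0.5) * stride` for strides 8, 16 and 32 at a given
#' input size, in the flattening order used by the prediction maps.
#'
#' @param input_size Square input side, divisible by 32.
#' @param strides Integer strides.
#' @return Data frame with columns `x`, `y`, `stride`.
#' @export
make_anchors <- function(input_size, strides = c(8L, 16L, 32L)) {
  out <- lapply(strides, function(s) {
    n <- input_size %/% s
    hw <- expand.grid(h = seq_len(n) - 1L, w = seq_len(n) - 1L)
    data.frame(x = (hw$w + 0.5) * s, y = (hw$h + 0.5) * s, stride = s)
  })
  do.call(rbind, out)
}

# Flatten per-scale prediction maps (single image) into anchor-major
# matrices of box-distribution and class logits.
flatten_predictions <- function(maps, reg_max = 16L, nc = 1L) {
  boxl <- list(); clsl <- list(); anch <- list()
  for (i in seq_along(maps)) {
    m <- as_map(maps[[i]])
    d <- dim(m)
    H <- d[1L]; W <- d[2L]
    stride <- NA_integer_
    nAs <- H * W
    bm <- matrix(m[, , seq_len(4L * reg_max), 1L], nrow = nAs)
    cm <- matrix(m[, , 4L * reg_max + seq_len(nc), 1L], nrow = nAs)
    boxl[[i]] <- bm
    clsl[[i]] <- cm
    anch[[i]] <- data.frame(
      x = rep((seq_len(W) - 0.5), each = H),
      y = rep(seq_len(H) - 0.5, times = W),
      scale = i, H = H, W = W)
  }
  list(box = do.call(rbind, boxl), cls = do.call(rbind, clsl),
       anchors = do.call(rbind, anch))
}

softmax_rows <- function(m) {
  m <- exp(m - apply(m, 1L, max))
  m / rowSums(m)
}

# Decode distribution logits to boxes. Returns xyxy (pixels), the per-side
# distances (stride units) and the softmax probabilities for the backward
# pass.
decode_boxes <- function(flat, strides = c(8L, 16L, 32L), reg_max = 16L) {
  a <- flat$anchors
  s <- strides[a$scale]
  ax <- a$x * s
  ay <- a$y * s
  nA <- nrow(flat$box)
  dist <- matrix(0, nA, 4L)
  probs <- vector("list", 4L)
  bins <- seq_len(reg_max) - 1L
  for (j in seq_len(4L)) {
    p <- softmax_rows(flat$box[, (j - 1L) * reg_max + seq_len(reg_max),
                               drop = FALSE])
    probs[[j]] <- p
    dist[, j] <- as.numeric(p %*% bins)
  }
  xyxy <- cbind(ax - dist[, 1L] * s, ay - dist[, 2L] * s,
                ax + dist[, 3L] * s, ay + dist[, 4L] * s)
  list(xyxy = xyxy, dist = dist, probs = probs, ax = ax, ay = ay, s = s)
}

# Shared task-aligned selection. Returns positives for one image.
tal_select <- function(gt_xyxy, in_box, align, topk) {
  nG <- nrow(gt_xyxy)
  nA <- ncol(align)
  pos <- matrix(FALSE, nG, nA)
  for (g in seq_len(nG)) {
    cand <- which(in_box[g, ])
    if (!length(cand)) next
    k <- min(topk, length(cand))
    sel <- cand[order(align[g, cand], decreasing = TRUE)[seq_len(k)]]
    pos[g, sel] <- TRUE
  }
  pos
}

centre_in_box <- function(ax, ay, gt_xyxy, expand = 1) {
  nG <- nrow(gt_xyxy)
  out <- matrix(FALSE, nG, length(ax))
  for (g in seq_len(nG)) {
    cx <- (gt_xyxy[g, 1L] + gt_xyxy[g, 3L]) / 2
    cy <- (gt_xyxy[g, 2L] + gt_xyxy[g, 4L]) / 2
    hw <- (gt_xyxy[g, 3L] - gt_xyxy[g, 1L]) / 2 * expand
    hh <- (gt_xyxy[g, 4L] - gt_xyxy[g, 2L]) / 2 * expand
    out[g, ] <- ax >= cx - hw & ax <= cx + hw & ay >= cy - hh & ay <= cy + hh
  }
  out
}

resolve_and_score <- function(pos, align, ious, gts) {
  nA <- ncol(pos)
  nG <- nrow(pos)
  matched <- rep(NA_integer_, nA)
  claimed <- which(colSums(pos) > 0L)
  for (a in claimed) {
    gs <- which(pos[, a])
    matched[a] <- gs[which.max(align[gs, a])]
  }
  target_scores <- numeric(nA)
  target_boxes <- matrix(NA_real_, nA, 4L)
  for (g in seq_len(nG)) {
    mine <- which(matched == g)
    if (!length(mine)) next
    amax <- max(align[g, mine])
    imax <- max(ious[g, mine])
    target_scores[mine] <- align[g, mine] / max(amax, 1e-9) * imax
    target_boxes[mine, ] <- matrix(gts$xyxy[g, ], length(mine), 4L,
                                   byrow = TRUE)
  }
  list(matched = matched, positive = !is.na(matched),
       target_scores = target_scores, target_boxes = target_boxes)
}

assign_core <- function(gts, predictions, nc, alpha, beta, topk, expand,
                        reg_max = 16L) {
  flat <- flatten_predictions(predictions, reg_max = reg_max, nc = nc)
  dec <- decode_boxes(flat, reg_max = reg_max)
  nA <- nrow(dec$xyxy)
  empty <- list(matched = rep(NA_integer_, nA),
                positive = rep(FALSE, nA),
                target_scores = numeric(nA),
                target_boxes = matrix(NA_real_, nA, 4L),
                flat = flat, decoded = dec, gts = NULL,
                align = NULL, ious = NULL)
  if (is.null(gts) || nrow(gts) == 0L) return(empty)
  gxy <- cxcywh_to_xyxy(as.matrix(gts[, c("cx", "cy", "w", "h")]))
  ious <- t(iou_matrix(dec$xyxy, gxy))          # nG x nA
  score <- t(sigmoid_(flat$cls[, gts$cls + 1L, drop = FALSE]))
  align <- score^alpha * ious^beta
  in_box <- centre_in_box(dec$ax, dec$ay, gxy, expand = expand)
  pos <- tal_select(gxy, in_box, align, topk)
  res <- resolve_and_score(pos, align, ious, list(xyxy = gxy))
  c(res, list(flat = flat, decoded = dec,
              gts = cbind(gts, gxy), align = align, ious = ious))
}

#' Fine-grained label assignment for the lead head
#'
#' Task-aligned assignment: candidates are anchors whose centre lies in the
#' ground-truth box, ranked by `score^alpha * IoU^beta`, top `topk` kept
#' per ground truth; an anchor claimed by several ground truths keeps the
#' highest-alignment match. Soft target scores are the alignment metric
#' normalised per ground truth to its best IoU.
#'
#' @param gts Data frame with columns `cls`, `cx`, `cy`, `w`, `h` (pixels);
#'   `NULL` or zero rows yields an all-negative assignment.
#' @param predictions List of three per-scale prediction maps for one image
#'   (as returned in `model_forward()$lead`).
#' @param nc Number of classes.
#' @param alpha,beta,topk Task-alignment hyper-parameters.
#' @return Assignment list: `matched` (ground-truth index per anchor or
#'   `NA`), `positive`, `target_scores`, `target_boxes` (xyxy) plus the
#'   flattened/decoded predictions used.
#' @export
assign_lead <- function(gts, predictions, nc = 1L, alpha = 0.5, beta = 6,
                        topk = 10L) {
  assign_core(gts, predictions, nc, alpha, beta, topk, expand = 1)
}

#' Coarse label assignment for the auxiliary head
#'
#' Same procedure as [assign_lead()] with a relaxed positive region (the
#' candidate window is the ground-truth box scaled by `expand` about its
#' centre) and doubled top-k; the extra positives are added to the lead
#' positives, so the auxiliary positive set is a superset of the lead set
#' on identical inputs.
#'
#' @inheritParams assign_lead
#' @param expand Scale factor of the candidate region; default 2.
#' @return Assignment list as in [assign_lead()].
#' @export
assign_aux <- function(gts, predictions, nc = 1L, alpha = 0.5, beta = 6,
                       topk = 10L, expand = 2) {
  lead <- assign_lead(gts, predictions, nc, alpha, beta, topk)
  aux <- assign_core(gts, predictions, nc, alpha, beta, 2L * topk,
                     expand = expand)
  if (is.null(aux$gts)) return(aux)
  take_lead <- lead$positive & !aux$positive
  aux$matched[take_lead] <- lead$matched[take_lead]
  aux$positive <- aux$positive | lead$positive
  aux$target_scores[take_lead] <- lead$target_scores[take_lead]
  aux$target_boxes[take_lead, ] <- lead$target_boxes[take_lead, ,
                                                     drop = FALSE]
  aux
}

#' SimOTA assignment on an explicit cost matrix
#'
#' Dynamic-k label assignment: for every ground truth,
#' `k = clamp(round(sum of top-q IoUs), 1, n_candidates)` lowest-cost
#' candidates are selected; a candidate claimed by several ground truths
#' keeps only its lowest-cost match.
#'
#' @param costs Matrix (ground truths x candidates) of non-negative costs,
#'   typically classification cost + `lambda * (1 - IoU)`.
#' @param ious Matrix of the same shape with pairwise IoUs.
#' @param topq Number of top IoUs summed to derive the dynamic k.
#' @return List with `matched` (ground-truth index per candidate or `NA`)
#'   and `positive` (logical per candidate).
#' @export
simota_assign <- function(costs, ious, topq = 10L) {
  if (is.null(costs) || length(costs) == 0L)
    return(list(matched = integer(0), positive = logical(0)))
  stopifnot(all(dim(costs) == dim(ious)), all(costs >= 0))
  nG <- nrow(costs); nC <- ncol(costs)
  pos <- matrix(FALSE, nG, nC)
  for (g in seq_len(nG)) {
    q <- min(topq, nC)
    dyn_k <- sum(sort(ious[g, ], decreasing = TRUE)[seq_len(q)])
    k <- min(max(1L, as.integer(round(dyn_k))), nC)
    sel <- order(costs[g, ])[seq_len(k)]
    pos[g, sel] <- TRUE
  }
  matched <- rep(NA_integer_, nC)
  for (a in which(colSums(pos) > 0L)) {
    gs <- which(pos[, a])
    matched[a] <- gs[which.min(costs[gs, a])]
  }
  list(matched = matched, positive = !is.na(matched))
}
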