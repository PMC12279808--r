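# Detection loss (BCE classification + complete-IoU box loss +
# distribution-focal loss) and a smoke-scale SGD training loop.
#
# The box distribution decode is differentiated analytically through the
# softmax expectation; the complete-IoU term is differentiated with
# central finite differences over the four box coordinates of the few
# positive anchors (cheap, O(positives) extra IoU evaluations).

#' Training hyper-parameter configuration
#'
#' Mirrors the usual single-stage detector recipe: SGD with momentum and
#' a linear learning-rate schedule.
#'
#' @param lr0 Initial learning rate.
#' @param lrf Final learning-rate fraction (of `lr0`).
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay.
#' @param warmup_epochs Warm-up length (fraction of total steps in the
#'   smoke loop).
#' @param epochs Nominal number of epochs (used only for the schedule).
#' @param imgsz Training image size.
#' @param iou IoU threshold used during training-time matching.
#' @param batch_size Images per optimisation step.
#' @param aux_weight Weight of the auxiliary-head loss.
#' @return List of class `train_config`.
#' @export
train_config <- function(lr0 = 0.01, lrf = 0.01, momentum = 0.937,
                         weight_decay = 5e-4, warmup_epochs = 3,
                         epochs = 300, imgsz = 640, iou = 0.7,
                         batch_size = 4L, aux_weight = 0.25) {
  structure(list(lr0 = lr0, lrf = lrf, momentum = momentum,
                 weight_decay = weight_decay, warmup_epochs = warmup_epochs,
                 epochs = epochs, imgsz = imgsz, iou = iou,
                 batch_size = as.integer(batch_size),
                 aux_weight = aux_weight),
            class = "train_config")
}

#' Read a training configuration from YAML
#'
#' @param path Path to a YAML file with keys matching [train_config()].
#' @return A `train_config` object.
#' @export
read_train_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(train_config)))]
  do.call(train_config, args)
}

bce_with_logits <- function(logits, targets) {
  pmax(logits, 0) - logits * targets + log1p(exp(-abs(logits)))
}

ciou_vec <- function(p, g) {
  iw <- pmax(0, pmin(p[, 3L], g[, 3L]) - pmax(p[, 1L], g[, 1L]))
  ih <- pmax(0, pmin(p[, 4L], g[, 4L]) - pmax(p[, 2L], g[, 2L]))
  inter <- iw * ih
  ap <- pmax(p[, 3L] - p[, 1L], 1e-9) * pmax(p[, 4L] - p[, 2L], 1e-9)
  ag <- (g[, 3L] - g[, 1L]) * (g[, 4L] - g[, 2L])
  iouv <- inter / pmax(ap + ag - inter, 1e-9)
  # enclosing box diagonal and centre distance
  cw <- pmax(p[, 3L], g[, 3L]) - pmin(p[, 1L], g[, 1L])
  chh <- pmax(p[, 4L], g[, 4L]) - pmin(p[, 2L], g[, 2L])
  c2 <- cw^2 + chh^2 + 1e-9
  rho2 <- ((p[, 1L] + p[, 3L]) - (g[, 1L] + g[, 3L]))^2 / 4 +
    ((p[, 2L] + p[, 4L]) - (g[, 2L] + g[, 4L]))^2 / 4
  wp <- pmax(p[, 3L] - p[, 1L], 1e-9); hp <- pmax(p[, 4L] - p[, 2L], 1e-9)
  wg <- g[, 3L] - g[, 1L]; hg <- g[, 4L] - g[, 2L]
  v <- 4 / pi^2 * (atan(wg / hg) - atan(wp / hp))^2
  alpha <- v / pmax(1 - iouv + v, 1e-9)
  iouv - rho2 / c2 - alpha * v
}

# Loss and flattened gradient for one image and one head.
# Returns loss components and a (nA x (4*reg_max + nc)) gradient matrix.
head_loss <- function(asn, nc, reg_max = 16L,
                      gains = c(box = 7.5, cls = 0.5, dfl = 1.5)) {
  flat <- asn$flat
  dec <- asn$decoded
  nA <- nrow(flat$cls)
  tgt_cls <- matrix(0, nA, nc)
  pos <- which(asn$positive)
  if (length(pos)) {
    gcls <- asn$gts$cls[asn$matched[pos]] + 1L
    tgt_cls[cbind(pos, gcls)] <- asn$target_scores[pos]
  }
  norm <- max(sum(tgt_cls), 1)
  loss_cls <- sum(bce_with_logits(flat$cls, tgt_cls)) / norm
  dcls <- (sigmoid_(flat$cls) - tgt_cls) / norm
  dbox <- matrix(0, nA, 4L * reg_max)
  loss_box <- 0; loss_dfl <- 0
  if (length(pos)) {
    w <- asn$target_scores[pos]
    sw <- max(sum(w), 1e-9)
    pxy <- dec$xyxy[pos, , drop = FALSE]
    gxy <- asn$target_boxes[pos, , drop = FALSE]
    ci <- ciou_vec(pxy, gxy)
    loss_box <- sum(w * (1 - ci)) / sw
    # d(1 - ciou)/d coordinate by central differences
    h <- 1e-3
    dcoord <- matrix(0, length(pos), 4L)
    for (j in seq_len(4L)) {
      pp <- pxy; pp[, j] <- pp[, j] + h
      pm <- pxy; pm[, j] <- pm[, j] - h
      dcoord[, j] <- -(ciou_vec(pp, gxy) - ciou_vec(pm, gxy)) / (2 * h)
    }
    # coordinate -> side distance: x1 = ax - l s, y1 = ay - t s,
    # x2 = ax + r s, y2 = ay + b s
    s <- dec$s[pos]
    ddist_box <- cbind(-dcoord[, 1L] * s, -dcoord[, 2L] * s,
                       dcoord[, 3L] * s, dcoord[, 4L] * s) * (w / sw)
    # distribution-focal loss on the distances in stride units
    gdist <- cbind((dec$ax[pos] - gxy[, 1L]) / s,
                   (dec$ay[pos] - gxy[, 2L]) / s,
                   (gxy[, 3L] - dec$ax[pos]) / s,
                   (gxy[, 4L] - dec$ay[pos]) / s)
    gdist <- pmin(pmax(gdist, 0), reg_max - 1 - 1e-3)
    bins <- seq_len(reg_max) - 1L
    for (j in seq_len(4L)) {
      p <- dec$probs[[j]][pos, , drop = FALSE]
      t <- gdist[, j]
      tl <- floor(t); wl <- tl + 1 - t; wu <- t - tl
      q <- matrix(0, length(pos), reg_max)
      q[cbind(seq_along(t), tl + 1L)] <- wl
      q[cbind(seq_along(t), pmin(tl + 2L, reg_max))] <-
        q[cbind(seq_along(t), pmin(tl + 2L, reg_max))] + wu
      loss_dfl <- loss_dfl +
        sum(w * (-rowSums(q * log(pmax(p, 1e-12))))) / sw
      # combined gradient through the softmax for this side:
      # expectation path: ddist * p * (bins - dist); CE path: p - q
      ddist <- ddist_box[, j] * gains[["box"]]
      gsoft <- p * (outer(rep(1, length(pos)), bins) -
                      matrix(dec$dist[pos, j], length(pos), reg_max)) * ddist
      gce <- (p - q) * (w / sw) * gains[["dfl"]]
      dbox[pos, (j - 1L) * reg_max + seq_len(reg_max)] <-
        dbox[pos, (j - 1L) * reg_max + seq_len(reg_max), drop = FALSE] +
        gsoft + gce
    }
  }
  total <- gains[["box"]] * loss_box + gains[["cls"]] * loss_cls +
    gains[["dfl"]] * loss_dfl
  grad <- cbind(dbox, gains[["cls"]] * dcls)
  list(loss = total, box = loss_box, cls = loss_cls, dfl = loss_dfl,
       grad = grad)
}

# Reshape a flattened (nA x C) gradient back into per-scale map gradients.
unflatten_grad <- function(grad, anchors, nchan) {
  scales <- sort(unique(anchors$scale))
  out <- vector("list", length(scales))
  at <- 0L
  for (i in seq_along(scales)) {
    sub <- anchors[anchors$scale == scales[i], ]
    H <- sub$H[1L]; W <- sub$W[1L]
    n <- H * W
    out[[i]] <- array(grad[at + seq_len(n), ], c(H, W, nchan, 1L))
    at <- at + n
  }
  out
}

slice_maps <- function(maps, n) {
  lapply(maps, function(m) m[, , , n, drop = FALSE])
}

#' Smoke-scale detector training
#'
#' Runs a few SGD steps on an in-memory synthetic dataset, with
#' task-aligned assignment for the lead head and the relaxed coarse
#' assignment for the auxiliary head (total loss = lead + `aux_weight` *
#' aux). Intended to demonstrate end-to-end trainability at desk scale,
#' not to reach field accuracy.
#'
#' @param model A `gma_model` built by [build_model()].
#' @param dataset List of samples, each `list(image = (H, W, 3) array in
#'   [0, 1], boxes = data.frame(cls, cx, cy, w, h))` with pixel
#'   coordinates; all images must share one size.
#' @param steps Number of optimisation steps.
#' @param seed RNG seed; the returned trace is reproducible.
#' @param config A [train_config()].
#' @return Numeric vector of per-step mean total losses (attribute
#'   `components` holds the box/cls/dfl decomposition of the last step).
#' @export
train_smoke <- function(model, dataset, steps = 50L, seed = 0L,
                        config = train_config()) {
  if (!length(dataset)) stop("empty dataset", call. = FALSE)
  set.seed(seed)
  nc <- model$config$num_classes
  has_aux <- !is.na(model$aux)
  bs <- min(config$batch_size, length(dataset))
  losses <- numeric(steps)
  last_comp <- NULL
  for (step in seq_len(steps)) {
    idx <- sample(length(dataset), bs)
    imgs <- lapply(dataset[idx], `[[`, "image")
    x <- array(unlist(imgs), c(dim(imgs[[1L]]), length(imgs)))
    gm_zero_grad_model(model)
    out <- model_forward(model, x, training = TRUE, with_aux = has_aux)
    total <- 0
    glead <- NULL; gaux <- NULL
    for (b in seq_along(idx)) {
      gts <- dataset[[idx[b]]]$boxes
      lead_maps <- slice_maps(out$lead, b)
      asn <- assign_lead(gts, lead_maps, nc = nc)
      hl <- head_loss(asn, nc)
      gl <- unflatten_grad(hl$grad / length(idx), asn$flat$anchors,
                           4L * 16L + nc)
      glead <- accumulate_scale_grads(glead, gl, b, length(idx))
      total <- total + hl$loss
      last_comp <- c(box = hl$box, cls = hl$cls, dfl = hl$dfl)
      if (has_aux) {
        aux_maps <- slice_maps(out$aux, b)
        asn_a <- assign_aux(gts, aux_maps, nc = nc)
        ha <- head_loss(asn_a, nc)
        ga <- unflatten_grad(config$aux_weight * ha$grad / length(idx),
                             asn_a$flat$anchors, 4L * 16L + nc)
        gaux <- accumulate_scale_grads(gaux, ga, b, length(idx))
        total <- total + config$aux_weight * ha$loss
      }
    }
    model_backward(model, glead, if (has_aux) gaux else NULL)
    frac <- (step - 1) / max(steps - 1, 1)
    lr <- config$lr0 * ((1 - frac) + frac * config$lrf)
    gm_sgd_step(model, lr, config$momentum, config$weight_decay)
    losses[step] <- total / length(idx)
  }
  attr(losses, "components") <- last_comp
  losses
}

gm_zero_grad_model <- function(model) {
  for (node in model$nodes) gm_zero_grad(node$m)
  invisible(model)
}

accumulate_scale_grads <- function(acc, g, b, nbatch) {
  if (is.null(acc))
    acc <- lapply(g, function(m) {
      d <- dim(m); d[4L] <- nbatch; array(0, d)
    })
  for (i in seq_along(g)) acc[[i]][, , , b] <- g[[i]][, , , 1L]
  acc
}

## ---- inference --------------------------------------------------------------

#' Greedy non-maximum suppression
#'
#' @param xyxy Matrix of boxes (corner format).
#' @param scores Confidence scores.
#' @param iou_thres Suppression threshold.
#' @return Indices of the kept boxes, in decreasing score order.
#' @export
nms_filter <- function(xyxy, scores, iou_thres = 0.45) {
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  while (length(ord)) {
    i <- ord[1L]
    keep <- c(keep, i)
    ord <- ord[-1L]
    if (!length(ord)) break
    ious <- iou_matrix(xyxy[ord, , drop = FALSE],
                       xyxy[i, , drop = FALSE])[, 1L]
    ord <- ord[ious <= iou_thres]
  }
  keep
}

#' Run a detector on one image
#'
#' Deploy-mode forward pass, distribution decode, confidence filtering and
#' non-maximum suppression.
#'
#' @param model A `gma_model`.
#' @param image Array `(H, W, 3)` in \\[0, 1\\].
#' @param conf_thres Confidence threshold (post-processing default 0.25).
#' @param iou_thres NMS IoU threshold (default 0.45).
#' @param max_det Maximum detections returned.
#' @return Data frame with columns `x`, `y`, `w`, `h` (pixels, centre
#'   format), `conf`, `cls`.
#' @export
detect_objects <- function(model, image, conf_thres = 0.25,
                           iou_thres = 0.45, max_det = 300L) {
  out <- model_forward(model, image, training = FALSE)
  nc <- model$config$num_classes
  flat <- flatten_predictions(out$lead, nc = nc)
  dec <- decode_boxes(flat)
  scores <- sigmoid_(flat$cls)
  best <- max.col(scores)
  conf <- scores[cbind(seq_len(nrow(scores)), best)]
  keep <- which(conf >= conf_thres)
  if (!length(keep))
    return(data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
                      h = numeric(0), conf = numeric(0), cls = integer(0)))
  kept <- nms_filter(dec$xyxy[keep, , drop = FALSE], conf[keep], iou_thres)
  kept <- kept[seq_len(min(length(kept), max_det))]
  sel <- keep[kept]
  data.frame(x = (dec$xyxy[sel, 1L] + dec$xyxy[sel, 3L]) / 2,
             y = (dec$xyxy[sel, 2L] + dec$xyxy[sel, 4L]) / 2,
             w = dec$xyxy[sel, 3L] - dec$xyxy[sel, 1L],
             h = dec$xyxy[sel, 4L] - dec$xyxy[sel, 2L],
             conf = conf[sel], cls = best[sel] - 1L)
}
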