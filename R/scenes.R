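# Procedural overhead corn-canopy scenes with whorl ("center leaf area")
# annotations, the augmentations used to expand the field datasets
# (brightness within +/-25%, rotation, directional motion blur), and
# synthetic per-frame detection streams for the decision-engine and
# delivery-simulator pipelines.

#' Synthetic scene configuration
#'
#' Emulates the study geometry: a camera 0.5-1 m above row-planted corn at
#' the V6-V8 stage, one whorl per plant, plants laid out along a row.
#'
#' @param size Square image side in pixels (>= 64).
#' @param n_plants Number of plants in view.
#' @param whorl_radius Range (min, max) of whorl radii in pixels.
#' @param leaf_count Leaves rendered per plant.
#' @param row_spacing_m Plant spacing along the row in metres.
#' @param px_per_m Pixel scale; together with `row_spacing_m` it fixes the
#'   on-screen spacing.
#' @return List of class `scene_config`.
#' @export
scene_config <- function(size = 160L, n_plants = 3L,
                         whorl_radius = c(7, 12), leaf_count = 7L,
                         row_spacing_m = 0.25, px_per_m = 200) {
  if (size < 64L) stop("size must be >= 64", call. = FALSE)
  if (n_plants < 1L) stop("n_plants must be >= 1", call. = FALSE)
  spacing_px <- row_spacing_m * px_per_m
  if (n_plants * spacing_px > size)
    stop("overcrowded scene: plants would overlap at whorl scale",
         call. = FALSE)
  structure(list(size = as.integer(size), n_plants = as.integer(n_plants),
                 whorl_radius = whorl_radius,
                 leaf_count = as.integer(leaf_count),
                 row_spacing_m = row_spacing_m, px_per_m = px_per_m,
                 spacing_px = spacing_px),
            class = "scene_config")
}

# Smooth value noise in [0, 1]: coarse uniform grid, resampled up and
# box-blurred a few times.
soil_noise <- function(size, coarse = 8L) {
  g <- matrix(runif(coarse^2), coarse, coarse)
  up <- cpp_upsample_nearest_fwd(array(g, c(coarse, coarse, 1L, 1L)),
                                 coarse, coarse, 1L, 1L, size, size)
  m <- matrix(up, size, size)
  for (i in 1:3) {
    m <- (m +
            m[c(1L, seq_len(size - 1L)), ] +
            m[c(seq_len(size - 1L) + 1L, size), ] +
            m[, c(1L, seq_len(size - 1L))] +
            m[, c(seq_len(size - 1L) + 1L, size)]) / 5
  }
  (m - min(m)) / max(max(m) - min(m), 1e-9)
}

#' Generate a synthetic corn-canopy scene
#'
#' Each plant is rendered as elongated leaf ellipses arranged radially
#' around a bright central whorl on a textured soil background; the
#' annotation is one box per plant covering the whorl. Deterministic for
#' a fixed seed.
#'
#' @param cfg A [scene_config()].
#' @param seed Integer seed.
#' @return List with `image` (array `(size, size, 3)` in \\[0, 1\\]),
#'   `boxes` (data frame `cls`, `cx`, `cy`, `w`, `h` in pixels) and
#'   `plants` (centres and whorl radii).
#' @export
generate_scene <- function(cfg, seed = 0L) {
  stopifnot(inherits(cfg, "scene_config"))
  set.seed(seed)
  S <- cfg$size
  # soil: brownish base modulated by smooth noise
  n1 <- soil_noise(S)
  img <- array(0, c(S, S, 3L))
  img[, , 1L] <- 0.35 + 0.15 * n1
  img[, , 2L] <- 0.26 + 0.12 * n1
  img[, , 3L] <- 0.16 + 0.08 * n1
  # pixel-centre grids (x = column, y = row), 0-based pixels
  xx <- matrix(rep(seq_len(S) - 0.5, each = S), S, S)
  yy <- matrix(rep(seq_len(S) - 0.5, times = S), S, S)
  # plant centres along a horizontal row through mid-image
  margin <- cfg$spacing_px / 2
  xs <- margin + (seq_len(cfg$n_plants) - 0.5) *
    (S - 2 * margin) / cfg$n_plants + runif(cfg$n_plants, -2, 2)
  ys <- S / 2 + runif(cfg$n_plants, -S / 10, S / 10)
  rs <- runif(cfg$n_plants, cfg$whorl_radius[1L], cfg$whorl_radius[2L])
  for (p in seq_len(cfg$n_plants)) {
    ang0 <- runif(1, 0, 2 * pi)
    for (l in seq_len(cfg$leaf_count)) {
      ang <- ang0 + 2 * pi * (l - 1) / cfg$leaf_count + runif(1, -0.2, 0.2)
      len <- rs[p] * runif(1, 2.2, 3.2)
      wid <- rs[p] * runif(1, 0.35, 0.55)
      lx <- xs[p] + cos(ang) * len * 0.55
      ly <- ys[p] + sin(ang) * len * 0.55
      u <- (xx - lx) * cos(ang) + (yy - ly) * sin(ang)
      v <- -(xx - lx) * sin(ang) + (yy - ly) * cos(ang)
      mask <- (u / len)^2 + (v / wid)^2 <= 1
      shade <- 0.75 + 0.25 * runif(1)
      img[, , 1L][mask] <- 0.10 * shade
      img[, , 2L][mask] <- (0.45 + 0.2 * runif(1)) * shade
      img[, , 3L][mask] <- 0.10 * shade
    }
    # bright young-leaf whorl with radial falloff
    d2 <- (xx - xs[p])^2 + (yy - ys[p])^2
    wmask <- d2 <= rs[p]^2
    glow <- pmax(0, 1 - d2 / rs[p]^2)
    img[, , 1L][wmask] <- (0.45 + 0.3 * glow[wmask])
    img[, , 2L][wmask] <- (0.70 + 0.3 * glow[wmask])
    img[, , 3L][wmask] <- 0.25
  }
  img <- pmin(pmax(img, 0), 1)
  side <- 2.4 * rs
  boxes <- data.frame(cls = 0L, cx = xs, cy = ys,
                      w = pmin(side, S), h = pmin(side, S))
  list(image = img, boxes = boxes,
       plants = data.frame(x = xs, y = ys, r = rs))
}

#' Augmentation parameters
#'
#' @param brightness Fractional brightness delta in \\[-0.25, 0.25\\].
#' @param rotation Rotation angle in degrees (about the image centre).
#' @param blur_len Motion-blur kernel length in pixels (0 or 1 = none).
#' @param blur_angle Motion-blur direction in degrees.
#' @return List of class `augment_params`.
#' @export
augment_params <- function(brightness = 0, rotation = 0, blur_len = 0L,
                           blur_angle = 0) {
  if (abs(brightness) > 0.25)
    stop("brightness delta must stay within +/-25%", call. = FALSE)
  structure(list(brightness = brightness, rotation = rotation,
                 blur_len = as.integer(blur_len), blur_angle = blur_angle),
            class = "augment_params")
}

#' Augment a scene
#'
#' Applies brightness scaling, rotation about the image centre (boxes are
#' transformed as axis-aligned hulls of their rotated corners and clipped
#' to the frame; boxes rotated fully out of frame are dropped with a
#' message) and directional motion blur.
#'
#' @param image Array `(H, W, 3)` in \\[0, 1\\].
#' @param boxes Data frame `cls`, `cx`, `cy`, `w`, `h` (pixels).
#' @param params An [augment_params()].
#' @return List with transformed `image` and `boxes`.
#' @export
augment_scene <- function(image, boxes, params) {
  stopifnot(inherits(params, "augment_params"))
  S <- dim(image)[1L]
  stopifnot(dim(image)[2L] == S)
  img <- image
  if (params$rotation != 0) {
    th <- params$rotation * pi / 180
    cx0 <- S / 2
    # inverse map: source = R(-theta) (dest - c) + c, nearest neighbour
    xs <- matrix(rep(seq_len(S) - 0.5, each = S), S, S) - cx0
    ys <- matrix(rep(seq_len(S) - 0.5, times = S), S, S) - cx0
    sx <- cos(th) * xs + sin(th) * ys + cx0
    sy <- -sin(th) * xs + cos(th) * ys + cx0
    si <- pmin(pmax(ceiling(sy), 1L), S)
    sj <- pmin(pmax(ceiling(sx), 1L), S)
    inside <- sx >= 0 & sx <= S & sy >= 0 & sy <= S
    fill <- apply(img, 3L, stats::median)
    rot <- array(0, dim(img))
    for (ch in 1:3) {
      plane <- img[, , ch][cbind(as.vector(si), as.vector(sj))]
      plane[!as.vector(inside)] <- fill[ch]
      rot[, , ch] <- matrix(plane, S, S)
    }
    img <- rot
    # transform the boxes: rotate corners by +theta about the centre
    nb <- nrow(boxes)
    keep <- logical(nb)
    for (b in seq_len(nb)) {
      cxs <- boxes$cx[b] + c(-1, 1, 1, -1) * boxes$w[b] / 2 - cx0
      cys <- boxes$cy[b] + c(-1, -1, 1, 1) * boxes$h[b] / 2 - cx0
      rx <- cos(th) * cxs - sin(th) * cys + cx0
      ry <- sin(th) * cxs + cos(th) * cys + cx0
      x1 <- max(min(rx), 0); x2 <- min(max(rx), S)
      y1 <- max(min(ry), 0); y2 <- min(max(ry), S)
      if (x2 - x1 > 1 && y2 - y1 > 1) {
        keep[b] <- TRUE
        boxes$cx[b] <- (x1 + x2) / 2
        boxes$cy[b] <- (y1 + y2) / 2
        boxes$w[b] <- x2 - x1
        boxes$h[b] <- y2 - y1
      }
    }
    if (any(!keep))
      message(sum(!keep), " box(es) rotated out of frame and dropped")
    boxes <- boxes[keep, , drop = FALSE]
  }
  if (params$blur_len > 1L) {
    L <- params$blur_len
    phi <- params$blur_angle * pi / 180
    t <- seq(-(L - 1) / 2, (L - 1) / 2, length.out = L)
    acc <- array(0, dim(img))
    for (k in seq_len(L)) {
      dx <- round(t[k] * cos(phi))
      dy <- round(t[k] * sin(phi))
      ii <- pmin(pmax(seq_len(S) + dy, 1L), S)
      jj <- pmin(pmax(seq_len(S) + dx, 1L), S)
      acc <- acc + img[ii, jj, , drop = FALSE]
    }
    img <- acc / L
  }
  if (params$brightness != 0)
    img <- pmin(pmax(img * (1 + params$brightness), 0), 1)
  list(image = img, boxes = boxes)
}

#' Write YOLO-format labels
#'
#' One `class cx cy w h` line per box, centre coordinates and sizes
#' normalised by the image side.
#'
#' @param boxes Data frame `cls`, `cx`, `cy`, `w`, `h` (pixels).
#' @param path Output text file.
#' @param size Image side in pixels used for normalisation.
#' @export
write_yolo_labels <- function(boxes, path, size) {
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", boxes$cls,
                   boxes$cx / size, boxes$cy / size,
                   boxes$w / size, boxes$h / size)
  writeLines(lines, path)
  invisible(path)
}

#' Read YOLO-format labels
#'
#' @param path Label text file.
#' @param size Image side in pixels; coordinates are rescaled to pixels.
#' @return Data frame `cls`, `cx`, `cy`, `w`, `h`.
#' @export
read_yolo_labels <- function(path, size) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(cls = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0)))
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  if (ncol(m) != 5L) stop("malformed YOLO label file", call. = FALSE)
  if (any(m[, 2:5] < 0 | m[, 2:5] > 1))
    stop("YOLO coordinates must lie in [0, 1]", call. = FALSE)
  data.frame(cls = as.integer(m[, 1L]), cx = m[, 2L] * size,
             cy = m[, 3L] * size, w = m[, 4L] * size, h = m[, 5L] * size)
}

#' Generate a dataset of scenes with augmented copies
#'
#' Writes `images/*.png`, `labels/*.txt` (YOLO format) and a
#' `manifest.yaml` when `out_dir` is given; always returns the samples
#' in memory. The augmentation multiplicity is a parameter because the
#' expansion factor of the source datasets is not uniquely determined.
#'
#' @param cfg A [scene_config()].
#' @param n Number of base scenes.
#' @param seed Integer seed.
#' @param multiplicity Augmented copies per base scene (0 = originals
#'   only); each copy draws a random brightness in +/-25%, rotation and
#'   motion-blur length.
#' @param out_dir Optional output directory.
#' @return List of samples `list(image, boxes)`.
#' @export
generate_dataset <- function(cfg, n, seed = 0L, multiplicity = 0L,
                             out_dir = NULL) {
  samples <- list()
  for (i in seq_len(n)) {
    sc <- generate_scene(cfg, seed = seed + i - 1L)
    samples[[length(samples) + 1L]] <- sc[c("image", "boxes")]
    if (multiplicity > 0L) {
      set.seed(seed * 1000L + i)
      for (j in seq_len(multiplicity)) {
        ap <- augment_params(
          brightness = runif(1, -0.25, 0.25),
          rotation = runif(1, 0, 360),
          blur_len = sample(0:5, 1L),
          blur_angle = runif(1, 0, 180))
        samples[[length(samples) + 1L]] <-
          augment_scene(sc$image, sc$boxes, ap)
      }
    }
  }
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "images"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, "labels"), recursive = TRUE,
               showWarnings = FALSE)
    for (i in seq_along(samples)) {
      png::writePNG(aperm(samples[[i]]$image, c(1L, 2L, 3L)),
                    file.path(out_dir, "images", sprintf("%05d.png", i)))
      write_yolo_labels(samples[[i]]$boxes,
                        file.path(out_dir, "labels", sprintf("%05d.txt", i)),
                        cfg$size)
    }
    yaml::write_yaml(list(n = n, seed = seed, multiplicity = multiplicity,
                          size = cfg$size),
                     file.path(out_dir, "manifest.yaml"))
  }
  samples
}

#' Generate a synthetic per-frame detection stream
#'
#' Plants move across the frame at a constant speed (the camera platform
#' drives along the row); each frame emits one jittered detection per
#' visible plant, with optional dropouts. Nominal frame rate 30 fps.
#'
#' @param cfg A [scene_config()].
#' @param speed_px Per-frame translation of the scene in pixels.
#' @param frames Number of frames.
#' @param noise List with `center_sd` (pixel jitter of detection centres)
#'   and `dropout` (per-frame probability of missing a plant).
#' @param seed Integer seed.
#' @return List of class `detection_stream`: per frame,
#'   `list(frame, boxes)` with `boxes` columns `x`, `y`, `w`, `h`,
#'   `conf`, `cls`; attribute `n_plants`.
#' @export
generate_detection_stream <- function(cfg, speed_px = 3, frames = 120L,
                                      noise = list(center_sd = 0,
                                                   dropout = 0),
                                      seed = 0L) {
  set.seed(seed)
  S <- cfg$size
  # plants start left of the frame and traverse it
  x0 <- -(seq_len(cfg$n_plants) - 1L) * cfg$spacing_px - 10
  y0 <- runif(cfg$n_plants, S * 0.35, S * 0.65)
  r <- runif(cfg$n_plants, cfg$whorl_radius[1L], cfg$whorl_radius[2L])
  stream <- vector("list", frames)
  for (f in seq_len(frames)) {
    xs <- x0 + f * speed_px
    vis <- which(xs >= 0 & xs <= S)
    rows <- list()
    for (p in vis) {
      if (noise$dropout > 0 && runif(1) < noise$dropout) next
      rows[[length(rows) + 1L]] <- data.frame(
        x = xs[p] + rnorm(1, 0, noise$center_sd),
        y = y0[p] + rnorm(1, 0, noise$center_sd),
        w = 2.4 * r[p], h = 2.4 * r[p],
        conf = runif(1, 0.5, 0.95), cls = 0L, plant = p)
    }
    boxes <- if (length(rows)) do.call(rbind, rows) else
      data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
                 h = numeric(0), conf = numeric(0), cls = integer(0),
                 plant = integer(0))
    stream[[f]] <- list(frame = f, boxes = boxes)
  }
  structure(stream, class = "detection_stream", n_plants = cfg$n_plants)
}

#' Write a detection stream as JSON lines
#'
#' @param stream A `detection_stream` (or any list of
#'   `list(frame, boxes)`).
#' @param path Output file; one JSON object per frame.
#' @export
write_detection_stream <- function(stream, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in stream) {
    boxes <- fr$boxes
    keep <- intersect(c("x", "y", "w", "h", "conf", "cls"), names(boxes))
    rec <- list(frame = fr$frame, boxes = boxes[, keep, drop = FALSE])
    writeLines(jsonlite::toJSON(rec, dataframe = "rows", auto_unbox = TRUE,
                                digits = NA), con)
  }
  invisible(path)
}

#' Read a detection stream from JSON lines
#'
#' @param path File written by [write_detection_stream()] (or an
#'   equivalent `{frame, boxes: [...]}` JSON-lines file).
#' @return A `detection_stream` list.
#' @export
read_detection_stream <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    boxes <- rec$boxes
    if (is.null(boxes) || !length(boxes))
      boxes <- data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
                          h = numeric(0), conf = numeric(0),
                          cls = integer(0))
    list(frame = rec$frame, boxes = as.data.frame(boxes))
  })
  structure(out, class = "detection_stream")
}
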