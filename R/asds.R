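# Spray-decision engine: per-frame post-processing of detections against a
# configurable trigger rectangle, debounce, and actuation packet
# formatting. The trigger test is centre-point containment with inclusive
# edges (the decision algorithm passes only the detection centre to the
# region test). Serial transmission is abstracted: packets are returned as
# wire strings and may be appended to any connection or file.

#' Rectangular decision region
#'
#' @param x1,y1,x2,y2 Pixel corners, `x1 < x2`, `y1 < y2`; origin top-left,
#'   x right, y down. The region can be adjusted at run time to match crop
#'   growth stage.
#' @return List of class `decision_region`.
#' @export
decision_region <- function(x1, y1, x2, y2) {
  if (!(x1 < x2 && y1 < y2))
    stop("need x1 < x2 and y1 < y2", call. = FALSE)
  structure(list(x1 = x1, y1 = y1, x2 = x2, y2 = y2),
            class = "decision_region")
}

#' Does a detection trigger the region?
#'
#' True iff the detection centre lies inside the region, edges inclusive.
#'
#' @param det List or one-row data frame with elements `x`, `y` (centre in
#'   pixels).
#' @param region A [decision_region()].
#' @return Logical flag.
#' @export
intersects_region <- function(det, region) {
  stopifnot(inherits(region, "decision_region"))
  det$x >= region$x1 & det$x <= region$x2 &
    det$y >= region$y1 & det$y <= region$y2
}

#' Format an actuation signal packet
#'
#' Wire form `"X<x>,Y<y>,C<centi-confidence>\n"`; integers throughout, the
#' confidence as `round(100 * conf)`.
#'
#' @param x,y Detection centre in pixels (rounded to integers).
#' @param conf Confidence in \\[0, 1\\].
#' @return Single string (including the trailing newline).
#' @export
format_signal <- function(x, y, conf) {
  if (conf < 0 || conf > 1)
    stop("confidence must lie in [0, 1]", call. = FALSE)
  sprintf("X%d,Y%d,C%d\n", as.integer(round(x)), as.integer(round(y)),
          as.integer(round(100 * conf)))
}

#' Parse an actuation signal packet
#'
#' @param packet String produced by [format_signal()].
#' @return List with integer `x`, `y` and `confidence_centi`.
#' @export
parse_signal <- function(packet) {
  m <- regmatches(packet,
                  regexec("^X(-?[0-9]+),Y(-?[0-9]+),C([0-9]+)\n?$", packet))[[1L]]
  if (length(m) != 4L) stop("malformed signal packet", call. = FALSE)
  list(x = as.integer(m[2L]), y = as.integer(m[3L]),
       confidence_centi = as.integer(m[4L]))
}

#' Engine state of the spray-decision loop
#'
#' @param refractory_frames Debounce window: after a trigger the region
#'   stays silent for this many frames (default 15, about 0.5 s at the
#'   30 fps acquisition rate).
#' @return List of class `asds_state` with the remaining refractory count
#'   and the region occupancy flag.
#' @export
asds_state <- function(refractory_frames = 15L) {
  structure(list(window = as.integer(refractory_frames),
                 remaining = 0L, occupied = FALSE),
            class = "asds_state")
}

#' Process one frame of detections
#'
#' Emits one packet per triggering detection (all plants triggering in the
#' same frame emit; multi-row operation treats them independently) unless
#' suppressed by the debounce: a packet is only sent when the region was
#' unoccupied in the previous frame and the refractory window has elapsed.
#' Malformed detections are skipped with a warning.
#'
#' @param dets Data frame of detections (`x`, `y`, `w`, `h`, `conf`,
#'   optionally `cls`), already confidence- and NMS-filtered (the
#'   post-processing defaults are `conf_thres = 0.25`,
#'   `iou_thres = 0.45`).
#' @param region A [decision_region()].
#' @param state An [asds_state()].
#' @param conf_thres Safety re-check of the confidence filter.
#' @return List with `packets` (character vector of wire strings) and the
#'   updated `state`.
#' @export
process_frame <- function(dets, region, state, conf_thres = 0.25) {
  stopifnot(inherits(state, "asds_state"))
  packets <- character(0)
  inside <- logical(0)
  if (!is.null(dets) && nrow(dets)) {
    for (i in seq_len(nrow(dets))) {
      d <- dets[i, ]
      bad <- any(is.na(c(d$x, d$y, d$conf))) ||
        (!is.null(d$w) && (is.na(d$w) || d$w <= 0)) ||
        (!is.null(d$h) && (is.na(d$h) || d$h <= 0)) ||
        d$conf < 0 || d$conf > 1
      if (bad) {
        warning("malformed detection skipped (frame processing continues)")
        next
      }
      if (d$conf < conf_thres) next
      inside <- c(inside, intersects_region(d, region))
      if (inside[length(inside)] && state$remaining == 0L &&
          !state$occupied) {
        packets <- c(packets, format_signal(d$x, d$y, d$conf))
      }
    }
  }
  if (length(packets)) state$remaining <- state$window
  else state$remaining <- max(0L, state$remaining - 1L)
  state$occupied <- any(inside)
  list(packets = packets, state = state)
}

#' Run the spray-decision engine over a detection stream
#'
#' @param stream A `detection_stream` (see
#'   [generate_detection_stream()] / [read_detection_stream()]).
#' @param region A [decision_region()].
#' @param state Initial [asds_state()].
#' @param conf_thres Confidence threshold.
#' @param sink Optional connection or file path; emitted packets are
#'   appended verbatim (stand-in for the serial port).
#' @return Data frame log with one row per packet: `frame`, `x`, `y`,
#'   `confidence_centi`, `packet`.
#' @export
run_asds <- function(stream, region, state = asds_state(),
                     conf_thres = 0.25, sink = NULL) {
  log <- list()
  con <- NULL
  if (!is.null(sink)) {
    con <- if (inherits(sink, "connection")) sink else file(sink, "w")
    if (!inherits(sink, "connection")) on.exit(close(con))
  }
  for (fr in stream) {
    res <- process_frame(fr$boxes, region, state, conf_thres)
    state <- res$state
    for (p in res$packets) {
      parsed <- parse_signal(p)
      log[[length(log) + 1L]] <- data.frame(
        frame = fr$frame, x = parsed$x, y = parsed$y,
        confidence_centi = parsed$confidence_centi, packet = p)
      if (!is.null(con)) cat(p, file = con, sep = "")
    }
  }
  if (length(log)) do.call(rbind, log) else
    data.frame(frame = integer(0), x = integer(0), y = integer(0),
               confidence_centi = integer(0), packet = character(0))
}
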