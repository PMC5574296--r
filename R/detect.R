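# Marker output: turn per-window SVM decisions into one averaged polyp
# marker per detected region, and render annotated frames.

#' Construct a detection record
#'
#' @param origin `c(x, y)` window origin in frame coordinates.
#' @param size Window side length.
#' @param frame_index Parent frame index.
#' @param label Predicted label.
#' @param score Signed SVM score.
#' @return List of class `detection`.
#' @export
detection <- function(origin, size, frame_index, label, score) {
  stopifnot(is.finite(score))
  structure(list(origin = as.numeric(origin), size = as.numeric(size),
                 frame_index = as.integer(frame_index),
                 label = as.character(label), score = as.numeric(score)),
            class = "detection")
}

.detection_center <- function(d) d$origin + d$size / 2

#' Group positive detections by proximity
#'
#' Single-linkage grouping of window centers: two detections belong to the
#' same group when their centers are within `link_distance`, directly or
#' through a chain of linked detections.
#'
#' @param detections List of [detection()] records from one frame.
#' @param link_distance Linking radius in pixels (default 227, one window).
#' @return List of groups, each a list of detections. Empty input gives an
#'   empty list.
#' @export
group_detections <- function(detections, link_distance = 227) {
  n <- length(detections)
  if (n == 0L) return(list())
  fi <- unique(vapply(detections, `[[`, integer(1), "frame_index"))
  if (length(fi) > 1L)
    stop("detections from multiple frames; group one frame at a time",
         call. = FALSE)
  centers <- t(vapply(detections, .detection_center, numeric(2)))
  # union-find over the link graph
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (sqrt(sum((centers[i, ] - centers[j, ])^2)) <= link_distance) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(unique(roots), function(r) detections[roots == r])
}

#' Aggregate a detection group into one marker
#'
#' Keeps the group's high-scoring detections — those with score at least
#' `score_fraction` times the group's maximum — and places the marker at
#' the arithmetic mean of the kept window centers.
#'
#' @param group Nonempty list of [detection()] records.
#' @param score_fraction Relative score threshold in (0, 1\] (default 0.8).
#' @return Object of class `marker`: `center`, `radius` (half the window
#'   size), `n_detections` (kept count), `mean_score`, `frame_index`.
#' @export
aggregate_marker <- function(group, score_fraction = 0.8) {
  stopifnot(length(group) >= 1L)
  scores <- vapply(group, `[[`, numeric(1), "score")
  keep <- scores >= score_fraction * max(scores)
  kept <- group[keep]
  centers <- t(vapply(kept, .detection_center, numeric(2)))
  structure(list(center = colMeans(centers),
                 radius = mean(vapply(kept, `[[`, numeric(1), "size")) / 2,
                 n_detections = length(kept),
                 mean_score = mean(scores[keep]),
                 frame_index = kept[[1L]]$frame_index),
            class = "marker")
}

#' Draw markers onto a frame
#'
#' Renders each marker as a circular stroke (default bright green, 3 px
#' wide) centered on the marker position; all other pixels are unchanged.
#'
#' @param frm A [frame()].
#' @param markers List of `marker` objects (see [aggregate_marker()]).
#' @param color RGB stroke color on the 0-255 scale.
#' @param stroke Stroke width in pixels.
#' @return A new annotated [frame()].
#' @export
annotate_frame <- function(frm, markers, color = c(0, 255, 0), stroke = 3) {
  stopifnot(inherits(frm, "polyp_frame"))
  px <- frm$pixels
  d <- dim(px); H <- d[1L]; W <- d[2L]
  for (mk in markers) {
    cx <- mk$center[1L]; cy <- mk$center[2L]
    if (cx < 0 || cx > W - 1 || cy < 0 || cy > H - 1)
      stop("marker center (", cx, ", ", cy, ") outside the frame", call. = FALSE)
    xs <- matrix(rep(seq_len(W) - 1, each = H), H, W)
    ys <- matrix(rep(seq_len(H) - 1, W), H, W)
    dist <- sqrt((xs - cx)^2 + (ys - cy)^2)
    ring <- abs(dist - mk$radius) <= stroke / 2
    for (k in 1:3) {
      ch <- px[, , k]
      ch[ring] <- color[k]
      px[, , k] <- ch
    }
  }
  frame(px, index = frm$index, roi = frm$roi)
}

#' Run the detector over one frame
#'
#' Tiles the frame into windows, extracts and fuses both feature families,
#' scores every window with the SVM, groups positive windows, and
#' aggregates each group into a marker.
#'
#' @param model A fitted [polyp_detector()].
#' @param frm A [frame()] (already cropped to its informative region).
#' @param stride Sliding-window stride in pixels (default 32).
#' @param link_distance Marker grouping radius (default 227).
#' @param score_fraction Relative score cut inside a group (default 0.8).
#' @return List with `markers` (list of `marker`) and `detections` (all
#'   window-level results as a data.frame).
#' @export
detect_frame <- function(model, frm, stride = 32L, link_distance = 227,
                         score_fraction = 0.8) {
  stopifnot(inherits(model, "polyp_detector"), inherits(frm, "polyp_frame"))
  windows <- generate_windows(frm, size = 227L, stride = stride)
  pred <- predict(model, windows)
  pos <- which(pred$label == model$svm$positive_class)
  dets <- lapply(pos, function(i)
    detection(windows[[i]]$origin, 227, frm$index,
              pred$label[i], pred$score[i]))
  groups <- group_detections(dets, link_distance = link_distance)
  markers <- lapply(groups, aggregate_marker, score_fraction = score_fraction)
  det_df <- data.frame(
    frame_index = frm$index,
    x = vapply(windows, function(w) w$origin[1L], integer(1)),
    y = vapply(windows, function(w) w$origin[2L], integer(1)),
    label = pred$label, score = pred$score)
  list(markers = markers, detections = det_df)
}

#' Run the detector over a frame sequence
#'
#' @param model A fitted [polyp_detector()].
#' @param frames List of [frame()] objects, or a path accepted by
#'   [read_frames()].
#' @param ... Passed to [detect_frame()].
#' @param annotate Draw markers on the frames? (default `TRUE`)
#' @return List with `markers` (per frame), `frames` (annotated copies if
#'   requested), and `report` (data.frame: frame_index, x, y, mean_score,
#'   n_windows).
#' @export
detect_frames <- function(model, frames, ..., annotate = TRUE) {
  if (is.character(frames)) frames <- read_frames(frames)
  res <- lapply(frames, function(f) detect_frame(model, f, ...))
  markers <- lapply(res, `[[`, "markers")
  out_frames <- if (annotate) {
    mapply(annotate_frame, frames, markers, SIMPLIFY = FALSE)
  } else frames
  rows <- do.call(rbind, lapply(seq_along(frames), function(i) {
    if (length(markers[[i]]) == 0L) return(NULL)
    do.call(rbind, lapply(markers[[i]], function(mk)
      data.frame(frame_index = mk$frame_index, x = mk$center[1L],
                 y = mk$center[2L], mean_score = mk$mean_score,
                 n_windows = mk$n_detections)))
  }))
  if (is.null(rows))
    rows <- data.frame(frame_index = integer(0), x = numeric(0),
                       y = numeric(0), mean_score = numeric(0),
                       n_windows = integer(0))
  list(markers = markers, frames = out_frames, report = rows)
}

#' Write a detection report as JSON
#'
#' @param report The `report` data.frame from [detect_frames()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @export
print.marker <- function(x, ...) {
  cat(sprintf("<marker frame %d at (%.1f, %.1f), %d windows, mean score %.3f>\n",
              x$frame_index, x$center[1L], x$center[2L], x$n_detections,
              x$mean_score))
  invisible(x)
}
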