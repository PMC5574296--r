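# Seeded synthetic endoscopy-like fixtures: smooth reddish mucosa-style
# backgrounds with optional textured elliptical polyp regions and exact
# ground truth, so every pipeline stage is testable without clinical data.

#' Fixture generation parameters
#'
#' Defaults emulate the statistics the detector keys on: a red-dominant,
#' smoothly varying background (mucosa), and an elliptical region carrying
#' extra high-frequency texture and a mild brightness dome (polyp). The
#' `texture_amplitude` knob sets the difficulty: it is the contrast between
#' polyp-surface texture and background smoothness.
#'
#' @param frame_width,frame_height Frame extent in pixels.
#' @param bg_scale Correlation length of the smooth background field (px).
#' @param bg_contrast Amplitude of background brightness variation (8-bit
#'   units).
#' @param noise_sd Per-pixel Gaussian noise standard deviation (8-bit units).
#' @param axes_range Range the polyp ellipse semi-axes are drawn from (px).
#' @param texture_amplitude Amplitude of the polyp's band-pass surface
#'   texture (8-bit units).
#' @param texture_scale Correlation length of the polyp texture (px); small
#'   against `bg_scale`, which is what the middle wavelet subbands respond
#'   to.
#' @param brightness Extra brightness of the polyp dome (8-bit units).
#' @return List of parameters (class `fixture_spec`).
#' @export
fixture_spec <- function(frame_width = 320L, frame_height = 320L,
                         bg_scale = 48, bg_contrast = 25, noise_sd = 8,
                         axes_range = c(55, 90), texture_amplitude = 10,
                         texture_scale = 4, brightness = 5) {
  structure(list(frame_width = as.integer(frame_width),
                 frame_height = as.integer(frame_height),
                 bg_scale = bg_scale, bg_contrast = bg_contrast,
                 noise_sd = noise_sd, axes_range = axes_range,
                 texture_amplitude = texture_amplitude,
                 texture_scale = texture_scale, brightness = brightness),
            class = "fixture_spec")
}

# Smooth random field: coarse Gaussian grid, bilinear upsampling.
.smooth_field <- function(nr, nc, scale) {
  gr <- max(2L, ceiling(nr / scale) + 1L)
  gc <- max(2L, ceiling(nc / scale) + 1L)
  coarse <- matrix(stats::rnorm(gr * gc), gr, gc)
  ry <- seq(1, gr, length.out = nr)
  rx <- seq(1, gc, length.out = nc)
  y0 <- pmin(floor(ry), gr - 1L); fy <- ry - y0
  x0 <- pmin(floor(rx), gc - 1L); fx <- rx - x0
  a <- coarse[cbind(rep(y0, nc), rep(x0, each = nr))]
  b <- coarse[cbind(rep(y0, nc), rep(x0 + 1L, each = nr))]
  d <- coarse[cbind(rep(y0 + 1L, nc), rep(x0, each = nr))]
  e <- coarse[cbind(rep(y0 + 1L, nc), rep(x0 + 1L, each = nr))]
  wfy <- rep(fy, nc); wfx <- rep(fx, each = nr)
  f <- a * (1 - wfy) * (1 - wfx) + d * wfy * (1 - wfx) +
    b * (1 - wfy) * wfx + e * wfy * wfx
  matrix(f, nr, nc)
}

#' Test points against a ground-truth polyp ellipse
#'
#' @param x,y Point coordinates (0-based pixel units, vectorized).
#' @param ellipse List with `cx`, `cy`, semi-axes `a`, `b`, rotation
#'   `theta` (radians), as produced by the fixture generator.
#' @return Logical vector: point inside (or on) the ellipse.
#' @export
inside_ellipse <- function(x, y, ellipse) {
  ct <- cos(ellipse$theta); st <- sin(ellipse$theta)
  dx <- x - ellipse$cx; dy <- y - ellipse$cy
  u <- dx * ct + dy * st
  v <- -dx * st + dy * ct
  (u / ellipse$a)^2 + (v / ellipse$b)^2 <= 1
}

.render_fixture <- function(nr, nc, spec, ellipse) {
  base <- .smooth_field(nr, nc, spec$bg_scale)
  tint <- .smooth_field(nr, nc, spec$bg_scale * 1.5)
  px <- array(0, c(nr, nc, 3L))
  px[, , 1L] <- 165 + spec$bg_contrast * base
  px[, , 2L] <- 80 + 0.6 * spec$bg_contrast * base + 8 * tint
  px[, , 3L] <- 70 + 0.5 * spec$bg_contrast * base - 6 * tint
  if (!is.null(ellipse)) {
    xs <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
    ys <- matrix(rep(seq_len(nr) - 1, nc), nr, nc)
    ct <- cos(ellipse$theta); st <- sin(ellipse$theta)
    dx <- xs - ellipse$cx; dy <- ys - ellipse$cy
    u <- dx * ct + dy * st
    v <- -dx * st + dy * ct
    r2 <- (u / ellipse$a)^2 + (v / ellipse$b)^2
    soft <- pmax(0, 1 - r2)               # dome profile, 1 at center
    fine <- .smooth_field(nr, nc, spec$texture_scale) -
      .smooth_field(nr, nc, spec$texture_scale * 2)   # band-pass texture
    bump <- spec$brightness * soft + spec$texture_amplitude * fine * (r2 <= 1)
    px[, , 1L] <- px[, , 1L] + bump
    px[, , 2L] <- px[, , 2L] + 0.8 * bump
    px[, , 3L] <- px[, , 3L] + 0.5 * bump
  }
  px <- px + array(stats::rnorm(nr * nc * 3L, sd = spec$noise_sd),
                   c(nr, nc, 3L))
  px[] <- pmin(255, pmax(0, round(px)))
  px
}

#' Generate one synthetic frame
#'
#' @param spec A [fixture_spec()].
#' @param seed Integer seed; fully determines the output.
#' @param polyp Include a polyp ellipse? (default `TRUE`)
#' @param ellipse Optional explicit ellipse
#'   `list(cx, cy, a, b, theta)` in 0-based pixel coordinates; drawn at
#'   random inside the frame when `NULL`.
#' @return List with `frame` (a [frame()]) and `ellipse` (ground truth, or
#'   `NULL` for polyp-free frames).
#' @export
make_frame <- function(spec = fixture_spec(), seed = 1L, polyp = TRUE,
                       ellipse = NULL) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  nr <- spec$frame_height; nc <- spec$frame_width
  if (polyp && is.null(ellipse)) {
    a <- stats::runif(1, spec$axes_range[1L], spec$axes_range[2L])
    b <- stats::runif(1, spec$axes_range[1L], spec$axes_range[2L])
    m <- max(a, b)
    ellipse <- list(cx = stats::runif(1, m, nc - 1 - m),
                    cy = stats::runif(1, m, nr - 1 - m),
                    a = a, b = b, theta = stats::runif(1, 0, pi))
  }
  if (!polyp) ellipse <- NULL
  if (!is.null(ellipse)) {
    m <- max(ellipse$a, ellipse$b)
    if (ellipse$cx - m < 0 || ellipse$cx + m > nc - 1 ||
        ellipse$cy - m < 0 || ellipse$cy + m > nr - 1)
      stop("polyp ellipse extends outside the frame", call. = FALSE)
  }
  px <- .render_fixture(nr, nc, spec, ellipse)
  list(frame = frame(px), ellipse = ellipse)
}

#' Generate a labelled window dataset
#'
#' Produces 227x227 windows with binary labels: polyp windows contain an
#' ellipse covering the window center; nonpolyp windows are pure
#' background. A window is labelled polyp exactly when its center lies
#' inside its ground-truth ellipse.
#'
#' @param n_polyp,n_nonpolyp Requested class counts (>= 0, not both zero).
#' @param spec A [fixture_spec()].
#' @param seed Integer seed.
#' @return List with `windows` (list of [window()]), `labels` (factor with
#'   levels polyp, nonpolyp), and `ellipses` (per-window ground truth or
#'   `NULL`).
#' @export
make_dataset <- function(n_polyp, n_nonpolyp, spec = fixture_spec(),
                         seed = 1L) {
  stopifnot(n_polyp >= 0L, n_nonpolyp >= 0L)
  if (n_polyp + n_nonpolyp == 0L) stop("empty dataset requested", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  n <- n_polyp + n_nonpolyp
  lab <- rep(c("polyp", "nonpolyp"), c(n_polyp, n_nonpolyp))
  windows <- vector("list", n)
  ellipses <- vector("list", n)
  side <- 227L
  for (i in seq_len(n)) {
    ellipse <- NULL
    if (lab[i] == "polyp") {
      a <- stats::runif(1, spec$axes_range[1L], spec$axes_range[2L])
      b <- stats::runif(1, spec$axes_range[1L], spec$axes_range[2L])
      # center jittered but still covering the window center
      r <- 0.5 * min(a, b)
      ellipse <- list(cx = 113 + stats::runif(1, -r, r),
                      cy = 113 + stats::runif(1, -r, r),
                      a = a, b = b, theta = stats::runif(1, 0, pi))
    }
    px <- .render_fixture(side, side, spec, ellipse)
    windows[[i]] <- window(px, origin = c(0L, 0L), frame_index = i - 1L)
    ellipses[i] <- list(ellipse)   # keep NULL slots for nonpolyp windows
  }
  list(windows = windows,
       labels = factor(lab, levels = c("polyp", "nonpolyp")),
       ellipses = ellipses)
}

#' Generate a synthetic video with a drifting polyp
#'
#' Writes a multi-frame TIFF (the package's lossless frame-sequence
#' container) in which one polyp ellipse drifts smoothly across frames,
#' plus a per-frame ground-truth track.
#'
#' @param n_frames Number of frames (>= 1).
#' @param spec A [fixture_spec()].
#' @param seed Integer seed.
#' @param path Output path (`.tif`); a temporary file by default.
#' @param drift Maximum per-frame center displacement in pixels (default 4).
#' @return List with `path` and `truth` (list of per-frame ellipses).
#' @export
make_video <- function(n_frames, spec = fixture_spec(), seed = 1L,
                       path = tempfile(fileext = ".tif"), drift = 4) {
  stopifnot(n_frames >= 1L)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  nr <- spec$frame_height; nc <- spec$frame_width
  a <- stats::runif(1, spec$axes_range[1L], spec$axes_range[2L])
  b <- stats::runif(1, spec$axes_range[1L], spec$axes_range[2L])
  m <- max(a, b)
  cx <- stats::runif(1, m + drift * n_frames / 2, nc - 1 - m - drift * n_frames / 2)
  cy <- stats::runif(1, m + drift * n_frames / 2, nr - 1 - m - drift * n_frames / 2)
  cx <- min(max(cx, m), nc - 1 - m); cy <- min(max(cy, m), nr - 1 - m)
  ang <- stats::runif(1, 0, 2 * pi)
  vel <- drift * 0.8 * c(cos(ang), sin(ang))
  theta <- stats::runif(1, 0, pi)
  frames <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    ellipse <- list(cx = cx, cy = cy, a = a, b = b, theta = theta)
    px <- .render_fixture(nr, nc, spec, ellipse)
    frames[[i]] <- frame(px, index = i - 1L)
    truth[[i]] <- ellipse
    # bounce off frame borders to keep the ellipse inside
    nxt <- c(cx, cy) + vel
    if (nxt[1L] < m || nxt[1L] > nc - 1 - m) vel[1L] <- -vel[1L]
    if (nxt[2L] < m || nxt[2L] > nr - 1 - m) vel[2L] <- -vel[2L]
    cx <- cx + vel[1L]; cy <- cy + vel[2L]
  }
  write_video(frames, path)
  list(path = path, truth = truth)
}

#' Write a window dataset to disk
#'
#' PNG window images plus `labels.csv` (filename, label) and
#' `ground_truth.json` with per-window ellipses.
#'
#' @param dataset Result of [make_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(dataset$windows)
  fn <- sprintf("w%04d.png", seq_len(n) - 1L)
  for (i in seq_len(n)) {
    png::writePNG(window_pixels(dataset$windows[[i]]) / 255,
                  file.path(dir, fn[i]))
  }
  utils::write.csv(data.frame(filename = fn, label = dataset$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  gt <- lapply(seq_len(n), function(i) {
    e <- dataset$ellipses[[i]]
    if (is.null(e)) list(filename = fn[i]) else c(list(filename = fn[i]), e)
  })
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
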