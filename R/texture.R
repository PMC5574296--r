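# Color-wavelet texture features: per-channel 3-level DWT, middle detail
# subbands, directional gray-level cooccurrence matrices, Haralick statistics.

#' Split an RGB window into its color channels
#'
#' @param window A [window()] object or a HxWx3 numeric array with values in
#'   \[0, 255\].
#' @return Named list of three HxW matrices: `r`, `g`, `b`.
#' @export
split_channels <- function(window) {
  px <- window_pixels(window)
  if (length(dim(px)) != 3L || dim(px)[3L] != 3L)
    stop("expected a 3-channel (RGB) image", call. = FALSE)
  list(r = px[, , 1L], g = px[, , 2L], b = px[, , 3L])
}

#' Select the middle detail subbands of three channel decompositions
#'
#' From each channel's 3-level decomposition keeps the three level-2 detail
#' images (indices 4, 5, 6 in the 1..9 detail numbering), giving nine images
#' in the fixed layout order channel (r, g, b) x subband (4, 5, 6).
#'
#' @param decomps Named list of three `channel_decomposition` objects keyed
#'   `r`, `g`, `b` (see [dwt3()]).
#' @return List of 9 matrices named e.g. `r4`, `r5`, ..., `b6`.
#' @export
select_middle_subbands <- function(decomps) {
  stopifnot(all(c("r", "g", "b") %in% names(decomps)))
  out <- list()
  for (ch in c("r", "g", "b")) {
    dc <- decomps[[ch]]
    stopifnot(inherits(dc, "channel_decomposition"), length(dc$details) == 9L)
    for (cl in 4:6) out[[paste0(ch, cl)]] <- dc$details[[cl]]
  }
  out
}

#' Quantize a real-valued subband to integer gray levels
#'
#' Linear min-max rescaling to `{0, ..., levels - 1}`. A constant input maps
#' to all zeros.
#'
#' @param subband Numeric matrix of finite values.
#' @param levels Number of gray levels `G >= 2`.
#' @return Integer matrix with values in `[0, levels - 1]`.
#' @export
quantize <- function(subband, levels = 32L) {
  if (levels < 2L) stop("levels must be >= 2", call. = FALSE)
  if (any(!is.finite(subband))) stop("non-finite values in subband", call. = FALSE)
  rng <- range(subband)
  if (rng[1L] == rng[2L]) {
    q <- matrix(0L, nrow(subband), ncol(subband))
  } else {
    q <- floor((subband - rng[1L]) / (rng[2L] - rng[1L]) * levels)
    q[q > levels - 1L] <- levels - 1L
    storage.mode(q) <- "integer"
  }
  q
}

.glcm_offsets <- c("0" = NA, "45" = NA, "90" = NA, "135" = NA)

#' Gray-level cooccurrence matrix
#'
#' Counts pairs of gray levels at a directed pixel offset, symmetrizes by
#' adding the transpose, and normalizes to sum 1. Directions follow the
#' usual image convention in (row, col) offsets: 0 deg is `(0, +d)`,
#' 45 deg `(-d, +d)`, 90 deg `(-d, 0)`, 135 deg `(-d, -d)`.
#'
#' @param qimage Integer matrix with values in `[0, levels - 1]`.
#' @param direction One of 0, 45, 90, 135 (degrees).
#' @param distance Positive integer pixel offset `d`.
#' @param levels Number of gray levels `G`.
#' @return Object of class `glcm`: `G x G` matrix summing to 1, with
#'   attributes `direction`, `distance`, `levels`.
#' @export
compute_glcm <- function(qimage, direction, distance = 1L, levels = 32L) {
  direction <- as.character(direction)
  d <- as.integer(distance)
  stopifnot(d >= 1L)
  off <- switch(direction,
    "0"   = c(0L,  d),
    "45"  = c(-d,  d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d),
    stop("direction must be one of 0, 45, 90, 135", call. = FALSE))
  if (any(qimage < 0L) || any(qimage >= levels))
    stop("pixel values must lie in [0, levels - 1]", call. = FALSE)
  nr <- nrow(qimage); nc <- ncol(qimage)
  dr <- off[1L]; dc <- off[2L]
  rows <- seq.int(max(1L, 1L - dr), min(nr, nr - dr))
  cols <- seq.int(max(1L, 1L - dc), min(nc, nc - dc))
  if (length(rows) < 1L || length(cols) < 1L)
    stop("image too small for the requested offset", call. = FALSE)
  i <- qimage[rows, cols, drop = FALSE]
  j <- qimage[rows + dr, cols + dc, drop = FALSE]
  counts <- tabulate(as.integer(i) * levels + as.integer(j) + 1L,
                     nbins = levels * levels)
  m <- matrix(counts, levels, levels, byrow = TRUE)  # row index = i, col = j
  m <- m + t(m)
  m <- m / sum(m)
  structure(m, class = c("glcm", "matrix"),
            direction = as.numeric(direction), distance = d, levels = levels)
}

#' Haralick statistics of a cooccurrence matrix
#'
#' Computes the four scalar texture descriptors used by the window
#' classifier. With \eqn{p(i,j)} the normalized entries and \eqn{\mu, \sigma}
#' the marginal mean and standard deviation:
#' \itemize{
#'   \item energy (angular second moment): \eqn{\sum p(i,j)^2}
#'   \item entropy: \eqn{-\sum p(i,j) \log_2 p(i,j)}, with \eqn{0 \log 0 = 0}
#'   \item homogeneity (inverse difference moment):
#'     \eqn{\sum p(i,j) / (1 + |i-j|)}
#'   \item correlation:
#'     \eqn{\sum (i-\mu_i)(j-\mu_j) p(i,j) / (\sigma_i \sigma_j)}, defined as
#'     1 when \eqn{\sigma_i \sigma_j = 0} (a constant image is treated as
#'     perfectly correlated)
#' }
#'
#' @param glcm A normalized cooccurrence matrix (class `glcm` or plain
#'   matrix summing to 1).
#' @return Named numeric vector `c(correlation, energy, homogeneity,
#'   entropy)`.
#' @export
haralick_stats <- function(glcm) {
  p <- unclass(glcm)
  G <- nrow(p)
  i <- matrix(seq_len(G) - 1, G, G)
  j <- t(i)
  energy <- sum(p^2)
  nz <- p > 0
  entropy <- -sum(p[nz] * log2(p[nz]))
  homogeneity <- sum(p / (1 + abs(i - j)))
  pi_ <- rowSums(p); pj <- colSums(p)
  mu_i <- sum((seq_len(G) - 1) * pi_); mu_j <- sum((seq_len(G) - 1) * pj)
  var_i <- sum(((seq_len(G) - 1) - mu_i)^2 * pi_)
  var_j <- sum(((seq_len(G) - 1) - mu_j)^2 * pj)
  s <- sqrt(var_i * var_j)
  correlation <- if (s == 0) 1 else sum((i - mu_i) * (j - mu_j) * p) / s
  c(correlation = correlation, energy = energy,
    homogeneity = homogeneity, entropy = entropy)
}

#' Color-wavelet texture features of a window
#'
#' The full hand-crafted feature path: split the window into R, G, B
#' channels; 3-level 2-D DWT per channel; keep the level-2 detail subbands
#' (indices 4-6); quantize each to `glcm_levels` gray levels; cooccurrence
#' matrices in four directions; four Haralick statistics per matrix. The
#' result is a fixed-layout vector of 3 channels x 3 subbands x
#' 4 directions x 4 statistics = 144 features.
#'
#' @param window A [window()] object or HxWx3 array.
#' @param wavelet Wavelet family (default `"db3"`, the 6-tap Daubechies
#'   filter).
#' @param glcm_levels Gray levels for quantization (default 32).
#' @param glcm_distance Cooccurrence offset in pixels (default 1).
#' @return Named numeric vector of length 144, names like
#'   `r4.d0.energy`. Layout order: channel (r, g, b), subband (4, 5, 6),
#'   direction (0, 45, 90, 135), statistic (correlation, energy,
#'   homogeneity, entropy).
#' @examples
#' w <- window(array(runif(227 * 227 * 3, 0, 255), c(227, 227, 3)))
#' f <- extract_color_wavelet(w)
#' length(f)  # 144
#' @export
extract_color_wavelet <- function(window, wavelet = "db3", glcm_levels = 32L,
                                  glcm_distance = 1L) {
  channels <- split_channels(window)
  decomps <- lapply(channels, dwt3, wavelet = wavelet)
  subbands <- select_middle_subbands(decomps)
  dirs <- c(0, 45, 90, 135)
  stats_names <- c("correlation", "energy", "homogeneity", "entropy")
  out <- numeric(0)
  for (sb_name in names(subbands)) {
    q <- quantize(subbands[[sb_name]], glcm_levels)
    for (ang in dirs) {
      g <- compute_glcm(q, ang, glcm_distance, glcm_levels)
      st <- haralick_stats(g)
      names(st) <- paste0(sb_name, ".d", ang, ".", stats_names)
      out <- c(out, st)
    }
  }
  stopifnot(length(out) == 144L)
  out
}

#' Write per-window feature vectors to CSV
#'
#' One row per window: `frame_index`, `x`, `y`, then the feature columns.
#'
#' @param features Matrix (windows x features) or list of feature vectors.
#' @param windows List of [window()] objects the rows correspond to.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, windows, path) {
  if (is.list(features)) features <- do.call(rbind, features)
  meta <- t(vapply(windows, function(w)
    c(frame_index = w$frame_index, x = w$origin[1L], y = w$origin[2L]),
    numeric(3)))
  df <- data.frame(meta, features, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
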