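# Multilevel 2-D discrete wavelet transform with symmetric boundary extension.
# Orthogonal Daubechies filter banks; coefficients stored to full double precision.

.wavelet_filters <- list(
  db1 = list(
    dec_lo = c(0.70710678118654757, 0.70710678118654757),
    dec_hi = c(-0.70710678118654757, 0.70710678118654757),
    rec_lo = c(0.70710678118654757, 0.70710678118654757),
    rec_hi = c(0.70710678118654757, -0.70710678118654757)),
  db2 = list(
    dec_lo = c(-0.12940952255126037, 0.22414386804201339, 0.83651630373780794, 0.48296291314453416),
    dec_hi = c(-0.48296291314453416, 0.83651630373780794, -0.22414386804201339, -0.12940952255126037),
    rec_lo = c(0.48296291314453416, 0.83651630373780794, 0.22414386804201339, -0.12940952255126037),
    rec_hi = c(-0.12940952255126037, -0.22414386804201339, 0.83651630373780794, -0.48296291314453416)),
  db3 = list(
    dec_lo = c(0.035226291885709533, -0.085441273882026658, -0.13501102001025458, 0.45987750211849154, 0.80689150931109255, 0.33267055295008263),
    dec_hi = c(-0.33267055295008263, 0.80689150931109255, -0.45987750211849154, -0.13501102001025458, 0.085441273882026658, 0.035226291885709533),
    rec_lo = c(0.33267055295008263, 0.80689150931109255, 0.45987750211849154, -0.13501102001025458, -0.085441273882026658, 0.035226291885709533),
    rec_hi = c(0.035226291885709533, 0.085441273882026658, -0.13501102001025458, -0.45987750211849154, 0.80689150931109255, -0.33267055295008263)),
  db4 = list(
    dec_lo = c(-0.010597401785069032, 0.032883011666885197, 0.030841381835560764, -0.18703481171909309, -0.027983769416859854, 0.63088076792985892, 0.71484657055291567, 0.23037781330889651),
    dec_hi = c(-0.23037781330889651, 0.71484657055291567, -0.63088076792985892, -0.027983769416859854, 0.18703481171909309, 0.030841381835560764, -0.032883011666885197, -0.010597401785069032),
    rec_lo = c(0.23037781330889651, 0.71484657055291567, 0.63088076792985892, -0.027983769416859854, -0.18703481171909309, 0.030841381835560764, 0.032883011666885197, -0.010597401785069032),
    rec_hi = c(-0.010597401785069032, -0.032883011666885197, 0.030841381835560764, 0.18703481171909309, -0.027983769416859854, -0.63088076792985892, 0.71484657055291567, -0.23037781330889651)),
  db5 = list(
    dec_lo = c(0.0033357252854737712, -0.012580751999081999, -0.0062414902127982744, 0.077571493840045719, -0.032244869584638375, -0.24229488706638203, 0.13842814590132074, 0.72430852843777294, 0.60382926979718965, 0.16010239797419293),
    dec_hi = c(-0.16010239797419293, 0.60382926979718965, -0.72430852843777294, 0.13842814590132074, 0.24229488706638203, -0.032244869584638375, -0.077571493840045719, -0.0062414902127982744, 0.012580751999081999, 0.0033357252854737712),
    rec_lo = c(0.16010239797419293, 0.60382926979718965, 0.72430852843777294, 0.13842814590132074, -0.24229488706638203, -0.032244869584638375, 0.077571493840045719, -0.0062414902127982744, -0.012580751999081999, 0.0033357252854737712),
    rec_hi = c(0.0033357252854737712, 0.012580751999081999, -0.0062414902127982744, -0.077571493840045719, -0.032244869584638375, 0.24229488706638203, 0.13842814590132074, -0.72430852843777294, 0.60382926979718965, -0.16010239797419293)),
  db6 = list(
    dec_lo = c(-0.0010773010853084796, 0.0047772575109455108, 0.00055384220116149613, -0.03158203931748603, 0.027522865530305727, 0.097501605587323043, -0.12976686756726194, -0.22626469396543983, 0.31525035170919763, 0.75113390802109536, 0.49462389039845306, 0.11154074335010947),
    dec_hi = c(-0.11154074335010947, 0.49462389039845306, -0.75113390802109536, 0.31525035170919763, 0.22626469396543983, -0.12976686756726194, -0.097501605587323043, 0.027522865530305727, 0.03158203931748603, 0.00055384220116149613, -0.0047772575109455108, -0.0010773010853084796),
    rec_lo = c(0.11154074335010947, 0.49462389039845306, 0.75113390802109536, 0.31525035170919763, -0.22626469396543983, -0.12976686756726194, 0.097501605587323043, 0.027522865530305727, -0.03158203931748603, 0.00055384220116149613, 0.0047772575109455108, -0.0010773010853084796),
    rec_hi = c(-0.0010773010853084796, -0.0047772575109455108, 0.00055384220116149613, 0.03158203931748603, 0.027522865530305727, -0.097501605587323043, -0.12976686756726194, 0.22626469396543983, 0.31525035170919763, -0.75113390802109536, 0.49462389039845306, -0.11154074335010947)),
  db8 = list(
    dec_lo = c(-0.00011747678412476953, 0.00067544940645056933, -0.00039174037337694705, -0.0048703529934515741, 0.0087460940474057766, 0.013981027917398282, -0.044088253930794755, -0.017369301001807547, 0.12874742662047847, 0.00047248457391328279, -0.28401554296154691, -0.015829105256349306, 0.58535468365420673, 0.67563073629728976, 0.31287159091429995, 0.054415842243104008),
    dec_hi = c(-0.054415842243104008, 0.31287159091429995, -0.67563073629728976, 0.58535468365420673, 0.015829105256349306, -0.28401554296154691, -0.00047248457391328279, 0.12874742662047847, 0.017369301001807547, -0.044088253930794755, -0.013981027917398282, 0.0087460940474057766, 0.0048703529934515741, -0.00039174037337694705, -0.00067544940645056933, -0.00011747678412476953),
    rec_lo = c(0.054415842243104008, 0.31287159091429995, 0.67563073629728976, 0.58535468365420673, -0.015829105256349306, -0.28401554296154691, 0.00047248457391328279, 0.12874742662047847, -0.017369301001807547, -0.044088253930794755, 0.013981027917398282, 0.0087460940474057766, -0.0048703529934515741, -0.00039174037337694705, 0.00067544940645056933, -0.00011747678412476953),
    rec_hi = c(-0.00011747678412476953, -0.00067544940645056933, -0.00039174037337694705, 0.0048703529934515741, 0.0087460940474057766, -0.013981027917398282, -0.044088253930794755, 0.017369301001807547, 0.12874742662047847, -0.00047248457391328279, -0.28401554296154691, 0.015829105256349306, 0.58535468365420673, -0.67563073629728976, 0.31287159091429995, -0.054415842243104008))
)

wavelet_filter_bank <- function(wavelet) {
  fb <- .wavelet_filters[[wavelet]]
  if (is.null(fb)) {
    stop("unknown wavelet family '", wavelet, "'; available: ",
         paste(names(.wavelet_filters), collapse = ", "), call. = FALSE)
  }
  fb
}

# Symmetric (half-sample) extension by `len` samples on each side.
.sym_ext <- function(x, len) {
  n <- length(x)
  if (len == 0L) return(x)
  left <- rev(x[seq_len(min(len, n))])
  right <- rev(x[seq.int(max(1L, n - len + 1L), n)])
  while (length(left) < len) left <- c(left, rev(left))[seq_len(len)]
  c(left, x, right)
}

#' Single-level 1-D discrete wavelet transform
#'
#' Decomposes a signal into approximation and detail coefficients using
#' symmetric boundary extension. Coefficient length is
#' `floor((n + L - 1) / 2)` for filter length `L`, so [idwt1()] reconstructs
#' the input exactly (orthogonal filters, machine precision).
#'
#' @param x Numeric vector, length >= 2.
#' @param wavelet Wavelet family name, e.g. `"db3"` (the 6-tap Daubechies
#'   filter, the package default throughout).
#' @return List with components `a` (approximation) and `d` (detail).
#' @seealso [idwt1()], [dwt3()]
#' @export
dwt1 <- function(x, wavelet = "db3") {
  fb <- wavelet_filter_bank(wavelet)
  L <- length(fb$dec_lo)
  n <- length(x)
  if (n < 2L) stop("signal too short for dwt", call. = FALSE)
  ext <- .sym_ext(x, L - 1L)
  nc <- (n + L - 1L) %/% 2L
  ya <- stats::convolve(ext, rev(fb$dec_lo), type = "open")
  yd <- stats::convolve(ext, rev(fb$dec_hi), type = "open")
  idx <- seq.int(L + 1L, by = 2L, length.out = nc)
  list(a = ya[idx], d = yd[idx])
}

#' Single-level inverse 1-D discrete wavelet transform
#'
#' @param a,d Approximation and detail coefficient vectors from [dwt1()].
#' @param n Original signal length to truncate to.
#' @param wavelet Wavelet family name.
#' @return Numeric vector of length `n`.
#' @export
idwt1 <- function(a, d, n, wavelet = "db3") {
  fb <- wavelet_filter_bank(wavelet)
  L <- length(fb$rec_lo)
  nc <- length(a)
  stopifnot(length(d) == nc)
  ua <- numeric(2L * nc); ua[seq.int(1L, by = 2L, length.out = nc)] <- a
  ud <- numeric(2L * nc); ud[seq.int(1L, by = 2L, length.out = nc)] <- d
  full <- stats::convolve(ua, rev(fb$rec_lo), type = "open") +
    stats::convolve(ud, rev(fb$rec_hi), type = "open")
  out_len <- 2L * nc - L + 2L
  out <- full[seq.int(L - 1L, length.out = out_len)]
  out[seq_len(n)]
}

.dwt1_mat_cols <- function(m, fb) {
  # transform every column of m at once; returns list(a, d) of matrices
  n <- nrow(m); L <- length(fb$dec_lo)
  ext <- apply(m, 2L, .sym_ext, len = L - 1L)
  nc <- (n + L - 1L) %/% 2L
  idx <- seq.int(L + 1L, by = 2L, length.out = nc)
  conv_cols <- function(f) {
    y <- apply(ext, 2L, function(col) stats::convolve(col, rev(f), type = "open"))
    y[idx, , drop = FALSE]
  }
  list(a = conv_cols(fb$dec_lo), d = conv_cols(fb$dec_hi))
}

#' Single-level 2-D discrete wavelet transform
#'
#' Separable 2-D transform: columns first, then rows. Subband names follow
#' the usual convention: `h` (horizontal detail, low-pass rows / high-pass
#' columns) responds to horizontal edges, `v` to vertical edges, `d` to
#' diagonal structure.
#'
#' @param m Numeric matrix (rows x cols), at least 2 in each dimension.
#' @param wavelet Wavelet family name.
#' @return List with `a` (approximation), `h`, `v`, `d` detail matrices.
#' @export
dwt2 <- function(m, wavelet = "db3") {
  fb <- wavelet_filter_bank(wavelet)
  cols <- .dwt1_mat_cols(m, fb)                    # along rows (vertical axis)
  lo_t <- .dwt1_mat_cols(t(cols$a), fb)            # along columns
  hi_t <- .dwt1_mat_cols(t(cols$d), fb)
  list(a = t(lo_t$a),   # low-pass both axes
       h = t(hi_t$a),   # high-pass down columns: horizontal edges
       v = t(lo_t$d),   # high-pass along rows: vertical edges
       d = t(hi_t$d))
}

#' Single-level inverse 2-D discrete wavelet transform
#'
#' @param sub List with `a`, `h`, `v`, `d` as returned by [dwt2()].
#' @param dims Original `c(nrow, ncol)` to truncate to.
#' @param wavelet Wavelet family name.
#' @return Reconstructed matrix of dimension `dims`.
#' @export
idwt2 <- function(sub, dims, wavelet = "db3") {
  nr <- dims[1L]; nc_ <- dims[2L]
  inv_cols <- function(a, d, n) {
    out <- matrix(0, n, ncol(a))
    for (j in seq_len(ncol(a))) out[, j] <- idwt1(a[, j], d[, j], n, wavelet)
    out
  }
  # invert the row-direction transform (restore column count)
  lo <- t(inv_cols(t(sub$a), t(sub$v), nc_))
  hi <- t(inv_cols(t(sub$h), t(sub$d), nc_))
  inv_cols(lo, hi, nr)
}

#' Three-level 2-D wavelet decomposition of a single channel
#'
#' Applies [dwt2()] recursively to the approximation. The nine detail images
#' are indexed 1..9: indices 1-3 are the level-1 (horizontal, vertical,
#' diagonal) details, 4-6 level-2, 7-9 level-3. The middle triplet (4-6)
#' feeds the cooccurrence texture features; see [select_middle_subbands()].
#'
#' @param channel Numeric matrix, at least 8x8.
#' @param wavelet Wavelet family name.
#' @return Object of class `channel_decomposition`: list with `approx`
#'   (level-3 approximation), `details` (list of 9 matrices), `dims`
#'   (per-level input dimensions, used by [idwt3()]), `wavelet`.
#' @export
dwt3 <- function(channel, wavelet = "db3") {
  channel <- as.matrix(channel)
  if (any(!is.finite(channel))) stop("non-finite values in channel", call. = FALSE)
  if (nrow(channel) < 8L || ncol(channel) < 8L)
    stop("channel must be at least 8x8 for a 3-level decomposition", call. = FALSE)
  details <- vector("list", 9L)
  dims <- vector("list", 3L)
  cur <- channel
  for (lev in 1:3) {
    dims[[lev]] <- dim(cur)
    s <- dwt2(cur, wavelet)
    details[[3L * (lev - 1L) + 1L]] <- s$h
    details[[3L * (lev - 1L) + 2L]] <- s$v
    details[[3L * (lev - 1L) + 3L]] <- s$d
    cur <- s$a
  }
  structure(list(approx = cur, details = details, dims = dims, wavelet = wavelet),
            class = "channel_decomposition")
}

#' Invert a three-level decomposition
#'
#' @param decomp A `channel_decomposition` from [dwt3()].
#' @return The reconstructed channel matrix.
#' @export
idwt3 <- function(decomp) {
  stopifnot(inherits(decomp, "channel_decomposition"))
  cur <- decomp$approx
  for (lev in 3:1) {
    sub <- list(a = cur,
                h = decomp$details[[3L * (lev - 1L) + 1L]],
                v = decomp$details[[3L * (lev - 1L) + 2L]],
                d = decomp$details[[3L * (lev - 1L) + 3L]])
    cur <- idwt2(sub, decomp$dims[[lev]], decomp$wavelet)
  }
  cur
}
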