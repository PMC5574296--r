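# Color-wavelet texture path: channel split, subband selection,
# quantization, cooccurrence matrices, Haralick statistics, and the
# 144-feature extractor.

test_that("split_channels separates and preserves pixel content", {
  red <- array(0, c(227, 227, 3)); red[, , 1] <- 255
  ch <- split_channels(window(red))
  expect_true(all(ch$r == 255) && all(ch$g == 0) && all(ch$b == 0))

  gray <- array(rep(matrix(131, 227, 227), 3), c(227, 227, 3))
  ch <- split_channels(window(gray))
  expect_identical(ch$r, ch$g)
  expect_identical(ch$g, ch$b)

  w <- test_window(3)
  ch <- split_channels(w)
  set.seed(42)
  for (k in 1:20) {
    i <- sample(227, 1); j <- sample(227, 1)
    expect_identical(ch$r[i, j], w$pixels[i, j, 1])
    expect_identical(ch$b[i, j], w$pixels[i, j, 3])
  }
  expect_error(split_channels(matrix(0, 227, 227)), "3-channel")
})

test_that("middle-subband selection keeps exactly CL 4-6 per channel", {
  w <- test_window(4, side = 64)
  decomps <- lapply(split_channels(w), dwt3)
  sel <- select_middle_subbands(decomps)
  expect_length(sel, 9L)
  expect_named(sel, c("r4", "r5", "r6", "g4", "g5", "g6", "b4", "b5", "b6"))
  expect_identical(sel$r4, decomps$r$details[[4L]])
  expect_identical(sel$b6, decomps$b$details[[6L]])
  # perturbing the unused subbands leaves the selection unchanged
  perturbed <- decomps
  for (cl in c(1:3, 7:9)) perturbed$g$details[[cl]] <- perturbed$g$details[[cl]] + 99
  expect_identical(select_middle_subbands(perturbed), sel)
})

test_that("quantization follows the linear min-max rule", {
  expect_true(all(quantize(matrix(3.7, 10, 10), 32) == 0L))
  expect_identical(as.vector(quantize(matrix(c(-1, 0, 1), 1), 3)), c(0L, 1L, 2L))
  ramp <- matrix(seq(0, 1, length.out = 64 * 64), 64, 64)
  q <- quantize(ramp, 32)
  expect_setequal(unique(as.vector(q)), 0:31)   # every level occupied
  expect_error(quantize(matrix(c(1, NA), 1), 8), "non-finite")
})

test_that("cooccurrence matrices match hand-enumerated pair counts", {
  m <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  g <- compute_glcm(m, 0, 1, 2)
  expect_equal(unclass(g)[], matrix(c(0.5, 0, 0, 0.5), 2, 2), ignore_attr = TRUE)
  m2 <- matrix(c(0, 1, 0, 1), 2, 2, byrow = TRUE)
  g2 <- compute_glcm(m2, 90, 1, 2)
  expect_equal(diag(unclass(g2)), c(0.5, 0.5))
})

test_that("cooccurrence matrices equal the brute-force oracle", {
  set.seed(11)
  for (rep in 1:25) {
    G <- sample(2:8, 1)
    nr <- sample(4:16, 1); nc <- sample(4:16, 1)
    img <- matrix(sample(0:(G - 1L), nr * nc, replace = TRUE), nr, nc)
    d <- sample(1:2, 1)
    for (ang in c(0, 45, 90, 135)) {
      fast <- unclass(compute_glcm(img, ang, d, G))
      slow <- glcm_oracle(img, ang, d, G)
      expect_equal(fast, slow, ignore_attr = TRUE,
                   info = sprintf("G=%d %dx%d ang=%d d=%d", G, nr, nc, ang, d))
      expect_equal(sum(fast), 1)
      expect_equal(fast, t(fast), ignore_attr = TRUE)
    }
  }
})

test_that("Haralick statistics match closed forms and the summation oracle", {
  # degenerate: all mass at one cell (constant image)
  p <- matrix(0, 4, 4); p[1, 1] <- 1
  st <- haralick_stats(p)
  expect_equal(unname(st), c(1, 1, 1, 0))

  # two-point diagonal
  st <- haralick_stats(diag(c(0.5, 0.5)))
  expect_equal(unname(st), c(1, 0.5, 1, 1))

  # uniform GxG
  for (G in c(2, 5, 8)) {
    p <- matrix(1 / G^2, G, G)
    st <- haralick_stats(p)
    expect_equal(unname(st["energy"]), 1 / G^2)
    expect_equal(unname(st["entropy"]), 2 * log2(G))
    expect_equal(unname(st["correlation"]), 0)
  }

  set.seed(21)
  for (rep in 1:20) {
    G <- sample(2:12, 1)
    raw <- matrix(stats::rexp(G * G), G, G)
    p <- raw + t(raw); p <- p / sum(p)
    expect_equal(haralick_stats(p), haralick_oracle(p), tolerance = 1e-12)
  }
})

test_that("the extractor emits 144 features deterministically", {
  w <- test_window(9)
  f1 <- extract_color_wavelet(w)
  f2 <- extract_color_wavelet(w)
  expect_length(f1, 144L)
  expect_identical(f1, f2)
  expect_true(all(is.finite(f1)))
  en <- f1[grepl("energy", names(f1))]
  ho <- f1[grepl("homogeneity", names(f1))]
  et <- f1[grepl("entropy", names(f1))]
  expect_true(all(en > 0 & en <= 1))
  expect_true(all(ho > 0 & ho <= 1))
  expect_true(all(et >= 0))
  expect_length(en, 36L)   # one energy per cooccurrence matrix
})

test_that("swapping the r and b channels permutes the feature blocks", {
  w <- test_window(13)
  swapped <- w
  swapped$pixels <- w$pixels[, , c(3, 2, 1)]
  f <- extract_color_wavelet(w)
  fs <- extract_color_wavelet(swapped)
  expect_equal(unname(fs[1:48]), unname(f[97:144]))
  expect_equal(unname(fs[97:144]), unname(f[1:48]))
  expect_equal(unname(fs[49:96]), unname(f[49:96]))
})

test_that("feature vectors depend only on pixels, not window placement", {
  w <- test_window(17)
  moved <- window(w$pixels, origin = c(50L, 80L), frame_index = 7L)
  expect_identical(extract_color_wavelet(w), extract_color_wavelet(moved))
})
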