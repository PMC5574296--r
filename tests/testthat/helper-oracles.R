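# Independent brute-force oracles the fast implementations are checked against.

# Cooccurrence matrix by explicit pair enumeration: nested loops over every
# pixel, counting the directed pair and its reverse, then normalizing.
glcm_oracle <- function(qimage, direction, distance, levels) {
  off <- switch(as.character(direction),
    "0"   = c(0L,  distance),
    "45"  = c(-distance,  distance),
    "90"  = c(-distance, 0L),
    "135" = c(-distance, -distance))
  m <- matrix(0, levels, levels)
  nr <- nrow(qimage); nc <- ncol(qimage)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    r2 <- r + off[1L]; c2 <- cc + off[2L]
    if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
      i <- qimage[r, cc] + 1L; j <- qimage[r2, c2] + 1L
      m[i, j] <- m[i, j] + 1
      m[j, i] <- m[j, i] + 1
    }
  }
  m / sum(m)
}

# Haralick statistics by direct elementwise summation.
haralick_oracle <- function(p) {
  G <- nrow(p)
  energy <- 0; entropy <- 0; homogeneity <- 0
  for (i in seq_len(G)) for (j in seq_len(G)) {
    v <- p[i, j]
    energy <- energy + v^2
    if (v > 0) entropy <- entropy - v * log2(v)
    homogeneity <- homogeneity + v / (1 + abs(i - j))
  }
  mu_i <- 0; mu_j <- 0
  for (i in seq_len(G)) for (j in seq_len(G)) {
    mu_i <- mu_i + (i - 1) * p[i, j]
    mu_j <- mu_j + (j - 1) * p[i, j]
  }
  var_i <- 0; var_j <- 0
  for (i in seq_len(G)) for (j in seq_len(G)) {
    var_i <- var_i + (i - 1 - mu_i)^2 * p[i, j]
    var_j <- var_j + (j - 1 - mu_j)^2 * p[i, j]
  }
  s <- sqrt(var_i * var_j)
  correlation <- if (s == 0) 1 else {
    acc <- 0
    for (i in seq_len(G)) for (j in seq_len(G))
      acc <- acc + (i - 1 - mu_i) * (j - 1 - mu_j) * p[i, j]
    acc / s
  }
  c(correlation = correlation, energy = energy,
    homogeneity = homogeneity, entropy = entropy)
}

# Confusion-matrix counter by explicit looping.
confusion_oracle <- function(pred, truth, positive) {
  tp <- fp <- tn <- fn <- 0L
  for (k in seq_along(pred)) {
    if (pred[k] == positive && truth[k] == positive) tp <- tp + 1L
    if (pred[k] == positive && truth[k] != positive) fp <- fp + 1L
    if (pred[k] != positive && truth[k] == positive) fn <- fn + 1L
    if (pred[k] != positive && truth[k] != positive) tn <- tn + 1L
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# A deterministic random-ish RGB window for feature tests.
test_window <- function(seed = 1L, side = 227L) {
  set.seed(seed)
  window(array(sample(0:255, side * side * 3L, replace = TRUE),
               c(side, side, 3L)))
}
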