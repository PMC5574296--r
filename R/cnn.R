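# CNN feature extractor: AlexNet-style network on 227x227 RGB windows whose
# second fully connected layer provides a 4096-dimensional learned
# representation of each window.

#' The window classifier's network architecture
#'
#' Fixed layer sequence for 227x227x3 input:
#' conv(96, 11x11, stride 4, pad 0) - relu - maxpool(3x3, stride 2) -
#' conv(256, 5x5, stride 1, pad 2) - relu - maxpool(3x3, stride 2) -
#' conv(384, 3x3, stride 1, pad 1) - relu - conv(384, 3x3) - relu -
#' conv(256, 3x3) - relu - maxpool(3x3, stride 2) - dense(4096) - relu -
#' dense(4096) - relu - dense(n_classes) - softmax.
#'
#' @param n_classes Output classes (default 2: polyp / nonpolyp).
#' @return List of layer descriptors (class `network_spec`).
#' @export
network_spec <- function(n_classes = 2L) {
  conv <- function(filters, kernel, stride = 1L, pad = 0L)
    list(type = "conv", filters = filters, kernel = kernel,
         stride = stride, pad = pad)
  pool <- function(kernel = 3L, stride = 2L)
    list(type = "maxpool", kernel = kernel, stride = stride)
  relu_ <- list(type = "relu")
  dense <- function(units) list(type = "dense", units = units)
  structure(list(
    conv(96L, 11L, stride = 4L, pad = 0L), relu_, pool(),
    conv(256L, 5L, stride = 1L, pad = 2L), relu_, pool(),
    conv(384L, 3L, stride = 1L, pad = 1L), relu_,
    conv(384L, 3L, stride = 1L, pad = 1L), relu_,
    conv(256L, 3L, stride = 1L, pad = 1L), relu_, pool(),
    dense(4096L), relu_, dense(4096L), relu_,
    dense(as.integer(n_classes)), list(type = "softmax")),
    class = "network_spec", input = c(227L, 227L, 3L))
}

# Closed-form output shape chain (used for validation and tests).
.spec_shapes <- function(spec) {
  dims <- attr(spec, "input")
  h <- dims[1L]; w <- dims[2L]; c <- dims[3L]
  flat <- NA_integer_
  out <- list()
  for (i in seq_along(spec)) {
    L <- spec[[i]]
    if (L$type == "conv") {
      h <- (h + 2L * L$pad - L$kernel) %/% L$stride + 1L
      w <- (w + 2L * L$pad - L$kernel) %/% L$stride + 1L
      c <- L$filters
    } else if (L$type == "maxpool") {
      h <- (h - L$kernel) %/% L$stride + 1L
      w <- (w - L$kernel) %/% L$stride + 1L
    } else if (L$type == "dense") {
      if (is.na(flat)) flat <- h * w * c
      flat <- L$units
    }
    out[[i]] <- if (is.na(flat)) c(h, w, c) else flat
  }
  out
}

.init_weights <- function(spec) {
  shapes <- .spec_shapes(spec)
  dims <- attr(spec, "input")
  in_c <- dims[3L]; fan_flat <- NA_integer_
  weights <- vector("list", length(spec))
  for (i in seq_along(spec)) {
    L <- spec[[i]]
    if (L$type == "conv") {
      fan_in <- L$kernel^2 * in_c
      W <- matrix(stats::rnorm(L$filters * fan_in, sd = sqrt(2 / fan_in)),
                  L$filters, fan_in)
      weights[[i]] <- list(W = W, b = numeric(L$filters))
      in_c <- L$filters
      fan_flat <- prod(shapes[[i]])
    } else if (L$type == "maxpool") {
      fan_flat <- prod(shapes[[i]])
    } else if (L$type == "dense") {
      fan_in <- fan_flat
      W <- matrix(stats::rnorm(L$units * fan_in, sd = sqrt(2 / fan_in)),
                  L$units, fan_in)
      weights[[i]] <- list(W = W, b = numeric(L$units))
      fan_flat <- L$units
    }
  }
  weights
}

#' Build the window-classification network
#'
#' He-style random initialization, fully determined by `seed`.
#'
#' @param spec Architecture from [network_spec()].
#' @param seed Integer seed controlling initialization.
#' @return Object of class `polyp_cnn` holding the spec, the weight
#'   tensors, preprocessing channel means, and training metadata.
#' @export
build_network <- function(spec = network_spec(), seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  net <- structure(list(spec = spec, weights = .init_weights(spec),
                        channel_means = c(0, 0, 0),
                        training = list(seed = seed, epochs = 0L,
                                        loss = numeric(0)),
                        env = new.env(parent = emptyenv())),
                   class = "polyp_cnn")
  net
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Live C++ handle for a network; rebuilt on demand (external pointers do not
# survive serialization).
.net_ptr <- function(net, refresh = FALSE) {
  if (!refresh && !is.null(net$env$ptr) && ptr_is_valid(net$env$ptr))
    return(net$env$ptr)
  ptr <- cnn_create(unclass(net$spec), net$weights)
  net$env$ptr <- ptr
  ptr
}

#' Rectified linear activation
#'
#' @param x Numeric vector or array.
#' @return `max(0, x)` elementwise.
#' @export
relu <- function(x) pmax(x, 0)

#' Numerically stable softmax
#'
#' @param logits Numeric vector of finite values.
#' @return Probabilities summing to 1; invariant to additive shifts of
#'   `logits`.
#' @export
softmax <- function(logits) {
  e <- exp(logits - max(logits))
  e / sum(e)
}

# Scale to [0,1] and subtract per-channel means (preprocessing contract of
# the network).
.preprocess_window <- function(w, channel_means) {
  px <- window_pixels(w) / 255
  for (k in 1:3) px[, , k] <- px[, , k] - channel_means[k]
  px
}

#' Train the window-classification network
#'
#' Minibatch stochastic gradient descent with momentum on the softmax
#' cross-entropy. All randomness (shuffling) is drawn from R's RNG, so a
#' fixed `seed` makes training bit-reproducible.
#'
#' @param net A `polyp_cnn` from [build_network()].
#' @param windows List of 227x227 [window()] objects.
#' @param labels Factor or character vector, one label per window; at least
#'   two classes must be present.
#' @param epochs Training epochs (default 10).
#' @param lr Learning rate (default 1e-3).
#' @param momentum Momentum coefficient (default 0.9).
#' @param batch_size Minibatch size (default 32).
#' @param seed Integer seed for shuffling.
#' @return The trained `polyp_cnn`; `$training$loss` holds the per-epoch
#'   mean cross-entropy.
#' @export
train_network <- function(net, windows, labels, epochs = 10L, lr = 1e-3,
                          momentum = 0.9, batch_size = 32L, seed = 1L) {
  stopifnot(inherits(net, "polyp_cnn"))
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L)
    stop("training labels contain a single class", call. = FALSE)
  n <- length(windows)
  stopifnot(length(labels) == n, n >= 2L)
  sizes <- vapply(windows, function(w) dim(window_pixels(w))[1:2], integer(2))
  if (any(sizes != attr(net$spec, "input")[1L]))
    stop("all training windows must be 227x227", call. = FALSE)

  # channel means over the training set, on the [0,1] scale
  ch_sum <- c(0, 0, 0)
  for (w in windows) {
    px <- window_pixels(w)
    ch_sum <- ch_sum + c(mean(px[, , 1L]), mean(px[, , 2L]), mean(px[, , 3L]))
  }
  net$channel_means <- ch_sum / n / 255

  imgs <- lapply(windows, .preprocess_window, channel_means = net$channel_means)
  y <- as.integer(labels) - 1L

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  order_mat <- vapply(seq_len(epochs), function(e) sample.int(n),
                      integer(n))
  ptr <- .net_ptr(net, refresh = TRUE)
  loss <- cnn_train_cpp(ptr, imgs, y, order_mat, lr, momentum,
                        as.integer(batch_size))
  net$weights <- cnn_get_weights_cpp(ptr)
  # drop the live handle so its memory can be reclaimed; it is rebuilt
  # lazily from the stored weights on the next forward pass
  net$env$ptr <- NULL
  rm(ptr, imgs)
  gc(verbose = FALSE)
  net$classes <- levels(labels)
  net$training <- list(seed = seed, epochs = as.integer(epochs),
                       lr = lr, momentum = momentum,
                       batch_size = as.integer(batch_size), loss = loss)
  net
}

#' Learned features of a window
#'
#' Post-ReLU activations of the network's second fully connected layer: a
#' nonnegative 4096-vector that is a pure function of the network weights
#' and the window pixels.
#'
#' @param net A `polyp_cnn` (trained or freshly initialized).
#' @param windows A single [window()] or a list of windows.
#' @return For one window, a numeric vector of length 4096; for a list, an
#'   n x 4096 matrix.
#' @export
extract_cnn_features <- function(net, windows) {
  stopifnot(inherits(net, "polyp_cnn"))
  single <- inherits(windows, "polyp_window") ||
    (is.array(windows) && length(dim(windows)) == 3L)
  if (single) windows <- list(windows)
  in_side <- attr(net$spec, "input")[1L]
  for (w in windows) {
    d <- dim(window_pixels(w))
    if (d[1L] != in_side || d[2L] != in_side || d[3L] != 3L)
      stop("window shape ", paste(d, collapse = "x"), " does not match the ",
           in_side, "x", in_side, "x3 network input", call. = FALSE)
  }
  imgs <- lapply(windows, .preprocess_window, channel_means = net$channel_means)
  feats <- cnn_features_cpp(.net_ptr(net), imgs, fc_tap = 2L)
  if (single) drop(feats[1L, ]) else feats
}

#' Class probabilities from the network head
#'
#' Runs the full forward pass, including the final softmax.
#'
#' @param net A `polyp_cnn`.
#' @param w A single [window()].
#' @return Probability vector over the network's classes.
#' @export
network_predict <- function(net, w) {
  img <- .preprocess_window(w, net$channel_means)
  res <- cnn_forward_cpp(.net_ptr(net), img, fc_tap = 0L)
  p <- res$output
  if (!is.null(net$classes)) names(p) <- net$classes
  p
}

#' Per-layer output shapes of a network's forward pass
#'
#' Runs one forward pass and returns the realized shape after every layer,
#' for checking against the closed-form convolution/pooling arithmetic.
#'
#' @param net A `polyp_cnn`.
#' @return List of integer vectors (HxWxC for spatial layers, a single
#'   width once flattened).
#' @export
network_shapes <- function(net) {
  dims <- attr(net$spec, "input")
  img <- array(0, dims)
  res <- cnn_forward_cpp(.net_ptr(net), img, fc_tap = 0L)
  res$shapes
}

#' @export
print.polyp_cnn <- function(x, ...) {
  n_par <- sum(vapply(x$weights, function(w)
    if (is.null(w)) 0L else length(w$W) + length(w$b), integer(1)))
  cat(sprintf("<polyp_cnn: %d layers, %s parameters, %s>\n",
              length(x$spec), format(n_par, big.mark = ","),
              if (x$training$epochs > 0)
                sprintf("trained %d epochs (final loss %.4f)",
                        x$training$epochs, utils::tail(x$training$loss, 1))
              else "untrained"))
  invisible(x)
}
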