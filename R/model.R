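# The fitted detector: a CNN feature extractor and a fused-feature linear
# SVM wrapped in one model object with the usual S3 surface.

#' Fit the polyp window detector
#'
#' Trains the full two-stage classifier on labelled 227x227 windows:
#' \enumerate{
#'   \item an AlexNet-style CNN is trained on the windows (softmax head,
#'     cross-entropy, SGD with momentum) and then frozen as a feature
#'     extractor — its second fully connected layer yields 4096 activations
#'     per window;
#'   \item 144 color-wavelet texture features are extracted per window
#'     (3-level DWT per color channel, cooccurrence matrices of the middle
#'     detail subbands, four Haralick statistics);
#'   \item both blocks are fused (4240 features), z-scored, and a linear
#'     SVM is fit on the result.
#' }
#'
#' @param windows List of 227x227 [window()] objects.
#' @param labels Factor or character labels (binary polyp/nonpolyp is the
#'   primary mode; more classes switch the SVM to one-vs-rest).
#' @param features Which feature families feed the SVM: `"fused"`
#'   (default), `"wavelet"`, or `"cnn"`. The CNN is trained in all modes
#'   that use it.
#' @param epochs,lr,momentum,batch_size CNN training hyperparameters; see
#'   [train_network()].
#' @param cost SVM soft-margin cost.
#' @param wavelet,glcm_levels,glcm_distance Color-wavelet parameters; see
#'   [extract_color_wavelet()].
#' @param positive_class Positive label for scores and metrics (default
#'   `"polyp"` if present).
#' @param seed Single integer seed controlling CNN initialization and
#'   shuffling; the whole fit is reproducible given `seed`.
#' @return Object of class `polyp_detector` with components `cnn`
#'   (the trained `polyp_cnn`, when used), `svm` (the `polyp_svm`),
#'   `features`, `config`, and `training_accuracy`.
#' @seealso [predict.polyp_detector()], [detect_frames()]
#' @export
polyp_detector <- function(windows, labels, features = c("fused", "wavelet", "cnn"),
                           epochs = 10L, lr = 1e-3, momentum = 0.9,
                           batch_size = 32L, cost = 1,
                           wavelet = "db3", glcm_levels = 32L,
                           glcm_distance = 1L, positive_class = NULL,
                           seed = 1L) {
  features <- match.arg(features)
  labels <- as.factor(labels)
  if (is.null(positive_class))
    positive_class <- if ("polyp" %in% levels(labels)) "polyp" else levels(labels)[1L]

  net <- NULL
  cnn_feats <- NULL
  if (features %in% c("fused", "cnn")) {
    net <- build_network(network_spec(nlevels(labels)), seed = seed)
    net <- train_network(net, windows, labels, epochs = epochs, lr = lr,
                         momentum = momentum, batch_size = batch_size,
                         seed = seed)
    cnn_feats <- extract_cnn_features(net, windows)
  }
  cw_feats <- NULL
  if (features %in% c("fused", "wavelet")) {
    cw_feats <- t(vapply(windows, extract_color_wavelet, numeric(144),
                         wavelet = wavelet, glcm_levels = glcm_levels,
                         glcm_distance = glcm_distance))
  }
  x <- switch(features,
              fused = fuse(cw_feats, cnn_feats),
              wavelet = cw_feats,
              cnn = cnn_feats)
  svm <- train_svm(x, labels, cost = cost, positive_class = positive_class,
                   seed = seed)
  train_pred <- predict(svm, x)
  model <- structure(list(
    cnn = net, svm = svm, features = features,
    config = list(epochs = epochs, lr = lr, momentum = momentum,
                  batch_size = batch_size, cost = cost, wavelet = wavelet,
                  glcm_levels = glcm_levels, glcm_distance = glcm_distance,
                  seed = seed),
    classes = levels(labels),
    training_accuracy = mean(train_pred$label == as.character(labels)),
    n_train = length(windows)),
    class = "polyp_detector")
  model
}

.model_features <- function(model, windows) {
  if (inherits(windows, "polyp_window")) windows <- list(windows)
  cw <- cnn <- NULL
  if (model$features %in% c("fused", "wavelet")) {
    cfg <- model$config
    cw <- t(vapply(windows, extract_color_wavelet, numeric(144),
                   wavelet = cfg$wavelet, glcm_levels = cfg$glcm_levels,
                   glcm_distance = cfg$glcm_distance))
  }
  if (model$features %in% c("fused", "cnn"))
    cnn <- rbind(extract_cnn_features(model$cnn, windows))
  switch(model$features, fused = fuse(cw, cnn), wavelet = cw, cnn = cnn)
}

#' Predict polyp labels for windows
#'
#' @param object A fitted [polyp_detector()].
#' @param windows A [window()] or list of windows.
#' @param ... Unused.
#' @return `data.frame` with one row per window: `label` and signed SVM
#'   `score` (positive = polyp side).
#' @export
predict.polyp_detector <- function(object, windows, ...) {
  predict(object$svm, .model_features(object, windows))
}

#' @export
print.polyp_detector <- function(x, ...) {
  cat(sprintf("<polyp_detector: %s features, %d training windows, training accuracy %.3f>\n",
              x$features, x$n_train, x$training_accuracy))
  invisible(x)
}

#' @export
summary.polyp_detector <- function(object, ...) {
  cat("Polyp window detector\n")
  cat("  feature mode   :", object$features, "\n")
  cat("  classes        :", paste(object$classes, collapse = ", "), "\n")
  cat("  svm input width:", length(object$svm$scaler$mean), "\n")
  if (!is.null(object$cnn)) {
    cat("  cnn            : trained", object$cnn$training$epochs,
        "epochs, final loss",
        sprintf("%.4f", utils::tail(object$cnn$training$loss, 1)), "\n")
  }
  cat("  training acc   :", sprintf("%.3f", object$training_accuracy), "\n")
  invisible(object)
}

#' Hyperplane coefficients of the fitted SVM stage
#'
#' @param object A fitted [polyp_detector()].
#' @param ... Unused.
#' @return Named list with `W` (weights, one row per hyperplane) and `b`.
#' @export
coef.polyp_detector <- function(object, ...) {
  list(W = object$svm$W, b = object$svm$b)
}

#' Training-loss curve of the CNN stage
#'
#' @param x A fitted [polyp_detector()] that includes the CNN.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.polyp_detector <- function(x, ...) {
  if (is.null(x$cnn) || length(x$cnn$training$loss) == 0L)
    stop("model has no CNN training history", call. = FALSE)
  loss <- x$cnn$training$loss
  graphics::plot(seq_along(loss), loss, type = "b", xlab = "epoch",
                 ylab = "mean cross-entropy", main = "CNN training loss", ...)
  invisible(x)
}

#' Save a fitted detector to disk
#'
#' Serializes the model (network spec and weights, SVM hyperplane, scaler,
#' label map, configuration) as a single-file archive readable with
#' [load_detector()].
#'
#' @param model A fitted [polyp_detector()].
#' @param path Output path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
save_detector <- function(model, path) {
  stopifnot(inherits(model, "polyp_detector"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a detector saved with [save_detector()]
#'
#' @param path Path to the archive.
#' @return The restored `polyp_detector`; the CNN's compute state is
#'   rebuilt lazily on first use.
#' @export
load_detector <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "polyp_detector"))
  if (!is.null(model$cnn)) model$cnn$env <- new.env(parent = emptyenv())
  model
}
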