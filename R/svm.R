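# Feature fusion and the linear SVM stage: concatenate the hand-crafted
# color-wavelet block with the learned CNN block, z-score per feature, and
# classify with a maximum-margin linear hyperplane.

#' Fuse color-wavelet and CNN feature blocks
#'
#' Concatenates the two blocks, color-wavelet first, giving the
#' 144 + 4096 = 4240-dimensional classifier input.
#'
#' @param cw Length-144 vector or n x 144 matrix of color-wavelet features.
#' @param cnn Length-4096 vector or n x 4096 matrix of CNN features.
#' @return Fused vector (or matrix) of width 4240.
#' @export
fuse <- function(cw, cnn) {
  if (is.matrix(cw) || is.matrix(cnn)) {
    cw <- rbind(cw); cnn <- rbind(cnn)
    if (ncol(cw) != 144L || ncol(cnn) != 4096L)
      stop("expected feature blocks of width 144 and 4096, got ",
           ncol(cw), " and ", ncol(cnn), call. = FALSE)
    if (nrow(cw) != nrow(cnn)) stop("row counts differ", call. = FALSE)
    return(cbind(cw, cnn))
  }
  if (length(cw) != 144L || length(cnn) != 4096L)
    stop("expected feature blocks of length 144 and 4096, got ",
         length(cw), " and ", length(cnn), call. = FALSE)
  c(cw, cnn)
}

#' Fit a per-feature standardizer
#'
#' Per-feature mean and population standard deviation from training data;
#' constant features get a standard deviation of 1 so scaling never divides
#' by zero.
#'
#' @param x Numeric matrix (samples x features), at least 2 rows.
#' @return List with `mean` and `sd` vectors (class `feature_scaler`).
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples to fit a scaler", call. = FALSE)
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2L, mu)^2))
  sdev[sdev == 0] <- 1
  structure(list(mean = mu, sd = sdev), class = "feature_scaler")
}

#' Apply a fitted standardizer
#'
#' @param scaler A `feature_scaler` from [fit_scaler()].
#' @param x Numeric vector or matrix of matching width.
#' @return Standardized copy of `x`.
#' @export
apply_scaler <- function(scaler, x) {
  if (is.matrix(x)) {
    sweep(sweep(x, 2L, scaler$mean), 2L, scaler$sd, "/")
  } else {
    (x - scaler$mean) / scaler$sd
  }
}

.fit_binary_hyperplane <- function(x, y01, cost) {
  # y01: logical, TRUE = positive class
  yf <- factor(ifelse(y01, "pos", "neg"), levels = c("pos", "neg"))
  fit <- e1071::svm(x, yf, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients the decision function toward the first factor level it
  # sees; normalize so positive scores mean the positive class
  if (fit$labels[1L] != 1L) { w <- -w; b <- -b }
  list(w = w, b = b)
}

#' Train the fused-feature linear SVM
#'
#' Standardizes features (z-score with the guard of [fit_scaler()]) and
#' fits a linear maximum-margin classifier; with more than two classes, one
#' one-vs-rest hyperplane per class.
#'
#' @param features Numeric matrix (samples x features), typically the
#'   4240-wide fused block from [fuse()].
#' @param labels Factor or character labels, >= 2 classes.
#' @param cost Soft-margin cost parameter C (default 1).
#' @param positive_class Label treated as the positive (polyp) class in
#'   binary mode; default the first level.
#' @param seed Unused by the deterministic solver; accepted for interface
#'   symmetry with the other training stages.
#' @return Object of class `polyp_svm`: hyperplane weights `W` (one row per
#'   class in multiclass mode, a single row in binary mode), intercepts
#'   `b`, the fitted `scaler`, `classes`, and `positive_class`.
#' @export
train_svm <- function(features, labels, cost = 1, positive_class = NULL,
                      seed = 1L) {
  x <- as.matrix(features)
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L)
    stop("training labels contain a single class", call. = FALSE)
  if (nrow(x) != length(labels)) stop("feature/label length mismatch", call. = FALSE)
  scaler <- fit_scaler(x)
  xs <- apply_scaler(scaler, x)
  classes <- levels(labels)
  if (is.null(positive_class)) positive_class <- classes[1L]
  stopifnot(positive_class %in% classes)
  if (length(classes) == 2L) {
    hp <- .fit_binary_hyperplane(xs, labels == positive_class, cost)
    W <- matrix(hp$w, nrow = 1L); b <- hp$b
    rownames(W) <- positive_class
  } else {
    hps <- lapply(classes, function(cl)
      .fit_binary_hyperplane(xs, labels == cl, cost))
    W <- do.call(rbind, lapply(hps, `[[`, "w"))
    b <- vapply(hps, `[[`, numeric(1), "b")
    rownames(W) <- classes
  }
  structure(list(W = W, b = b, scaler = scaler, classes = classes,
                 positive_class = positive_class, cost = cost),
            class = "polyp_svm")
}

#' Predict labels and scores from a linear SVM
#'
#' The score of a sample is its signed distance direction `w . x + b` to
#' the (binary) hyperplane after standardization: positive scores fall on
#' the positive-class (polyp) side. With more than two classes the label is
#' the argmax over one-vs-rest scores and the winning score is reported.
#'
#' @param object A `polyp_svm` from [train_svm()].
#' @param features Vector or matrix of unstandardized features of matching
#'   width.
#' @param ... Unused.
#' @return `data.frame` with columns `label` and `score`.
#' @export
predict.polyp_svm <- function(object, features, ...) {
  x <- rbind(as.matrix(features))
  if (ncol(x) != length(object$scaler$mean))
    stop("feature width ", ncol(x), " does not match the model (",
         length(object$scaler$mean), ")", call. = FALSE)
  xs <- apply_scaler(object$scaler, x)
  scores <- xs %*% t(object$W)
  scores <- sweep(scores, 2L, object$b, "+")
  if (length(object$classes) == 2L) {
    s <- drop(scores[, 1L])
    neg <- setdiff(object$classes, object$positive_class)
    lab <- ifelse(s > 0, object$positive_class, neg)
    data.frame(label = lab, score = s, stringsAsFactors = FALSE)
  } else {
    k <- max.col(scores, ties.method = "first")
    data.frame(label = object$classes[k],
               score = scores[cbind(seq_len(nrow(scores)), k)],
               stringsAsFactors = FALSE)
  }
}

#' Classification metrics against ground truth
#'
#' Confusion counts and the three headline rates of the window classifier:
#' sensitivity `TP / (TP + FN)` (true positive rate on polyp windows),
#' specificity `TN / (TN + FP)` (true negative rate), and accuracy
#' `(TP + TN) / n`.
#'
#' @param predictions Predicted labels.
#' @param truth True labels of the same length.
#' @param positive_class Label counted as positive (default `"polyp"`).
#' @return Object of class `eval_metrics`: list with `confusion` (2x2
#'   matrix, predicted x truth), `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `accuracy`.
#' @export
evaluate <- function(predictions, truth, positive_class = "polyp") {
  predictions <- as.character(predictions)
  truth <- as.character(truth)
  if (length(predictions) != length(truth))
    stop("prediction/truth length mismatch", call. = FALSE)
  if (!positive_class %in% c(predictions, truth))
    stop("positive class '", positive_class, "' absent from labels", call. = FALSE)
  pos_p <- predictions == positive_class
  pos_t <- truth == positive_class
  tp <- sum(pos_p & pos_t); fp <- sum(pos_p & !pos_t)
  fn <- sum(!pos_p & pos_t); tn <- sum(!pos_p & !pos_t)
  conf <- matrix(c(tp, fn, fp, tn), 2L, 2L,
                 dimnames = list(predicted = c(positive_class, "other"),
                                 truth = c(positive_class, "other")))
  structure(list(confusion = conf, tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 accuracy = (tp + tn) / length(truth)),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat("Confusion matrix (rows: predicted, cols: truth)\n")
  print(x$confusion)
  cat(sprintf("sensitivity %.4f | specificity %.4f | accuracy %.4f\n",
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Stratified train/test split
#'
#' Splits indices class by class so both parts keep the class proportions.
#'
#' @param labels Factor or character labels.
#' @param train_fraction Fraction assigned to training (default 0.7).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.7, seed = 1L) {
  labels <- as.factor(labels)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  train <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    n_tr <- round(length(idx) * train_fraction)
    train <- c(train, sort(sample(idx, n_tr)))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}
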