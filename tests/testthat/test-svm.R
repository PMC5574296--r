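# Fusion and the linear SVM stage.

test_that("fusion concatenates the blocks in order", {
  cw <- as.numeric(seq_len(144)); cnn <- seq_len(4096) + 1000
  f <- fuse(cw, cnn)
  expect_length(f, 4240L)
  expect_identical(f[1L], cw[1L])
  expect_identical(f[145L], cnn[1L])
  expect_identical(fuse(rep(0, 144), rep(0, 4096)), rep(0, 4240))
  expect_error(fuse(seq_len(100), cnn), "144")
  m <- fuse(rbind(cw, cw), rbind(cnn, cnn))
  expect_identical(dim(m), c(2L, 4240L))
})

test_that("the scaler uses population moments with a constant-feature guard", {
  x <- rbind(rep(0, 5), rep(2, 5))
  sc <- fit_scaler(x)
  expect_equal(unname(sc$mean), rep(1, 5))
  expect_equal(unname(sc$sd), rep(1, 5))

  x2 <- cbind(c(1, 1, 1), c(0, 3, 6))
  sc2 <- fit_scaler(x2)
  expect_equal(sc2$sd[1L], 1)                      # constant column guard
  scaled <- apply_scaler(sc2, x2)
  expect_equal(colMeans(scaled), c(0, 0))
  expect_error(fit_scaler(matrix(0, 1, 3)), "2 samples")
})

test_that("a separable toy problem is classified perfectly", {
  x <- rbind(c(0, 0), c(0, 1), c(4, 0), c(4, 1))
  y <- c("polyp", "polyp", "nonpolyp", "nonpolyp")
  m <- train_svm(x, y, positive_class = "polyp")
  pr <- predict(m, x)
  expect_identical(pr$label, y)
  expect_true(all(pr$score[1:2] > 0) && all(pr$score[3:4] < 0))
  # decision boundary halfway between the clusters
  mid <- predict(m, rbind(c(2, 0.5)))
  expect_lt(abs(mid$score), 1e-6)
})

test_that("contradictory labels do not crash and score at chance", {
  x <- rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 1))
  y <- c("polyp", "nonpolyp", "polyp", "nonpolyp")
  m <- train_svm(x, y, positive_class = "polyp")
  pr <- predict(m, x)
  expect_lte(mean(pr$label == y), 0.5)
})

test_that("three separated clusters are solved one-vs-rest", {
  set.seed(8)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  x <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(20, sd = 0.3), 10, 2), 2, centers[k, ], "+")))
  y <- rep(c("a", "b", "c"), each = 10)
  m <- train_svm(x, y)
  expect_identical(nrow(m$W), 3L)
  pr <- predict(m, x)
  expect_identical(pr$label, y)
})

test_that("predictions agree exactly with the exported hyperplane", {
  set.seed(9)
  x <- matrix(rnorm(60 * 5), 60, 5)
  y <- ifelse(x[, 1] + 0.5 * x[, 2] + rnorm(60, sd = 0.3) > 0, "polyp", "nonpolyp")
  expect_gte(length(unique(y)), 2L)
  m <- train_svm(x, y, positive_class = "polyp")
  pr <- predict(m, x)
  xs <- apply_scaler(m$scaler, x)
  manual <- drop(xs %*% t(m$W)) + m$b
  expect_equal(pr$score, unname(manual), tolerance = 1e-12)
  expect_identical(pr$label, ifelse(manual > 0, "polyp", "nonpolyp"))
  # hand-checkable hyperplane: w = (1, 0), b = -2 scores (4, 0) as +2
  hand <- structure(list(
    W = matrix(c(1, 0), 1), b = -2,
    scaler = structure(list(mean = c(0, 0), sd = c(1, 1)),
                       class = "feature_scaler"),
    classes = c("polyp", "nonpolyp"), positive_class = "polyp", cost = 1),
    class = "polyp_svm")
  expect_equal(predict(hand, rbind(c(4, 0)))$score, 2)
  expect_equal(predict(hand, rbind(c(2, 5)))$score, 0)
})

test_that("single-class training input raises a degenerate-labels error", {
  expect_error(train_svm(matrix(rnorm(10), 5, 2), rep("polyp", 5)),
               "single class")
})

test_that("evaluation metrics follow the rate definitions", {
  ev <- evaluate(c("polyp", "polyp", "nonpolyp", "nonpolyp"),
                 c("polyp", "polyp", "nonpolyp", "nonpolyp"))
  expect_equal(c(ev$sensitivity, ev$specificity, ev$accuracy), c(1, 1, 1))

  ev2 <- evaluate(c("polyp", "nonpolyp", "nonpolyp", "polyp"),
                  c("polyp", "polyp", "nonpolyp", "nonpolyp"))
  expect_equal(c(ev2$sensitivity, ev2$specificity, ev2$accuracy),
               c(0.5, 0.5, 0.5))

  pred <- c(rep("polyp", 98), rep("nonpolyp", 2),   # truth polyp
            rep("nonpolyp", 97), rep("polyp", 3))   # truth nonpolyp
  truth <- c(rep("polyp", 100), rep("nonpolyp", 100))
  ev3 <- evaluate(pred, truth)
  expect_equal(ev3$sensitivity, 0.98)
  expect_equal(ev3$specificity, 0.97)
  expect_equal(ev3$accuracy, 0.975)
  expect_equal(sum(ev3$confusion), 200)
})

test_that("evaluation matches the brute-force confusion counter", {
  set.seed(10)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    pred <- sample(c("polyp", "nonpolyp"), n, replace = TRUE)
    truth <- sample(c("polyp", "nonpolyp"), n, replace = TRUE)
    if (!"polyp" %in% c(pred, truth)) next
    ev <- evaluate(pred, truth)
    o <- confusion_oracle(pred, truth, "polyp")
    expect_identical(c(tp = ev$tp, fp = ev$fp, tn = ev$tn, fn = ev$fn), o)
  }
  expect_error(evaluate(c("a", "b"), c("a", "b"), positive_class = "polyp"),
               "absent")
})

test_that("stratified splits keep class proportions and are seeded", {
  labels <- rep(c("polyp", "nonpolyp"), c(100, 200))
  sp <- stratified_split(labels, 0.7, seed = 42)
  expect_length(sp$train, 210L)
  expect_length(sp$test, 90L)
  expect_equal(sum(labels[sp$train] == "polyp"), 70)
  sp2 <- stratified_split(labels, 0.7, seed = 42)
  expect_identical(sp, sp2)
})
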