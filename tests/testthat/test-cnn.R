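# CNN feature extractor: architecture arithmetic, activations, training
# behavior, and determinism.

test_that("the forward shape chain matches the conv/pool arithmetic", {
  net <- build_network(seed = 1)
  shapes <- network_shapes(net)
  # closed-form: conv (n + 2p - k) / s + 1; pool (n - k) / s + 1
  expect_identical(shapes[[1]], c(55L, 55L, 96L))    # (227 - 11) / 4 + 1
  expect_identical(shapes[[3]], c(27L, 27L, 96L))    # (55 - 3) / 2 + 1
  expect_identical(shapes[[4]], c(27L, 27L, 256L))   # 5x5 pad 2 stride 1
  expect_identical(shapes[[6]], c(13L, 13L, 256L))
  expect_identical(shapes[[7]], c(13L, 13L, 384L))
  expect_identical(shapes[[11]], c(13L, 13L, 256L))
  expect_identical(shapes[[13]], c(6L, 6L, 256L))    # flatten width 9216
  expect_identical(shapes[[14]], 4096L)
  expect_identical(shapes[[16]], 4096L)
  expect_identical(shapes[[18]], 2L)                 # two-neuron head
  spec <- network_spec()
  expect_identical(spec[[1]]$filters, 96L)
  expect_identical(spec[[1]]$kernel, 11L)
  expect_identical(spec[[1]]$stride, 4L)
  rm(net); gc(verbose = FALSE)
})

test_that("relu and softmax follow their definitions", {
  expect_identical(relu(-3), 0)
  expect_identical(relu(5), 5)
  expect_identical(relu(0), 0)
  expect_equal(relu(c(-1, 2, 0)), c(0, 2, 0))

  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(c(3 + 7, 1 + 7)), softmax(c(3, 1)))   # shift invariance
  p <- softmax(c(1000, 0))                                   # no overflow
  expect_true(all(is.finite(p)))
  expect_equal(sum(p), 1)
  expect_gt(p[1], 1 - 1e-12)
})

test_that("fc2 features are 4096 nonnegative values, batch-invariant", {
  net <- build_network(seed = 2)
  w1 <- test_window(41)
  w2 <- test_window(42)
  f1 <- extract_cnn_features(net, w1)
  expect_length(f1, 4096L)
  expect_true(all(f1 >= 0))
  expect_true(all(is.finite(f1)))
  expect_identical(f1, extract_cnn_features(net, w1))   # pure function

  batch <- extract_cnn_features(net, list(w1, w2))
  expect_identical(dim(batch), c(2L, 4096L))
  expect_equal(unname(batch[1, ]), unname(f1), tolerance = 1e-5)

  small <- window(array(0, c(100, 100, 3)))
  expect_error(extract_cnn_features(net, small), "227")
  rm(net); gc(verbose = FALSE)
})

test_that("zeroing the fc2 weights zeroes the features", {
  net <- build_network(seed = 3)
  # layer 16 is the second dense layer (fc2) in the fixed architecture
  net$weights[[16]]$W[] <- 0
  net$weights[[16]]$b[] <- 0
  net$env$ptr <- NULL   # force rebuild from modified weights
  f <- extract_cnn_features(net, test_window(43))
  expect_true(all(f == 0))
  rm(net); gc(verbose = FALSE)
})

test_that("initialization and training are seed-reproducible", {
  na <- build_network(seed = 7)
  nb <- build_network(seed = 7)
  expect_identical(na$weights, nb$weights)
  seed8_w1 <- build_network(seed = 8)$weights[[1]]$W
  expect_false(identical(na$weights[[1]]$W, seed8_w1))
  rm(na, nb, seed8_w1); gc(verbose = FALSE)

  ds <- make_dataset(4, 4, seed = 44)
  t1 <- train_network(build_network(seed = 7), ds$windows, ds$labels,
                      epochs = 1L, seed = 7)
  t2 <- train_network(build_network(seed = 7), ds$windows, ds$labels,
                      epochs = 1L, seed = 7)
  expect_identical(t1$weights, t2$weights)
  expect_identical(t1$training$loss, t2$training$loss)
  rm(t1, t2); gc(verbose = FALSE)
})

test_that("training rejects degenerate labels", {
  ds <- make_dataset(4, 0, seed = 45)
  expect_error(train_network(build_network(seed = 1), ds$windows, ds$labels,
                             epochs = 1L), "single class")
})

test_that("the softmax head outputs a two-class probability vector", {
  net <- build_network(seed = 9)
  p <- network_predict(net, test_window(46))
  expect_length(p, 2L)
  expect_true(all(p > 0))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  rm(net); gc(verbose = FALSE)
})

test_that("training reduces the loss and separates the fixture classes", {
  fe <- shared_features()
  loss <- fe$net$training$loss
  expect_lt(loss[length(loss)], loss[1L])
  # the trained feature space separates classes above chance
  ds <- shared_dataset(); sp <- shared_split()
  ev <- shared_family_eval("cnn")$metrics
  expect_gt(ev$accuracy, 0.7)
})
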