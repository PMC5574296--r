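# Shared expensive fixtures, built once per test run and reused across
# files. The dataset geometry mirrors the pipeline's reference evaluation:
# 300 windows at a 1:2 polyp:nonpolyp ratio, 70/30 stratified split. The
# CNN training budget is 3 epochs, the package's reduced desk-scale budget
# (see the methods vignette).

.pipeline_cache <- new.env(parent = emptyenv())

pipeline_seed <- 2024L
pipeline_epochs <- 3L

shared_dataset <- function() {
  if (is.null(.pipeline_cache$dataset)) {
    .pipeline_cache$dataset <- make_dataset(100, 200, seed = pipeline_seed)
  }
  .pipeline_cache$dataset
}

shared_split <- function() {
  stratified_split(shared_dataset()$labels, 0.7, seed = pipeline_seed)
}

# Feature matrices for the whole shared dataset (CNN trained on the train
# split only, then applied to everything).
shared_features <- function() {
  if (is.null(.pipeline_cache$features)) {
    ds <- shared_dataset()
    sp <- shared_split()
    net <- build_network(network_spec(2), seed = pipeline_seed)
    net <- train_network(net, ds$windows[sp$train], ds$labels[sp$train],
                         epochs = pipeline_epochs, seed = pipeline_seed)
    cw <- t(vapply(ds$windows, extract_color_wavelet, numeric(144)))
    cnn <- extract_cnn_features(net, ds$windows)
    .pipeline_cache$features <- list(net = net, cw = cw, cnn = cnn,
                                     fused = fuse(cw, cnn))
  }
  .pipeline_cache$features
}

# Held-out metrics for one feature family.
shared_family_eval <- function(which = c("fused", "wavelet", "cnn")) {
  which <- match.arg(which)
  key <- paste0("eval_", which)
  if (is.null(.pipeline_cache[[key]])) {
    ds <- shared_dataset(); sp <- shared_split()
    fe <- shared_features()
    x <- switch(which, fused = fe$fused, wavelet = fe$cw, cnn = fe$cnn)
    m <- train_svm(x[sp$train, ], ds$labels[sp$train],
                   positive_class = "polyp")
    pr <- predict(m, x[sp$test, ])
    .pipeline_cache[[key]] <- list(
      model = m,
      metrics = evaluate(pr$label, ds$labels[sp$test], "polyp"))
  }
  .pipeline_cache[[key]]
}

# A full fitted detector sharing the cached CNN and fused features.
shared_detector <- function() {
  if (is.null(.pipeline_cache$detector)) {
    ds <- shared_dataset(); sp <- shared_split()
    fe <- shared_features()
    svm <- shared_family_eval("fused")$model
    model <- structure(list(
      cnn = fe$net, svm = svm, features = "fused",
      config = list(epochs = pipeline_epochs, lr = 1e-3, momentum = 0.9,
                    batch_size = 32L, cost = 1, wavelet = "db3",
                    glcm_levels = 32L, glcm_distance = 1L,
                    seed = pipeline_seed),
      classes = levels(ds$labels),
      training_accuracy = NA_real_, n_train = length(sp$train)),
      class = "polyp_detector")
    .pipeline_cache$detector <- model
  }
  .pipeline_cache$detector
}
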