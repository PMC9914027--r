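test_that("the step learning-rate policy decays by gamma every period", {
  cfg <- train_config()
  expect_equal(lr_at(0, cfg), 0.001)
  expect_equal(lr_at(cfg$step_period, cfg), 0.0005)
  expect_equal(lr_at(3 * cfg$step_period, cfg), 0.000125)
  expect_equal(lr_at(cfg$step_period - 1, cfg), 0.001)
  expect_error(lr_at(-1, cfg), ">= 0")
})

test_that("stratified folds are balanced, disjoint and exhaustive", {
  # 70 balanced samples over 10 folds: exactly one per class per fold
  mf <- data.frame(id = as.character(1:70),
                   label = rep(lesion_classes(), each = 10),
                   stringsAsFactors = FALSE)
  folds <- stratified_kfold(mf, folds = 10, seed = 1)
  for (f in folds) {
    expect_equal(length(f$test), 7)
    expect_equal(unname(table(mf$label[mf$id %in% f$test])), rep(1L, 7),
                 ignore_attr = TRUE)
    expect_length(intersect(f$train, f$test), 0)
  }
  all_test <- unlist(lapply(folds, `[[`, "test"))
  expect_setequal(all_test, mf$id)
  expect_equal(anyDuplicated(all_test), 0)

  # deterministic given seed
  expect_identical(stratified_kfold(mf, 10, 5), stratified_kfold(mf, 10, 5))

  expect_error(stratified_kfold(mf, folds = 11), "fewer than folds")
})

test_that("folds of the archive-imbalance manifest stay proportional", {
  m <- make_fixture("ham10000", synthetic_spec(image_size = 32L), seed = 1,
                    write_images = FALSE)
  folds <- stratified_kfold(m, folds = 10, seed = 2)
  counts <- class_count_preset("ham10000")
  for (f in folds) {
    tab <- table(m$label[m$id %in% f$test])
    for (cl in lesion_classes()) {
      expect_lte(abs(tab[[cl]] - counts[[cl]] / 10), 1)
    }
  }
})

test_that("one epoch over one batch performs exactly one optimizer step", {
  set.seed(2)
  imgs <- lapply(1:64, function(i) array(runif(16 * 16 * 3), c(16, 16, 3)))
  labs <- factor(rep(lesion_classes(), length.out = 64),
                 levels = lesion_classes())
  model <- build_model(tiny_model_config(input_size = 16L))
  fit <- train(model, list(images = imgs, labels = labs),
               cfg = train_config(epochs = 1L, batch_size = 64L, seed = 1))
  expect_equal(nrow(fit$history), 1)
  expect_equal(fit$history$steps, 1L)
  expect_equal(fit$history$lr, 0.001)
})

test_that("training separates a linearly separable two-class toy set", {
  set.seed(0)
  n <- 32
  imgs <- vector("list", n)
  labs <- character(n)
  for (i in seq_len(n)) {
    bright <- i %% 2 == 0
    imgs[[i]] <- array(runif(16 * 16 * 3, if (bright) 0.7 else 0,
                             if (bright) 1 else 0.3), c(16, 16, 3))
    labs[i] <- if (bright) "hi" else "lo"
  }
  cfg2 <- tiny_model_config(n_classes = 2L, input_size = 16L)
  model <- build_model(cfg2)
  fit <- train(model, list(images = imgs,
                           labels = factor(labs, levels = c("hi", "lo"))),
               cfg = train_config(epochs = 5L, base_lr = 0.01, seed = 0))
  expect_true(all(diff(fit$history$train_loss) < 0))
})

test_that("training is deterministic and records the lr schedule", {
  set.seed(6)
  imgs <- lapply(1:32, function(i) array(runif(16 * 16 * 3), c(16, 16, 3)))
  labs <- factor(rep(lesion_classes()[1:4], each = 8),
                 levels = lesion_classes()[1:4])
  data <- list(images = imgs, labels = labs)
  cfg <- train_config(epochs = 4L, step_period = 2L, batch_size = 16L,
                      seed = 3)
  run <- function() {
    set.seed(99)
    model <- build_model(tiny_model_config(n_classes = 4L, input_size = 16L))
    train(model, data, cfg = cfg)$history
  }
  h1 <- run(); h2 <- run()
  expect_identical(h1[setdiff(names(h1), "seconds")],
                   h2[setdiff(names(h2), "seconds")])
  expect_equal(h1$lr, lr_at(0:3, cfg))
})

test_that("divergent training aborts with a diagnostic", {
  set.seed(1)
  imgs <- lapply(1:8, function(i) array(runif(16 * 16 * 3), c(16, 16, 3)))
  labs <- factor(rep(lesion_classes()[1:2], 4), levels = lesion_classes()[1:2])
  model <- build_model(tiny_model_config(n_classes = 2L, input_size = 16L))
  expect_error(
    train(model, list(images = imgs, labels = labs),
          cfg = train_config(epochs = 8L, base_lr = 1e20, seed = 1)),
    "diverged")
})

test_that("optimizer menu updates parameters under every policy", {
  set.seed(4)
  imgs <- lapply(1:16, function(i) array(runif(16 * 16 * 3), c(16, 16, 3)))
  labs <- factor(rep(lesion_classes()[1:2], 8), levels = lesion_classes()[1:2])
  data <- list(images = imgs, labels = labs)
  for (opt in c("sgd", "adam", "rmsprop", "adamax", "adadelta", "nadam")) {
    set.seed(10)
    model <- build_model(tiny_model_config(n_classes = 2L, input_size = 16L))
    w0 <- model$layers$head_fc2$params$W
    fit <- train(model, data,
                 cfg = train_config(optimizer = opt, epochs = 1L, seed = 1))
    expect_false(identical(w0, fit$model$layers$head_fc2$params$W),
                 info = opt)
    expect_true(is.finite(fit$history$train_loss), info = opt)
  }
})

test_that("cross-validation trains disjoint folds and aggregates them", {
  set.seed(12)
  n_per <- 4
  imgs <- list(); labs <- character(0)
  for (cl in lesion_classes()) {
    for (i in seq_len(n_per)) {
      imgs[[length(imgs) + 1]] <- array(runif(16 * 16 * 3), c(16, 16, 3))
      labs <- c(labs, cl)
    }
  }
  data <- list(images = imgs, labels = factor(labs, levels = lesion_classes()),
               ids = sprintf("im%02d", seq_along(imgs)))
  tcfg <- train_config(epochs = 1L, folds = 2L, batch_size = 16L, seed = 5)
  cv <- suppressWarnings(
    cross_validate(data, tiny_model_config(input_size = 16L), tcfg))
  expect_length(cv$fold_reports, 2)
  expect_equal(nrow(cv$aggregate), 6)
  macros <- vapply(cv$fold_reports, function(r) r$macro, numeric(6))
  expect_equal(cv$aggregate$mean, unname(rowMeans(macros)))
  # id-level audit: no test id ever appears in its own training fold
  for (f in cv$folds) expect_length(intersect(f$train, f$test), 0)
  # deterministic
  cv2 <- suppressWarnings(
    cross_validate(data, tiny_model_config(input_size = 16L), tcfg))
  expect_equal(cv$aggregate, cv2$aggregate)
})
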