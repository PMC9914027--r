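# Seeded training harness: cross-entropy on logits, an optimizer menu with
# SGD (momentum + weight decay) as the default, step learning-rate decay,
# stratified k-fold cross-validation.

#' Training configuration
#'
#' Defaults follow the reference protocol: SGD with momentum 0.9 and weight
#' decay 5e-4, base learning rate 0.001, step decay with gamma 0.5 (period
#' 10 epochs, so 4 decays over the 40-epoch default), batch size 64, and
#' 10-fold cross-validation.
#'
#' @param optimizer One of `"sgd"`, `"adam"`, `"rmsprop"`, `"adamax"`,
#'   `"adadelta"`, `"nadam"`.
#' @param base_lr Initial learning rate.
#' @param momentum SGD momentum coefficient.
#' @param weight_decay L2 penalty coefficient added to every gradient.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param gamma Multiplicative step-decay factor.
#' @param step_period Epochs between decays.
#' @param folds Cross-validation folds.
#' @param seed Master seed for initialization, data order and augmentation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(optimizer = "sgd", base_lr = 0.001, momentum = 0.9,
                         weight_decay = 5e-4, batch_size = 64L, epochs = 40L,
                         gamma = 0.5, step_period = 10L, folds = 10L,
                         seed = 0L) {
  optimizer <- match.arg(optimizer, c("sgd", "adam", "rmsprop", "adamax",
                                      "adadelta", "nadam"))
  if (base_lr <= 0) stop("base_lr must be positive")
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  if (folds < 2) stop("folds must be >= 2")
  cfg <- list(optimizer = optimizer, base_lr = base_lr, momentum = momentum,
              weight_decay = weight_decay, batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), gamma = gamma,
              step_period = as.integer(step_period), folds = as.integer(folds),
              seed = as.integer(seed))
  class(cfg) <- "train_config"
  cfg
}

#' Learning rate at an epoch
#'
#' Step policy: `base_lr * gamma^floor(epoch / step_period)` with 0-based
#' epochs.
#'
#' @param epoch 0-based epoch index (vectorized).
#' @param cfg A [train_config()].
#' @return Numeric learning rate(s).
#' @export
#' @examples
#' lr_at(0, train_config()) # 0.001
#' lr_at(10, train_config()) # 0.0005
lr_at <- function(epoch, cfg = train_config()) {
  if (any(epoch < 0)) stop("epoch must be >= 0")
  cfg$base_lr * cfg$gamma^(epoch %/% cfg$step_period)
}

#' Stratified k-fold split
#'
#' Partitions record ids so that every class's count differs by at most one
#' across folds; folds are disjoint and cover the manifest. Deterministic
#' given `seed`.
#'
#' @param manifest A manifest data.frame (active records are used), or any
#'   data.frame with `id` and `label` columns.
#' @param folds Number of folds.
#' @param seed Integer seed.
#' @return List of length `folds`; each element is `list(train =, test =)`
#'   holding record ids.
#' @export
stratified_kfold <- function(manifest, folds = 10L, seed = 0L) {
  act <- if (is.null(manifest$provenance)) manifest else
    manifest[manifest$provenance != "downsampled-out", , drop = FALSE]
  set.seed(seed)
  assign_fold <- rep(NA_integer_, nrow(act))
  for (cl in sort(unique(act$label))) {
    idx <- which(act$label == cl)
    if (length(idx) < folds)
      stop("class ", cl, " has ", length(idx),
           " records, fewer than folds = ", folds)
    assign_fold[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  lapply(seq_len(folds), function(f)
    list(train = act$id[assign_fold != f], test = act$id[assign_fold == f]))
}

## ---- datasets --------------------------------------------------------------

# A dataset is list(images = list of (H,W,3) arrays OR paths, labels =
# factor over lesion classes). Internal helper to assemble a batch tensor.
ds_batch <- function(data, idx) {
  imgs <- data$images[idx]
  if (is.character(imgs[[1]])) imgs <- lapply(imgs, load_image)
  d <- dim(imgs[[1]])
  x <- array(0, c(d[1], d[2], 3, length(imgs)))
  for (i in seq_along(imgs)) x[, , , i] <- imgs[[i]]
  x
}

#' Build an in-memory dataset from a manifest
#'
#' @param manifest A manifest data.frame with on-disk paths.
#' @param classes Class level order.
#' @param in_memory Load all images now (`TRUE`) or keep paths and load per
#'   batch (`FALSE`).
#' @return List with `images`, `labels` (factor), `ids`.
#' @export
manifest_dataset <- function(manifest, classes = lesion_classes(),
                             in_memory = FALSE) {
  act <- manifest[manifest$provenance != "downsampled-out", , drop = FALSE]
  images <- as.list(act$path)
  if (in_memory) images <- lapply(act$path, load_image)
  list(images = images,
       labels = factor(act$label, levels = intersect(classes, unique(act$label))),
       ids = act$id)
}

## ---- optimizers ------------------------------------------------------------

opt_update <- function(layer, lr, cfg, t) {
  for (nm in names(layer$params)) {
    g <- layer$grads[[nm]]
    if (is.null(g)) next
    p <- layer$params[[nm]]
    g <- g + cfg$weight_decay * p
    st <- layer$opt[[nm]]
    if (is.null(st)) st <- list(v = 0, m = 0, s = 0, u = 0, d = 0)
    if (cfg$optimizer == "sgd") {
      st$v <- cfg$momentum * st$v - lr * g
      p <- p + st$v
    } else if (cfg$optimizer %in% c("adam", "nadam")) {
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      st$m <- b1 * st$m + (1 - b1) * g
      st$s <- b2 * st$s + (1 - b2) * g^2
      mh <- st$m / (1 - b1^t)
      sh <- st$s / (1 - b2^t)
      if (cfg$optimizer == "nadam")
        mh <- b1 * mh + (1 - b1) * g / (1 - b1^t)
      p <- p - lr * mh / (sqrt(sh) + eps)
    } else if (cfg$optimizer == "rmsprop") {
      st$s <- 0.9 * st$s + 0.1 * g^2
      p <- p - lr * g / sqrt(st$s + 1e-8)
    } else if (cfg$optimizer == "adamax") {
      b1 <- 0.9; b2 <- 0.999
      st$m <- b1 * st$m + (1 - b1) * g
      st$u <- pmax(b2 * st$u, abs(g))
      p <- p - lr / (1 - b1^t) * st$m / (st$u + 1e-8)
    } else if (cfg$optimizer == "adadelta") {
      rho <- 0.95; eps <- 1e-6
      st$s <- rho * st$s + (1 - rho) * g^2
      dx <- -sqrt(st$d + eps) / sqrt(st$s + eps) * g
      st$d <- rho * st$d + (1 - rho) * dx^2
      p <- p + dx
    }
    layer$opt[[nm]] <- st
    layer$params[[nm]] <- p
  }
}

## ---- training --------------------------------------------------------------

#' Train a model
#'
#' Minimizes categorical cross-entropy over logits with the configured
#' optimizer and step learning-rate schedule. Fully seeded: weight
#' initialization is whatever the model was built with, while data order
#' and any stochastic transforms derive from `cfg$seed`. When validation
#' data is supplied, the weights of the best validation-accuracy epoch are
#' restored at the end.
#'
#' @param model A [build_model()] network.
#' @param train_data Dataset list (`images`, `labels`) as from
#'   [manifest_dataset()].
#' @param val_data Optional validation dataset.
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return List with `model` and `history` (data.frame with per-epoch
#'   `epoch`, `lr`, `train_loss`, `train_acc`, `val_loss`, `val_acc`,
#'   `seconds`).
#' @export
train <- function(model, train_data, val_data = NULL, cfg = train_config(),
                  verbose = FALSE) {
  set.seed(cfg$seed)
  n <- length(train_data$images)
  if (n == 0) stop("empty training set")
  y <- as.integer(train_data$labels)
  n_cls <- model$config$n_classes
  flat <- flatten_layers(model$layers)
  hist <- vector("list", cfg$epochs)
  t_global <- 0L
  best_val <- -Inf
  best_state <- NULL

  for (epoch in 0:(cfg$epochs - 1)) {
    t0 <- Sys.time()
    lr <- lr_at(epoch, cfg)
    ord <- sample(n)
    losses <- c(); correct <- 0L; steps <- 0L
    for (b0 in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1, n)]
      x <- ds_batch(train_data, idx)
      logits <- model_forward(model, x, training = TRUE)
      probs <- softmax_cols(logits)
      sel <- cbind(y[idx], seq_along(idx))
      loss <- -mean(log(pmax(probs[sel], 1e-12)))
      if (!is.finite(loss))
        stop("training diverged: non-finite loss at epoch ", epoch)
      losses <- c(losses, loss)
      correct <- correct + sum(apply(probs, 2, which.max) == y[idx])
      dlogits <- probs
      dlogits[sel] <- dlogits[sel] - 1
      dlogits <- dlogits / length(idx)
      dy <- dlogits
      for (l in rev(model$layers)) dy <- l$backward(dy)
      t_global <- t_global + 1L
      steps <- steps + 1L
      for (l in flat) opt_update(l, lr, cfg, t_global)
    }
    ep <- list(epoch = epoch, lr = lr, steps = steps,
               train_loss = mean(losses), train_acc = correct / n,
               val_loss = NA_real_, val_acc = NA_real_)
    if (!is.null(val_data)) {
      ev <- evaluate_model(model, val_data, batch_size = cfg$batch_size,
                           classes = levels(train_data$labels))
      ep$val_loss <- ev$loss
      ep$val_acc <- ev$accuracy
      if (ev$accuracy > best_val) {
        best_val <- ev$accuracy
        best_state <- model_state(model)
      }
    }
    ep$seconds <- as.numeric(Sys.time() - t0, units = "secs")
    hist[[epoch + 1]] <- ep
    if (verbose)
      message(sprintf("epoch %2d lr %.5f loss %.4f acc %.3f val %.3f",
                      epoch, lr, ep$train_loss, ep$train_acc,
                      ifelse(is.na(ep$val_acc), NaN, ep$val_acc)))
  }
  if (!is.null(best_state)) restore_state(model, best_state)
  list(model = model,
       history = do.call(rbind, lapply(hist, as.data.frame)))
}

#' Evaluate a model on a dataset
#'
#' @param model A trained network.
#' @param data Dataset list (`images`, `labels`).
#' @param batch_size Evaluation batch size.
#' @param classes Class order of the confusion matrix.
#' @return List with `confusion` (matrix), `report` ([macro_report()]),
#'   `accuracy` (fraction), `loss` (mean cross-entropy), `pred`, `truth`.
#' @export
evaluate_model <- function(model, data, batch_size = 64L, classes = NULL) {
  n <- length(data$images)
  y <- as.integer(data$labels)
  if (is.null(classes)) classes <- levels(data$labels)
  preds <- integer(n); nll <- numeric(0)
  for (b0 in seq(1, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1, n)
    x <- ds_batch(data, idx)
    probs <- softmax_cols(model_forward(model, x, training = FALSE))
    preds[idx] <- apply(probs, 2, which.max)
    nll <- c(nll, -log(pmax(probs[cbind(y[idx], seq_along(idx))], 1e-12)))
  }
  cm <- confusion_matrix(classes[y], classes[preds], classes = classes)
  list(confusion = cm, report = macro_report(cm),
       accuracy = mean(preds == y), loss = mean(nll),
       pred = classes[preds], truth = classes[y])
}

#' Cross-validated training
#'
#' Trains one model per stratified fold from scratch and aggregates the
#' macro metrics as mean and standard deviation across folds.
#'
#' @param data Dataset list (`images`, `labels`, optional `ids`).
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()]; `folds` and `seed` drive the split.
#' @param verbose Print per-fold progress.
#' @return List with `fold_reports` (per-fold [macro_report()]s),
#'   `aggregate` (data.frame of macro metric mean/sd), and `folds` (the id
#'   partitions).
#' @export
cross_validate <- function(data, model_cfg = model_config(),
                           train_cfg = train_config(), verbose = FALSE) {
  n <- length(data$images)
  ids <- if (!is.null(data$ids)) data$ids else as.character(seq_len(n))
  mf <- data.frame(id = ids, label = as.character(data$labels),
                   provenance = "original", stringsAsFactors = FALSE)
  folds <- stratified_kfold(mf, folds = train_cfg$folds, seed = train_cfg$seed)
  reports <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    tr <- match(folds[[f]]$train, ids)
    te <- match(folds[[f]]$test, ids)
    sub <- function(k) list(images = data$images[k],
                            labels = data$labels[k],
                            ids = ids[k])
    set.seed(train_cfg$seed + f)
    model <- build_model(model_cfg)
    fit <- train(model, sub(tr), val_data = NULL, cfg = train_cfg)
    ev <- evaluate_model(fit$model,
                         list(images = data$images[te],
                              labels = data$labels[te]),
                         classes = levels(data$labels))
    reports[[f]] <- ev$report
    if (verbose)
      message(sprintf("fold %d/%d accuracy %.3f", f, length(folds),
                      ev$accuracy))
  }
  macros <- t(vapply(reports, function(r) r$macro, numeric(6)))
  agg <- data.frame(metric = colnames(macros),
                    mean = colMeans(macros),
                    sd = apply(macros, 2, sd),
                    row.names = NULL)
  agg$formatted <- sprintf("%.1f ± %.1f", agg$mean, agg$sd)
  list(fold_reports = reports, aggregate = agg, folds = folds)
}
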