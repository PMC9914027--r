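# Assembly of the full lightweight shuffle-attention network, parameter
# accounting against the 1.9 M budget, and checkpoint I/O.

#' Model configuration
#'
#' The canonical configuration: a 24-channel stem, four stages of shuffle
#' units with 64/128/256/512 channels repeated 3/7/10/9 times, an SE block
#' with reduction 16 closing every stage followed by 2x2 max pooling, and a
#' 128-wide GELU head over 7 classes. This configuration holds 1,920,027
#' trainable parameters (1.9 M).
#'
#' @param stem_channels Channels of the 3x3 stem convolution.
#' @param stage_widths Channel width of each of the four stages (all even).
#' @param stage_repeats Number of shuffle units per stage.
#' @param se_reduction Bottleneck reduction ratio of the SE blocks.
#' @param head_width Width of the hidden fully connected layer.
#' @param n_classes Number of output classes.
#' @param activation Transform-branch/head activation, one of
#'   `"gelu"`, `"relu"`, `"leakyrelu"`, `"tanh"`, `"sigmoid"`.
#' @param use_shuffle Enable the channel shuffle closing each unit.
#' @param input_size Expected square input extent in pixels; must be
#'   divisible by 16 (four 2x2 pools).
#' @return An object of class `model_config`.
#' @export
model_config <- function(stem_channels = 24L,
                         stage_widths = c(64L, 128L, 256L, 512L),
                         stage_repeats = c(3L, 7L, 10L, 9L),
                         se_reduction = 16L,
                         head_width = 128L,
                         n_classes = 7L,
                         activation = "gelu",
                         use_shuffle = TRUE,
                         input_size = 256L) {
  cfg <- list(stem_channels = as.integer(stem_channels),
              stage_widths = as.integer(stage_widths),
              stage_repeats = as.integer(stage_repeats),
              se_reduction = as.integer(se_reduction),
              head_width = as.integer(head_width),
              n_classes = as.integer(n_classes),
              activation = match.arg(activation, activation_menu()),
              use_shuffle = isTRUE(use_shuffle),
              input_size = as.integer(input_size))
  if (length(cfg$stage_widths) != 4 || length(cfg$stage_repeats) != 4)
    stop("exactly four stages are required")
  if (any(cfg$stage_widths %% 2 != 0)) stop("all stage widths must be even")
  if (cfg$n_classes < 2) stop("n_classes must be >= 2")
  if (any(cfg$stage_repeats < 1)) stop("stage repeats must be >= 1")
  class(cfg) <- "model_config"
  cfg
}

#' @export
print.model_config <- function(x, ...) {
  cat("Model configuration\n")
  cat("  stem:", x$stem_channels, "channels\n")
  cat("  stages:", paste(sprintf("%dx%d", x$stage_repeats, x$stage_widths),
                         collapse = ", "), "\n")
  cat("  SE reduction:", x$se_reduction, " head:", x$head_width,
      " classes:", x$n_classes, "\n")
  cat("  activation:", x$activation, " shuffle:", x$use_shuffle,
      " input:", x$input_size, "px\n")
  invisible(x)
}

# Closed-form parameter count of a configuration (no allocation). Used by
# calibrate_budget(); count_parameters() enumerates the built weight arrays
# and the two must agree exactly.
count_config_params <- function(cfg) {
  unit_p <- function(C) {
    h <- C / 2
    2 * h^2 + 9 * h + 3 * C          # two 1x1 convs, depthwise 3x3, three BNs
  }
  se_p <- function(C) {
    b <- max(1, C %/% cfg$se_reduction)
    2 * C * b + b + C
  }
  w <- cfg$stage_widths
  total <- 9 * 3 * cfg$stem_channels + 2 * cfg$stem_channels +
    cfg$stem_channels * w[1] + 2 * w[1]
  for (i in 1:4) {
    total <- total + cfg$stage_repeats[i] * unit_p(w[i]) + se_p(w[i])
    if (i < 4) total <- total + w[i] * w[i + 1] + 2 * w[i + 1]
  }
  total <- total + w[4] * cfg$head_width + cfg$head_width +
    cfg$head_width * cfg$n_classes + cfg$n_classes
  as.numeric(total)
}

#' Build the network
#'
#' Assembles the full network from a [model_config()]: a 3x3 stride-1 stem
#' (BN + ReLU) with a 1x1 expansion into stage 1; four stages of stride-1
#' shuffle units each closed by an SE block and a 2x2 stride-2 max pool,
#' with 1x1 conv + BN + GELU expansions between stages; then global average
#' pooling and a two-layer GELU head. All downsampling comes from the four
#' pools, so the input extent must be divisible by 16. Weights are drawn
#' from the current RNG; seed the session for reproducible initialization.
#'
#' @param cfg A [model_config()].
#' @return An object of class `ds_model`: an ordered, named layer list plus
#'   the configuration.
#' @export
build_model <- function(cfg = model_config()) {
  stopifnot(inherits(cfg, "model_config"))
  if (cfg$input_size %% 16 != 0)
    stop("input_size must be divisible by 2^4 = 16, got ", cfg$input_size)
  w <- cfg$stage_widths
  layers <- list()
  layers$stem_conv <- layer_conv2d(3L, cfg$stem_channels, 3L)
  layers$stem_bn <- layer_bn(cfg$stem_channels)
  layers$stem_act <- layer_act("relu")
  layers$stem_expand_conv <- layer_conv2d(cfg$stem_channels, w[1], 1L)
  layers$stem_expand_bn <- layer_bn(w[1])
  layers$stem_expand_act <- layer_act(cfg$activation)
  for (i in 1:4) {
    for (j in seq_len(cfg$stage_repeats[i])) {
      layers[[sprintf("stage%d_unit%d", i, j)]] <-
        layer_shuffle_unit(w[i], use_shuffle = cfg$use_shuffle,
                           activation = cfg$activation)
    }
    layers[[sprintf("stage%d_se", i)]] <- layer_se(w[i], cfg$se_reduction)
    layers[[sprintf("stage%d_pool", i)]] <- layer_maxpool2()
    if (i < 4) {
      layers[[sprintf("stage%d_expand_conv", i)]] <-
        layer_conv2d(w[i], w[i + 1], 1L)
      layers[[sprintf("stage%d_expand_bn", i)]] <- layer_bn(w[i + 1])
      layers[[sprintf("stage%d_expand_act", i)]] <- layer_act(cfg$activation)
    }
  }
  layers$global_pool <- layer_globalpool()
  layers$head_fc1 <- layer_dense(w[4], cfg$head_width)
  layers$head_act <- layer_act(cfg$activation)
  layers$head_fc2 <- layer_dense(cfg$head_width, cfg$n_classes)
  model <- list(layers = layers, config = cfg)
  class(model) <- "ds_model"
  model
}

#' @export
print.ds_model <- function(x, ...) {
  r <- count_parameters(x)
  cat(sprintf("<ds_model: %d layers, %s parameters (%.1f M)>\n",
              length(x$layers), format(r$total_params, big.mark = ","),
              r$total_params / 1e6))
  invisible(x)
}

#' Forward pass
#'
#' Runs a batch through the network and returns class logits. Inputs are
#' (H, W, 3, N) arrays (a single (H, W, 3) image is promoted to a batch of
#' one) with pixel values on the `[0, 1]` scale.
#'
#' @param model A built [build_model()] network.
#' @param x Input array.
#' @param training Use batch statistics in the normalization layers and
#'   cache intermediates for the backward pass.
#' @return Matrix (n_classes, N) of logits.
#' @export
model_forward <- function(model, x, training = FALSE) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  for (l in model$layers) x <- l$forward(x, training)
  x
}

#' Class probabilities
#'
#' Softmax over the logits of [model_forward()]; each column sums to 1.
#'
#' @inheritParams model_forward
#' @return Matrix (n_classes, N) of probabilities with class-code rownames.
#' @export
predict_proba <- function(model, x) {
  p <- softmax_cols(model_forward(model, x, training = FALSE))
  if (model$config$n_classes == 7) rownames(p) <- lesion_classes()
  p
}

#' Count trainable parameters
#'
#' Enumerates every trainable array of the built network (convolution and
#' dense weights, biases, normalization scale/shift, SE bottlenecks) and
#' reports the per-module breakdown, the exact total, and the total in
#' millions rounded to one decimal. BN running statistics are not trainable
#' and are excluded.
#'
#' @param model A [build_model()] network.
#' @return An object of class `complexity_report` with fields
#'   `total_params`, `breakdown`, and `params_millions`.
#' @export
#' @examples
#' \donttest{
#' m <- build_model(model_config())
#' count_parameters(m)$params_millions # 1.9
#' }
count_parameters <- function(model) {
  stopifnot(inherits(model, "ds_model"))
  breakdown <- vapply(model$layers, layer_n_params, numeric(1))
  total <- sum(breakdown)
  r <- list(total_params = total,
            breakdown = breakdown[breakdown > 0],
            params_millions = round(total / 1e6, 1))
  class(r) <- "complexity_report"
  r
}

#' @export
print.complexity_report <- function(x, ...) {
  cat("Trainable parameters:", format(x$total_params, big.mark = ","),
      sprintf("(%.1f M)\n", x$params_millions))
  b <- x$breakdown
  for (nm in names(b))
    cat(sprintf("  %-22s %10s\n", nm, format(b[[nm]], big.mark = ",")))
  invisible(x)
}

#' Calibrate a configuration to the parameter budget
#'
#' Repairs a configuration whose parameter count falls outside the
#' 1.85-1.95 million budget window by a deterministic search: the stage-4
#' repeat count is adjusted first (offsets 0, -1, +1, -2, +2, -3, +3), then
#' the head width is tried over 64/128/256 at each offset. The first
#' configuration landing in the window is returned; a configuration already
#' in the window is returned unchanged.
#'
#' @param cfg A [model_config()].
#' @param budget Target window on the raw parameter count.
#' @return A `model_config` within the budget window.
#' @export
calibrate_budget <- function(cfg = model_config(),
                             budget = c(1.85e6, 1.95e6)) {
  stopifnot(inherits(cfg, "model_config"))
  in_range <- function(n) n >= budget[1] && n <= budget[2]
  if (in_range(count_config_params(cfg))) return(cfg)
  best <- NULL
  best_gap <- Inf
  mid <- mean(budget)
  for (dr in c(0L, -1L, 1L, -2L, 2L, -3L, 3L)) {
    rep4 <- cfg$stage_repeats[4] + dr
    if (rep4 < 1) next
    for (hw in unique(c(cfg$head_width, 64L, 128L, 256L))) {
      cand <- cfg
      cand$stage_repeats[4] <- rep4
      cand$head_width <- hw
      n <- count_config_params(cand)
      if (in_range(n)) return(cand)
      if (abs(n - mid) < best_gap) {
        best_gap <- abs(n - mid)
        best <- n
      }
    }
  }
  stop("budget calibration failed; closest achievable count was ",
       format(best, big.mark = ","))
}

## ---- checkpoint I/O --------------------------------------------------------

model_state <- function(model) {
  lapply(model$layers, function(l) {
    s <- list(params = l$params)
    if (!is.null(l$sublayers))
      s$sublayers <- lapply(l$sublayers, function(sl)
        list(params = sl$params,
             running_mean = sl$running_mean, running_var = sl$running_var))
    if (!is.null(l$running_mean)) {
      s$running_mean <- l$running_mean
      s$running_var <- l$running_var
    }
    s
  })
}

restore_state <- function(model, state) {
  for (nm in names(state)) {
    l <- model$layers[[nm]]
    s <- state[[nm]]
    if (length(s$params)) l$params <- s$params
    if (!is.null(s$running_mean)) {
      l$running_mean <- s$running_mean
      l$running_var <- s$running_var
    }
    if (!is.null(s$sublayers)) {
      for (snm in names(s$sublayers)) {
        sl <- l$sublayers[[snm]]
        ss <- s$sublayers[[snm]]
        if (length(ss$params)) sl$params <- ss$params
        if (!is.null(ss$running_mean)) {
          sl$running_mean <- ss$running_mean
          sl$running_var <- ss$running_var
        }
      }
    }
  }
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS file holding all weights and normalization
#' statistics, with a JSON sidecar (`<path>.json`) recording the
#' configuration for inspection without deserializing.
#'
#' @param model A [build_model()] network.
#' @param path Checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the rebuilt model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = unclass(model$config), state = model_state(model)),
          path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(model_config, ck$config)
  model <- build_model(cfg)
  restore_state(model, ck$state)
  model
}
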