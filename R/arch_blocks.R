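# Architecture blocks: channel shuffle, depthwise-separable convolution,
# squeeze-and-excitation, and the composite shuffle unit.

#' Channel shuffle permutation index
#'
#' The fixed permutation that interleaves channels across groups: channels
#' are laid out as a (G, N) matrix with N = C / G channels per group,
#' transposed, and flattened. Output channel `j` (0-based) takes input
#' channel `(j mod G) * N + floor(j / G)`.
#'
#' @param C Total channel count.
#' @param G Number of groups; must divide `C`.
#' @return Integer vector of length `C` with 1-based input indices: output
#'   channel `j` is input channel `shuffle_index(C, G)[j]`.
#' @export
#' @examples
#' shuffle_index(4, 2) # 1 3 2 4
shuffle_index <- function(C, G) {
  C <- as.integer(C); G <- as.integer(G)
  if (C < 1 || G < 1 || C %% G != 0)
    stop("channel count C = ", C, " is not divisible by groups G = ", G)
  N <- C %/% G
  j <- 0:(C - 1)
  (j %% G) * N + j %/% G + 1L
}

#' Channel shuffle
#'
#' Reorders the channel dimension of a feature map by the group-interleaving
#' permutation of [shuffle_index()]. A pure permutation: no arithmetic is
#' applied to the activations, and applying the shuffle with `G` followed by
#' the shuffle with `C / G` restores the original order.
#'
#' @param x Activation array of shape (H, W, C) or (H, W, C, N).
#' @param G Number of groups; must divide the channel count.
#' @return Array of the same shape with channels permuted.
#' @export
#' @examples
#' x <- array(1:24, dim = c(1, 1, 4, 6))
#' y <- channel_shuffle(x, 2)
channel_shuffle <- function(x, G) {
  d <- dim(x)
  was_3d <- length(d) == 3
  if (was_3d) dim(x) <- c(d, 1L)
  C <- dim(x)[3]
  perm <- shuffle_index(C, G)
  y <- x[, , perm, , drop = FALSE]
  if (was_3d) dim(y) <- d
  y
}

#' Convolution specification
#'
#' Describes a (possibly grouped) 2-D convolution for parameter accounting
#' and block construction.
#'
#' @param kernel_w,kernel_h Kernel extent in pixels.
#' @param in_channels,out_channels Channel counts; both must be divisible by
#'   `groups`.
#' @param groups Number of channel groups (`groups = in_channels` with
#'   `out_channels = in_channels` gives a depthwise convolution).
#' @param stride Spatial stride.
#' @param bias Whether the convolution carries a per-output-channel bias.
#' @return An object of class `conv_spec`.
#' @export
conv_spec <- function(kernel_w, kernel_h, in_channels, out_channels,
                      groups = 1L, stride = 1L, bias = FALSE) {
  s <- list(kernel_w = as.integer(kernel_w), kernel_h = as.integer(kernel_h),
            in_channels = as.integer(in_channels),
            out_channels = as.integer(out_channels),
            groups = as.integer(groups), stride = as.integer(stride),
            bias = isTRUE(bias))
  if (s$kernel_w < 1 || s$kernel_h < 1) stop("kernel dimensions must be >= 1")
  if (s$in_channels %% s$groups != 0 || s$out_channels %% s$groups != 0)
    stop("channel counts must be divisible by groups")
  class(s) <- "conv_spec"
  s
}

#' Trainable parameter count of a convolution
#'
#' For a dense convolution the weight tensor holds
#' `kernel_w * kernel_h * in_channels * out_channels` scalars; grouping
#' divides the input-channel extent by the group count, so the depthwise
#' special case (groups = channels) collapses to `kernel_w * kernel_h *
#' channels`. Normalization layers are counted separately.
#'
#' @param spec A [conv_spec()].
#' @return Integer: exact trainable-weight count, including the bias
#'   vector when present.
#' @export
#' @examples
#' conv_param_count(conv_spec(3, 3, 64, 128)) # 73728
#' conv_param_count(conv_spec(3, 3, 64, 64, groups = 64)) # 576
conv_param_count <- function(spec) {
  stopifnot(inherits(spec, "conv_spec"))
  n <- spec$kernel_w * spec$kernel_h *
    (spec$in_channels %/% spec$groups) * spec$out_channels
  if (spec$bias) n <- n + spec$out_channels
  as.integer(n)
}

#' Depthwise-separable convolution
#'
#' Applies a k x k depthwise convolution (one kernel per channel) followed
#' by a 1 x 1 pointwise convolution mapping to `out_channels`, both
#' biasless. The pair holds `k^2 * C + C * out_channels` trainable weights,
#' attached to the result as attribute `n_params`.
#'
#' @param x Activation array (H, W, C) or (H, W, C, N).
#' @param spec A [conv_spec()] giving the kernel size, input and output
#'   channels of the separable pair (`groups` is ignored; the depthwise
#'   stage always uses `groups = C`).
#' @param weights Optional list with elements `dw` (array k x k x 1 x C)
#'   and `pw` (array 1 x 1 x C x out); drawn from the current RNG when
#'   omitted.
#' @return Feature map with `out_channels` channels.
#' @export
dw_separable_conv <- function(x, spec, weights = NULL) {
  stopifnot(inherits(spec, "conv_spec"))
  d <- dim(x)
  was_3d <- length(d) == 3
  if (was_3d) dim(x) <- c(d, 1L)
  C <- dim(x)[3]
  if (C != spec$in_channels)
    stop("input has ", C, " channels but spec expects ", spec$in_channels)
  k <- spec$kernel_w
  dw_l <- layer_conv2d(C, C, k, stride = spec$stride, groups = C)
  pw_l <- layer_conv2d(C, spec$out_channels, 1L)
  if (!is.null(weights)) {
    dw_l$params$W <- array(weights$dw, dim = dim(dw_l$params$W))
    pw_l$params$W <- array(weights$pw, dim = dim(pw_l$params$W))
  }
  y <- pw_l$forward(dw_l$forward(x))
  if (was_3d) dim(y) <- dim(y)[1:3]
  attr(y, "n_params") <- layer_n_params(dw_l) + layer_n_params(pw_l)
  y
}

#' Squeeze-and-excitation configuration
#'
#' @param C Channel count of the map entering the block.
#' @param reduction Bottleneck reduction ratio r; the bottleneck width is
#'   `max(1, floor(C / r))`.
#' @return An object of class `se_config`.
#' @export
se_config <- function(C, reduction = 16L) {
  C <- as.integer(C); reduction <- as.integer(reduction)
  if (C < 1 || reduction < 1) stop("C and reduction must be positive")
  s <- list(C = C, reduction = reduction,
            bottleneck = max(1L, C %/% reduction))
  class(s) <- "se_config"
  s
}

#' Squeeze-and-excitation block
#'
#' Channel attention: the squeeze step global-average-pools the W x H x C
#' map to one scalar per channel; the excitation step runs the two-layer
#' bottleneck (C down to C/r, GELU, back up to C) and a final sigmoid so
#' every per-channel gate lies strictly in (0, 1); the scale step multiplies
#' each input channel by its gate.
#'
#' @param x Activation array (H, W, C) or (H, W, C, N).
#' @param cfg An [se_config()] with `cfg$C` matching the channels of `x`.
#' @param weights Optional list `W1` (b x C), `b1`, `W2` (C x b), `b2`;
#'   random when omitted.
#' @return The gated feature map, with the gate matrix (C x N) attached as
#'   attribute `gate`.
#' @export
se_block <- function(x, cfg, weights = NULL) {
  stopifnot(inherits(cfg, "se_config"))
  d <- dim(x)
  was_3d <- length(d) == 3
  if (was_3d) dim(x) <- c(d, 1L)
  if (dim(x)[3] != cfg$C)
    stop("input has ", dim(x)[3], " channels but SE config expects ", cfg$C)
  l <- layer_se(cfg$C, cfg$reduction)
  if (!is.null(weights)) {
    l$params$W1 <- matrix(weights$W1, cfg$bottleneck, cfg$C)
    l$params$b1 <- as.numeric(weights$b1)
    l$params$W2 <- matrix(weights$W2, cfg$C, cfg$bottleneck)
    l$params$b2 <- as.numeric(weights$b2)
  }
  y <- l$forward(x)
  g <- l$g
  if (was_3d) dim(y) <- d
  attr(y, "gate") <- g
  y
}

#' Shuffle unit
#'
#' The composite block repeated inside each network stage: the input is
#' split into two channel halves; the first half passes through unchanged
#' while the second runs 1x1 conv + BN + ReLU, 3x3 depthwise conv + BN,
#' 1x1 conv + BN + activation; the halves are concatenated and (when
#' `use_shuffle` is set) channel-shuffled with G = 2 so information mixes
#' across the halves. Stride is 1 and the output width equals the input
#' width.
#'
#' @param x Activation array (H, W, C) or (H, W, C, N) with `C = width`.
#' @param width Channel width; must be even.
#' @param use_shuffle Apply the closing channel shuffle (the permutation is
#'   the only difference the switch makes).
#' @param activation Final transform-branch activation (default GELU).
#' @param init `"random"` (current RNG) or `"zero"` to zero the transform
#'   branch convolutions.
#' @return Feature map of the same shape, with the unit's trainable
#'   parameter count attached as attribute `n_params`.
#' @export
shuffle_unit <- function(x, width, use_shuffle = TRUE, activation = "gelu",
                         init = c("random", "zero")) {
  init <- match.arg(init)
  d <- dim(x)
  was_3d <- length(d) == 3
  if (was_3d) dim(x) <- c(d, 1L)
  l <- layer_shuffle_unit(width, use_shuffle = use_shuffle,
                          activation = activation)
  if (init == "zero") {
    for (nm in c("pw1", "dw", "pw2")) {
      s <- l$sublayers[[nm]]
      s$params$W <- array(0, dim(s$params$W))
    }
  }
  y <- l$forward(x, training = TRUE)
  if (was_3d) dim(y) <- d
  attr(y, "n_params") <- layer_n_params(l)
  y
}
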