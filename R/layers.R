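# Minimal define-by-layer neural network framework.
#
# A layer is an environment of class "ds_layer" holding
#   type      layer kind (string)
#   params    named list of trainable arrays (possibly empty)
#   grads     gradients of the last backward pass, same shapes as params
#   forward   function(x, training) -> output, caching what backward needs
#   backward  function(dy) -> gradient w.r.t. the layer input
#
# Activations flow as (H, W, C, N) arrays; after global pooling they become
# (C, N) matrices. Mutability through environments lets the optimizer
# update weights in place.

new_layer <- function(type) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  l$params <- list()
  l$grads <- list()
  class(l) <- "ds_layer"
  l
}

#' @export
print.ds_layer <- function(x, ...) {
  cat(sprintf("<ds_layer %s: %s parameters>\n", x$type,
              format(layer_n_params(x), big.mark = ",")))
  invisible(x)
}

# Trainable scalar count of one layer (composite layers recurse).
layer_n_params <- function(l) {
  n <- sum(vapply(l$params, length, integer(1)))
  if (!is.null(l$sublayers)) {
    n <- n + sum(vapply(l$sublayers, layer_n_params, numeric(1)))
  }
  n
}

# He-style fan-in scaled Gaussian initialization.
init_weight <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

# Column-broadcast helpers: apply a per-column vector to a matrix without
# sweep()'s aperm overhead (v recycles once per column).
col_mul <- function(m, v) m * rep(v, each = nrow(m))
col_add <- function(m, v) m + rep(v, each = nrow(m))

## ---- convolution -----------------------------------------------------------

layer_conv2d <- function(in_ch, out_ch, kernel, stride = 1L, pad = NULL,
                         groups = 1L, bias = FALSE) {
  if (in_ch %% groups != 0 || out_ch %% groups != 0)
    stop("channels (", in_ch, " -> ", out_ch,
         ") not divisible by groups (", groups, ")")
  if (is.null(pad)) pad <- (kernel - 1L) %/% 2L
  l <- new_layer("conv2d")
  l$spec <- conv_spec(kernel, kernel, in_ch, out_ch, groups = groups,
                      stride = stride, bias = bias)
  l$pad <- as.integer(pad)
  fan_in <- kernel * kernel * in_ch / groups
  l$params$W <- init_weight(c(kernel, kernel, in_ch %/% groups, out_ch), fan_in)
  if (bias) l$params$b <- numeric(out_ch)
  l$forward <- function(x, training = FALSE) {
    l$x <- x
    y <- cpp_conv2d_fwd(x, dim(x), l$params$W, dim(l$params$W),
                        l$spec$stride, l$pad, l$spec$groups)
    if (!is.null(l$params$b)) {
      d <- dim(y)
      y <- y + rep(rep(l$params$b, each = d[1] * d[2]), d[4])
      dim(y) <- d
    }
    y
  }
  l$backward <- function(dy) {
    g <- cpp_conv2d_bwd(l$x, dim(l$x), l$params$W, dim(l$params$W),
                        dy, l$spec$stride, l$pad, l$spec$groups)
    l$grads$W <- g$dw
    if (!is.null(l$params$b)) {
      d <- dim(dy)
      l$grads$b <- rowSums(matrix(colSums(matrix(dy, d[1] * d[2])),
                                  d[3], d[4]))
    }
    g$dx
  }
  l
}

## ---- batch normalization ---------------------------------------------------

# Per-channel statistics over (H, W, N); learnable scale and shift
# (2 parameters per channel, included in all parameter budgets).
layer_bn <- function(C, eps = 1e-5, momentum = 0.1) {
  l <- new_layer("bn")
  l$C <- C
  l$eps <- eps
  l$momentum <- momentum
  l$params$gamma <- rep(1, C)
  l$params$beta <- rep(0, C)
  l$running_mean <- rep(0, C)
  l$running_var <- rep(1, C)
  l$forward <- function(x, training = FALSE) {
    d <- dim(x)
    HW <- d[1] * d[2]; N <- d[4]
    if (training) {
      # column j of the implicit (HW, C*N) view is (channel, sample)
      mu <- rowMeans(matrix(.colMeans(x, HW, C * N), C, N))
      ex2 <- rowMeans(matrix(cpp_colsums_prod(x, x, HW), C, N)) / HW
      v <- pmax(ex2 - mu^2, 0)
      l$running_mean <- (1 - l$momentum) * l$running_mean + l$momentum * mu
      l$running_var <- (1 - l$momentum) * l$running_var + l$momentum * v
    } else {
      mu <- l$running_mean
      v <- l$running_var
    }
    invstd <- 1 / sqrt(v + l$eps)
    xhat <- cpp_col_affine(x, HW, rep(invstd, N), rep(-mu * invstd, N))
    y <- cpp_col_affine(xhat, HW, rep(l$params$gamma, N),
                        rep(l$params$beta, N))
    l$xhat <- xhat; l$invstd <- invstd; l$d <- d
    l$batch_stats <- isTRUE(training)
    y
  }
  l$backward <- function(dy) {
    d <- l$d
    HW <- d[1] * d[2]; N <- d[4]
    m <- HW * N
    per_ch <- function(v) rowSums(matrix(.colSums(v, HW, C * N), C, N))
    per_ch_prod <- function(a, b)
      rowSums(matrix(cpp_colsums_prod(a, b, HW), C, N))
    l$grads$gamma <- per_ch_prod(dy, l$xhat)
    l$grads$beta <- per_ch(dy)
    dxhat <- cpp_col_scale(dy, HW, rep(l$params$gamma, N))
    if (l$batch_stats) {
      # statistics depend on the batch, so the mean/variance terms enter
      s1 <- per_ch(dxhat)
      s2 <- per_ch_prod(dxhat, l$xhat)
      dx <- dxhat + cpp_col_affine(l$xhat, HW, rep(-s2 / m, N),
                                   rep(-s1 / m, N))
    } else {
      dx <- dxhat                     # running stats are constants
    }
    cpp_col_scale(dx, HW, rep(l$invstd, N))
  }
  l
}

## ---- activations -----------------------------------------------------------

layer_act <- function(name) {
  l <- new_layer(paste0("act_", name))
  if (name == "relu") {
    l$forward <- function(x, training = FALSE) {
      l$x <- x
      cpp_relu_fwd(x)
    }
    l$backward <- function(dy) cpp_relu_bwd(dy, l$x)
    return(l)
  }
  if (name == "gelu") {
    # cache the Gaussian CDF: it is needed by both passes
    l$forward <- function(x, training = FALSE) {
      l$x <- x
      r <- cpp_gelu_fwd(x)
      l$pn <- r$pn
      r$y
    }
    l$backward <- function(dy) cpp_gelu_bwd(dy, l$x, l$pn)
    return(l)
  }
  f <- act_fun(name)
  g <- act_grad(name)
  l$forward <- function(x, training = FALSE) {
    l$x <- x
    l$y <- f(x)
    l$y
  }
  l$backward <- function(dy) dy * g(l$x, l$y)
  l
}

## ---- pooling ---------------------------------------------------------------

layer_maxpool2 <- function() {
  l <- new_layer("maxpool2")
  l$forward <- function(x, training = FALSE) {
    l$xdim <- dim(x)
    r <- cpp_maxpool2_fwd(x, dim(x))
    l$argmax <- r$argmax
    r$y
  }
  l$backward <- function(dy) cpp_maxpool2_bwd(dy, l$argmax, l$xdim)
  l
}

# Global average pool: (H, W, C, N) -> (C, N).
layer_globalpool <- function() {
  l <- new_layer("globalpool")
  l$forward <- function(x, training = FALSE) {
    d <- dim(x)
    l$d <- d
    matrix(.colMeans(x, d[1] * d[2], d[3] * d[4]), d[3], d[4])
  }
  l$backward <- function(dy) {
    d <- l$d
    HW <- d[1] * d[2]
    dx <- rep(as.vector(dy) / HW, each = HW)
    dim(dx) <- d
    dx
  }
  l
}

## ---- dense -----------------------------------------------------------------

layer_dense <- function(in_f, out_f, bias = TRUE) {
  l <- new_layer("dense")
  l$params$W <- matrix(rnorm(out_f * in_f, sd = sqrt(2 / in_f)), out_f, in_f)
  if (bias) l$params$b <- numeric(out_f)
  l$forward <- function(x, training = FALSE) {
    l$x <- x
    y <- l$params$W %*% x
    if (!is.null(l$params$b)) y <- y + l$params$b
    y
  }
  l$backward <- function(dy) {
    l$grads$W <- dy %*% t(l$x)
    if (!is.null(l$params$b)) l$grads$b <- rowSums(dy)
    t(l$params$W) %*% dy
  }
  l
}

## ---- channel shuffle (as a layer) ------------------------------------------

layer_channel_shuffle <- function(C, groups) {
  l <- new_layer("channel_shuffle")
  l$perm <- shuffle_index(C, groups)
  l$inv <- order(l$perm)
  l$forward <- function(x, training = FALSE) cpp_chan_perm(x, dim(x), l$perm)
  l$backward <- function(dy) cpp_chan_perm(dy, dim(dy), l$inv)
  l
}

## ---- squeeze-and-excitation ------------------------------------------------

# Squeeze: global average pool to one scalar per channel. Excitation:
# bottleneck C -> max(1, floor(C/r)) -> C with GELU inside and a sigmoid
# gate at the end; the input map is rescaled channelwise by the gate.
layer_se <- function(C, reduction = 16L, inner_act = "gelu") {
  l <- new_layer("se")
  l$cfg <- se_config(C, reduction)
  b <- l$cfg$bottleneck
  l$params$W1 <- matrix(rnorm(b * C, sd = sqrt(2 / C)), b, C)
  l$params$b1 <- numeric(b)
  l$params$W2 <- matrix(rnorm(C * b, sd = sqrt(2 / b)), C, b)
  l$params$b2 <- numeric(C)
  f_in <- act_fun(inner_act)
  g_in <- act_grad(inner_act)
  l$forward <- function(x, training = FALSE) {
    d <- dim(x)
    if (d[3] != C) stop("SE block built for ", C, " channels, got ", d[3])
    HW <- d[1] * d[2]; N <- d[4]
    z <- matrix(.colMeans(x, HW, C * N), C, N)           # squeeze
    a1 <- l$params$W1 %*% z + l$params$b1
    h <- f_in(a1)
    a2 <- l$params$W2 %*% h + l$params$b2
    g <- 1 / (1 + exp(-a2))                              # gate in (0,1)
    y <- cpp_col_scale(x, HW, as.vector(g))
    l$x <- x; l$z <- z; l$a1 <- a1; l$h <- h; l$g <- g; l$d <- d
    l$g_in <- g_in
    y
  }
  l$backward <- function(dy) {
    d <- l$d
    HW <- d[1] * d[2]; N <- d[4]
    dx <- cpp_col_scale(dy, HW, as.vector(l$g))
    dg <- matrix(cpp_colsums_prod(dy, l$x, HW), C, N)
    da2 <- dg * l$g * (1 - l$g)
    l$grads$W2 <- da2 %*% t(l$h)
    l$grads$b2 <- rowSums(da2)
    dh <- t(l$params$W2) %*% da2
    da1 <- dh * l$g_in(l$a1, l$h)
    l$grads$W1 <- da1 %*% t(l$z)
    l$grads$b1 <- rowSums(da1)
    dz <- t(l$params$W1) %*% da1
    dx + rep(as.vector(dz) / HW, each = HW)
  }
  l
}

## ---- shuffle unit ----------------------------------------------------------

# ShuffleNet-v2 style unit at stride 1: even channel split, identity branch
# plus a transform branch (1x1 conv + BN + ReLU, 3x3 depthwise + BN,
# 1x1 conv + BN + GELU), concatenation, then channel shuffle with G = 2.
layer_shuffle_unit <- function(width, use_shuffle = TRUE, activation = "gelu") {
  if (width %% 2 != 0)
    stop("shuffle unit width must be even, got ", width)
  h <- width %/% 2L
  l <- new_layer("shuffle_unit")
  l$width <- width
  l$use_shuffle <- isTRUE(use_shuffle)
  l$sublayers <- list(
    pw1 = layer_conv2d(h, h, 1L),
    bn1 = layer_bn(h),
    act1 = layer_act("relu"),
    dw = layer_conv2d(h, h, 3L, groups = h),
    bn2 = layer_bn(h),
    pw2 = layer_conv2d(h, h, 1L),
    bn3 = layer_bn(h),
    act2 = layer_act(activation)
  )
  l$perm <- shuffle_index(width, 2L)
  l$inv <- order(l$perm)
  l$forward <- function(x, training = FALSE) {
    if (dim(x)[3] != width)
      stop("shuffle unit expects ", width, " channels, got ", dim(x)[3])
    x1 <- cpp_chan_slice(x, dim(x), 1L, h)
    x2 <- cpp_chan_slice(x, dim(x), h + 1L, width)
    for (s in l$sublayers) x2 <- s$forward(x2, training)
    cpp_chan_concat_perm(x1, x2, dim(x1), dim(x2),
                         if (l$use_shuffle) l$perm else integer(0))
  }
  l$backward <- function(dy) {
    if (l$use_shuffle) dy <- cpp_chan_perm(dy, dim(dy), l$inv)
    d1 <- cpp_chan_slice(dy, dim(dy), 1L, h)
    d2 <- cpp_chan_slice(dy, dim(dy), h + 1L, width)
    for (s in rev(l$sublayers)) d2 <- s$backward(d2)
    cpp_chan_concat_perm(d1, d2, dim(d1), dim(d2), integer(0))
  }
  l
}

## ---- parameter/optimizer plumbing ------------------------------------------

# Flat list of every parameter-bearing layer (descending into composites).
flatten_layers <- function(layers) {
  out <- list()
  for (l in layers) {
    if (!is.null(l$sublayers)) out <- c(out, flatten_layers(l$sublayers))
    if (length(l$params) > 0) out <- c(out, list(l))
  }
  out
}
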