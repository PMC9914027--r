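# Pointwise nonlinearities and their derivatives. GELU uses the exact
# Gaussian CDF form x * pnorm(x) rather than the tanh approximation.

act_fun <- function(name) {
  switch(name,
    gelu = function(x) x * pnorm(x),
    relu = function(x) pmax(x, 0),
    leakyrelu = function(x) ifelse(x > 0, x, 0.01 * x),
    tanh = function(x) tanh(x),
    sigmoid = function(x) 1 / (1 + exp(-x)),
    stop("unknown activation: ", name)
  )
}

act_grad <- function(name) {
  switch(name,
    gelu = function(x, y) pnorm(x) + x * dnorm(x),
    relu = function(x, y) (x > 0) + 0,
    leakyrelu = function(x, y) ifelse(x > 0, 1, 0.01),
    tanh = function(x, y) 1 - y^2,
    sigmoid = function(x, y) y * (1 - y),
    stop("unknown activation: ", name)
  )
}

activation_menu <- function() c("gelu", "relu", "leakyrelu", "tanh", "sigmoid")

# Clip to [0, 1] preserving dim attributes.
clamp01 <- function(x) {
  d <- dim(x)
  x <- pmin(pmax(x, 0), 1)
  dim(x) <- d
  x
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}
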