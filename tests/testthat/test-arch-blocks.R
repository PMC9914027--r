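test_that("channel shuffle matches the reshape/transpose oracle and inverts", {
  # G = 1 is the identity
  x <- array(rnorm(3 * 3 * 6 * 2), c(3, 3, 6, 2))
  expect_identical(channel_shuffle(x, 1), x)

  # C = 4, G = 2: labelled channels [c0,c1,c2,c3] -> [c0,c2,c1,c3]
  lab <- array(0, c(1, 1, 4, 1))
  lab[1, 1, , 1] <- 1:4
  expect_equal(as.vector(channel_shuffle(lab, 2)), c(1, 3, 2, 4))

  # oracle + double-shuffle inverse over a grid of (C, G)
  for (C in c(4L, 6L, 12L, 24L)) {
    for (G in Filter(function(g) C %% g == 0, 1:C)) {
      expect_identical(shuffle_index(C, G), shuffle_oracle(C, G),
                       info = sprintf("C=%d G=%d", C, G))
      y <- array(rnorm(2 * 2 * C), c(2, 2, C, 1))
      expect_equal(channel_shuffle(channel_shuffle(y, G), C %/% G), y)
      # bijection: channel sums conserved exactly
      expect_identical(sort(apply(channel_shuffle(y, G), 3, sum)),
                       sort(apply(y, 3, sum)))
    }
  }

  expect_error(channel_shuffle(x, 4), "not divisible")
  expect_error(shuffle_index(10, 3), "10")
})

test_that("conv_param_count reproduces the dense and depthwise closed forms", {
  expect_identical(conv_param_count(conv_spec(1, 1, 1, 1)), 1L)
  expect_identical(conv_param_count(conv_spec(3, 3, 64, 128)), 73728L)
  # depthwise special case: k*k*C
  expect_identical(conv_param_count(conv_spec(3, 3, 64, 64, groups = 64)),
                   576L)
  # agrees with weight-array enumeration on random specs
  set.seed(11)
  for (i in 1:50) {
    g <- sample(c(1L, 1L, 2L, 4L), 1)
    cin <- g * sample(1:8, 1)
    s <- conv_spec(sample(1:5, 1), sample(1:5, 1), cin,
                   g * sample(1:8, 1), groups = g,
                   bias = runif(1) < 0.5)
    expect_identical(conv_param_count(s), as.integer(enumerate_conv_weights(s)))
  }
})

test_that("depthwise-separable convolution has the k2C + C*out parameters", {
  x1 <- array(rnorm(4 * 4), c(4, 4, 1))
  y <- dw_separable_conv(x1, conv_spec(1, 1, 1, 1))
  expect_equal(attr(y, "n_params"), 2)

  x <- array(rnorm(6 * 6 * 64), c(6, 6, 64, 1))
  y <- dw_separable_conv(x, conv_spec(3, 3, 64, 128))
  expect_equal(attr(y, "n_params"), 576 + 8192)
  expect_identical(dim(y)[3], 128L)

  # unit depthwise kernel + identity pointwise reproduces a 1-channel map
  xi <- array(rnorm(5 * 5), c(5, 5, 1))
  dw <- array(0, c(3, 3, 1, 1)); dw[2, 2, 1, 1] <- 1
  yi <- dw_separable_conv(xi, conv_spec(3, 3, 1, 1),
                          weights = list(dw = dw, pw = array(1, c(1, 1, 1, 1))))
  expect_equal(array(yi, dim(xi)), xi)
})

test_that("SE block gates lie in (0,1) and match hand arithmetic", {
  cfg <- se_config(4, 2)
  x <- array(rnorm(5 * 5 * 4 * 2), c(5, 5, 4, 2))

  # all-zero excitation weights: sigmoid(0) = 0.5 gate everywhere
  zw <- list(W1 = matrix(0, 2, 4), b1 = rep(0, 2),
             W2 = matrix(0, 4, 2), b2 = rep(0, 4))
  y <- se_block(x, cfg, weights = zw)
  expect_equal(array(y, dim(x)), 0.5 * x)

  # gates in (0,1) imply |output| <= |input| elementwise
  set.seed(2)
  y2 <- se_block(x, cfg)
  expect_true(all(abs(y2) <= abs(x) + 1e-12))
  g <- attr(y2, "gate")
  expect_true(all(g > 0 & g < 1))

  # C = 2, r = 1 hand example on constant planes (1, 2):
  # z = (1, 2); identity first layer; GELU x*Phi(x) with Phi(1) =
  # 0.8413447461, Phi(2) = 0.9772498681 -> (0.8413447, 1.9544997);
  # W2 = [[0.5, 0], [0, -0.5]] -> (0.4206724, -0.9772499);
  # sigmoid -> (0.6036441, 0.2734378)
  xc <- array(0, c(3, 3, 2, 1))
  xc[, , 1, 1] <- 1; xc[, , 2, 1] <- 2
  w <- list(W1 = diag(2), b1 = c(0, 0),
            W2 = matrix(c(0.5, 0, 0, -0.5), 2, 2), b2 = c(0, 0))
  yc <- se_block(xc, se_config(2, 1), weights = w)
  expect_equal(as.vector(attr(yc, "gate")),
               c(1 / (1 + exp(-0.5 * 0.8413447461)),
                 1 / (1 + exp(0.5 * 2 * 0.9772498681))),
               tolerance = 1e-6)

  expect_error(se_block(x, se_config(8, 2)), "channels")
})

test_that("SE gate saturates to 1 for large positive logits", {
  cfg <- se_config(4, 2)
  x <- array(rnorm(4 * 4 * 4), c(4, 4, 4, 1))
  w <- list(W1 = matrix(0, 2, 4), b1 = rep(50, 2),
            W2 = matrix(0, 4, 2), b2 = rep(50, 4))
  y <- se_block(x, cfg, weights = w)
  expect_equal(array(y, dim(x)), x, tolerance = 1e-12)
})

test_that("shuffle unit is a width-preserving split/transform/concat/shuffle", {
  set.seed(4)
  x <- array(rnorm(6 * 6 * 8 * 2), c(6, 6, 8, 2))

  # with vs without shuffle differ only by the fixed G = 2 permutation
  set.seed(9); y_on <- shuffle_unit(x, 8, use_shuffle = TRUE)
  set.seed(9); y_off <- shuffle_unit(x, 8, use_shuffle = FALSE)
  perm <- shuffle_index(8, 2)
  expect_equal(y_on, y_off[, , perm, , drop = FALSE],
               ignore_attr = TRUE)
  expect_identical(dim(y_on), dim(x))

  # zeroed transform branch: the identity half passes through untouched
  yz <- shuffle_unit(x, 8, use_shuffle = FALSE, init = "zero")
  expect_equal(yz[, , 1:4, ], x[, , 1:4, ])
  expect_true(all(yz[, , 5:8, ] == 0))

  # parameter count at width 64: 2*(C/2)^2 + 9*(C/2) + 3 BNs of C params
  y64 <- shuffle_unit(array(rnorm(4 * 4 * 64), c(4, 4, 64, 1)), 64)
  expect_identical(attr(y64, "n_params"), 2 * 32^2 + 9 * 32 + 3 * 64)

  expect_error(shuffle_unit(x, 7), "even")
})
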