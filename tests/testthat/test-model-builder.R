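test_that("canonical configuration meets the 1.9 M parameter budget", {
  set.seed(1)
  model <- build_model(model_config())
  rep <- count_parameters(model)

  # closed-form sum assembled independently from the architecture:
  # stem 3x3 conv + BN, 1x1 expansion, per-stage units + SE + expansions,
  # and the two-layer head
  unit <- function(C) 2 * (C / 2)^2 + 9 * (C / 2) + 3 * C
  se <- function(C) 2 * C * (C %/% 16) + (C %/% 16) + C
  w <- c(64, 128, 256, 512)
  expected <- 27 * 24 + 2 * 24 + 24 * 64 + 2 * 64 +
    sum(c(3, 7, 10, 9) * unit(w)) + sum(se(w)) +
    sum(w[1:3] * w[2:4] + 2 * w[2:4]) +
    512 * 128 + 128 + 128 * 7 + 7
  expect_identical(rep$total_params, expected)
  expect_true(rep$total_params >= 1.85e6 && rep$total_params <= 1.95e6)
  expect_identical(rep$params_millions, 1.9)

  # breakdown sums exactly to the total
  expect_identical(sum(rep$breakdown), rep$total_params)

  # enumeration oracle: walk the serialized weight state and count scalars
  count_state <- function(s) {
    n <- sum(vapply(s$params, length, integer(1)))
    if (!is.null(s$sublayers))
      n <- n + sum(vapply(s$sublayers,
                          function(ss) sum(vapply(ss$params, length,
                                                  integer(1))),
                          numeric(1)))
    n
  }
  enum <- sum(vapply(dermshuffle:::model_state(model), count_state,
                     numeric(1)))
  expect_identical(enum, rep$total_params)
})

test_that("parameter count is invariant to the shuffle switch", {
  cfg_on <- tiny_model_config()
  cfg_off <- tiny_model_config()
  cfg_off$use_shuffle <- FALSE
  set.seed(1); n_on <- count_parameters(build_model(cfg_on))$total_params
  set.seed(1); n_off <- count_parameters(build_model(cfg_off))$total_params
  expect_identical(n_on, n_off)
})

test_that("forward pass yields a normalized 7-class probability vector", {
  set.seed(5)
  model <- build_model(tiny_model_config(input_size = 32L))
  x <- array(runif(32 * 32 * 3 * 3), c(32, 32, 3, 3))
  p <- predict_proba(model, x)
  expect_identical(dim(p), c(7L, 3L))
  expect_equal(colSums(p), rep(1, 3), tolerance = 1e-6)
  expect_identical(rownames(p), lesion_classes())

  # deterministic in evaluation mode
  expect_identical(p, predict_proba(model, x))

  # softmax shift invariance: adding a constant to all logits via the
  # output-layer bias leaves the probabilities unchanged
  model$layers$head_fc2$params$b <- model$layers$head_fc2$params$b + 3.7
  expect_equal(predict_proba(model, x), p, tolerance = 1e-12)
})

test_that("four 2x2 pools reduce a 256 input to 16x16 before global pooling", {
  set.seed(5)
  model <- build_model(tiny_model_config(input_size = 256L))
  x <- array(runif(256 * 256 * 3), c(256, 256, 3, 1))
  for (nm in names(model$layers)) {
    x <- model$layers[[nm]]$forward(x, FALSE)
    if (nm == "stage4_pool") break
  }
  expect_identical(dim(x)[1:2], c(16L, 16L))

  expect_error(build_model(tiny_model_config(input_size = 100L)),
               "divisible")
})

test_that("budget calibration repairs an over-budget configuration", {
  cfg <- model_config()
  expect_identical(calibrate_budget(cfg), cfg)   # already in range

  over <- model_config()
  over$stage_repeats[4] <- over$stage_repeats[4] + 2L
  fixed <- calibrate_budget(over)
  n <- dermshuffle:::count_config_params(fixed)
  expect_true(n >= 1.85e6 && n <= 1.95e6)
  expect_identical(fixed$stage_repeats[4], cfg$stage_repeats[4])

  # deterministic: repeated runs return identical configs
  expect_identical(calibrate_budget(over), fixed)

  # impossible budget errors with the closest count
  expect_error(calibrate_budget(cfg, budget = c(1, 2)), "closest")
})

test_that("checkpoints round-trip weights and configuration", {
  set.seed(8)
  model <- build_model(tiny_model_config(input_size = 16L))
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  p1 <- predict_proba(model, x)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(model, ck)
  expect_true(file.exists(paste0(ck, ".json")))
  m2 <- load_checkpoint(ck)
  expect_equal(predict_proba(m2, x), p1, tolerance = 1e-12)
})
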