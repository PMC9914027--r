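test_that("preprocess resizes bilinearly and rescales by 1/255", {
  # constant input of any size: only the intensity scale changes
  x <- array(128, c(40, 60, 3))
  y <- preprocess(x, size = 256)
  expect_identical(dim(y), c(256L, 256L, 3L))
  expect_equal(range(y), rep(128 / 255, 2), tolerance = 1e-9)

  # already at target size: values only rescaled
  x2 <- array(runif(256 * 256 * 3, 0, 255), c(256, 256, 3))
  expect_equal(preprocess(x2), x2 / 255)

  # 512 -> 256 checkerboard: the mean is preserved within 1%
  cb <- array(0, c(512, 512, 3))
  cb[, , ] <- ((row(cb[, , 1]) + col(cb[, , 1])) %% 2) * 255
  y3 <- preprocess(cb, size = 256)
  expect_equal(mean(y3), mean(cb / 255), tolerance = 0.01)

  expect_error(preprocess(matrix(1, 4, 4)), "RGB")
})

test_that("centroid ROI crop finds dark lesions and falls back to center", {
  # centered dark blob: crop centered at the image center
  img <- array(1, c(80, 80, 3))
  blob <- (row(img[, , 1]) - 40)^2 + (col(img[, , 1]) - 40)^2 < 64
  for (ch in 1:3) { p <- img[, , ch]; p[blob] <- 0; img[, , ch] <- p }
  cr <- roi_crop_centroid(img)
  expect_equal(attr(cr, "center"), c(40, 40), tolerance = 1.5)

  # uniform image: geometric center, half-short-side floor on the crop
  u <- array(0.5, c(64, 96, 3))
  cu <- roi_crop_centroid(u)
  expect_equal(attr(cu, "center"), c(32.5, 48.5))
  expect_gte(attr(cu, "side"), 32)

  # dark disc at (0.25 H, 0.25 W) on white ground: crop center within 5 px
  w <- array(1, c(120, 120, 3))
  disc <- (row(w[, , 1]) - 30)^2 + (col(w[, , 1]) - 30)^2 < 144
  for (ch in 1:3) { p <- w[, , ch]; p[disc] <- 0.05; w[, , ch] <- p }
  cw <- roi_crop_centroid(w)
  ctr <- attr(cw, "center")
  expect_lt(sqrt(sum((ctr - c(30, 30))^2)), 5)
  expect_gte(attr(cw, "side"), 60)
})

test_that("transform sampling follows the configured distributions", {
  cfg <- augmentation_config(seed = 123)
  set.seed(cfg$seed)
  tfs <- replicate(1e4, sample_transform(cfg), simplify = FALSE)
  rot <- vapply(tfs, `[[`, 0, "rotation")
  expect_lt(abs(mean(rot)), 1)
  expect_true(all(abs(rot) <= 30))
  hf <- vapply(tfs, `[[`, TRUE, "hflip")
  expect_lt(abs(mean(hf) - 0.5), 0.02)
  br <- vapply(tfs, `[[`, 0, "brightness")
  expect_true(all(br >= 0.9 & br <= 1.1))
  ns <- vapply(tfs, `[[`, 0, "noise_sd")
  expect_true(all(ns >= 0 & ns <= 0.45))

  # same seed: identical transform sequence
  set.seed(7); a <- replicate(5, sample_transform(cfg), simplify = FALSE)
  set.seed(7); b <- replicate(5, sample_transform(cfg), simplify = FALSE)
  expect_identical(a, b)
})

test_that("zeroed config yields the identity transform", {
  z <- augmentation_config(rotation_deg = 0, brightness_range = c(1, 1),
                           zoom = 0, shear = 0, hflip = FALSE, vflip = FALSE,
                           noise = 0)
  set.seed(1)
  tf <- sample_transform(z)
  img <- generate_image("NV", synthetic_spec(), seed = 3)$image
  expect_equal(apply_transform(img, tf), img, tolerance = 1e-12)
})

test_that("transforms replay bit-identically and keep pixels in [0,1]", {
  img <- generate_image("BKL", synthetic_spec(), seed = 9)$image
  set.seed(5)
  for (i in 1:5) {
    tf <- sample_transform(augmentation_config())
    a <- apply_transform(img, tf)
    expect_identical(a, apply_transform(img, tf))
    expect_true(all(a >= 0 & a <= 1))
  }
})

test_that("balance_augment hits the target exactly in both directions", {
  # toy counts {A:3, B:1}, target 4 -> augmented {A:1, B:3}
  toy <- data.frame(id = c("a1", "a2", "a3", "b1"), path = NA_character_,
                    label = c("A", "A", "A", "B"), provenance = "original",
                    origin_id = NA_character_,
                    transform_json = NA_character_,
                    stringsAsFactors = FALSE)
  bal <- balance_augment(toy, target_per_class = 4,
                         cfg = augmentation_config(seed = 1))
  expect_equal(unname(manifest_counts(bal)), c(4, 4))
  expect_equal(sum(bal$provenance == "augmented" & bal$label == "A"), 1)
  expect_equal(sum(bal$provenance == "augmented" & bal$label == "B"), 3)
  # round-robin: each B augmentation references the single original
  expect_true(all(bal$origin_id[bal$provenance == "augmented" &
                                  bal$label == "B"] == "b1"))

  # idempotence
  expect_identical(balance_augment(bal, 4, augmentation_config(seed = 1)),
                   bal)

  # oversized class: seeded downsampling without replacement
  big <- data.frame(id = sprintf("c%02d", 1:10), path = NA_character_,
                    label = "C", provenance = "original",
                    origin_id = NA_character_,
                    transform_json = NA_character_, stringsAsFactors = FALSE)
  dn <- balance_augment(big, target_per_class = 6,
                        cfg = augmentation_config(seed = 2))
  expect_equal(unname(manifest_counts(dn)), 6)
  expect_equal(sum(dn$provenance == "downsampled-out"), 4)
  expect_identical(balance_augment(big, 6, augmentation_config(seed = 2)), dn)

  expect_error(balance_augment(toy[0, ], 4), "at least one")
})

test_that("materialized augmented records replay bit-identically", {
  dir <- tempfile("mat")
  m <- make_fixture(c(AK = 3, MEL = 1), synthetic_spec(image_size = 32L),
                    dir = dir, seed = 5)
  out <- file.path(dir, "balanced")
  bal <- balance_augment(m, target_per_class = 3,
                         cfg = augmentation_config(seed = 11),
                         out_dir = out)
  aug <- bal[bal$provenance == "augmented", ]
  expect_equal(nrow(aug), 2)
  expect_true(all(file.exists(aug$path)))
  for (i in seq_len(nrow(aug))) {
    written <- load_image(aug$path[i])
    # PNG quantizes to 8 bits; replaying the logged transform must agree
    replayed <- replay_augmented(bal, aug$id[i])
    expect_equal(written, replayed, tolerance = 1 / 255)
  }
})

test_that("manifests round-trip through CSV", {
  m <- make_fixture(c(DF = 2, VASC = 2), synthetic_spec(image_size = 32L),
                    seed = 8)
  path <- file.path(dirname(m$path[1]), "..", "manifest.csv")
  m2 <- read_manifest(path)
  expect_equal(m2$id, m$id)
  expect_equal(m2$label, m$label)
})
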