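# Shared, lazily built fixtures. Expensive objects (the archive-scale image
# fixture, the trained reduced-width model) are built once per test session
# and reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# The archive imbalance fixture (500/2000/2000/200/3000/6000/300 at 64x64),
# materialized as PNGs. Shared by the fixture-integrity and balancing tests.
table2_fixture <- function() {
  cache_get("table2", function() {
    dir <- file.path(tempdir(), "ds_table2_fixture")
    manifest <- make_fixture("ham10000", synthetic_spec(image_size = 64L),
                             dir = dir, seed = 42L)
    list(dir = dir, manifest = manifest)
  })
}

# Reduced-width configuration used for desk-scale training tests.
reduced_model_config <- function() {
  model_config(stem_channels = 4L, stage_widths = c(4L, 8L, 16L, 32L),
               stage_repeats = c(1L, 1L, 1L, 1L), se_reduction = 4L,
               head_width = 32L, input_size = 64L)
}

# 100 images per class at 64x64, deterministic.
synthetic_training_set <- function() {
  cache_get("train700", function() {
    spec <- synthetic_spec()
    imgs <- vector("list", 700)
    labs <- character(700)
    k <- 0
    for (cl in lesion_classes()) {
      for (i in 1:100) {
        k <- k + 1
        imgs[[k]] <- generate_image(cl, spec, seed = 7000 + k)$image
        labs[k] <- cl
      }
    }
    list(images = imgs, labels = factor(labs, levels = lesion_classes()))
  })
}

# The reduced-width model trained 15 epochs on the synthetic set (seed 0).
# Shared by the learnability and Grad-CAM acceptance tests.
trained_reduced_model <- function() {
  cache_get("trained", function() {
    data <- synthetic_training_set()
    set.seed(0)
    model <- build_model(reduced_model_config())
    cfg <- train_config(optimizer = "sgd", base_lr = 0.01, epochs = 15L,
                        seed = 0L)
    fit <- train(model, data, cfg = cfg)
    fit
  })
}

# Tiny model/config helpers for fast structural tests.
tiny_model_config <- function(n_classes = 7L, input_size = 16L) {
  model_config(stem_channels = 4L, stage_widths = c(4L, 4L, 4L, 4L),
               stage_repeats = c(1L, 1L, 1L, 1L), se_reduction = 2L,
               head_width = 8L, n_classes = n_classes,
               input_size = input_size)
}

# Per-class weight-array enumeration for a convolution: the independent
# counting oracle (materialize every scalar, count lengths).
enumerate_conv_weights <- function(spec) {
  n <- length(array(0, c(spec$kernel_h, spec$kernel_w,
                         spec$in_channels %/% spec$groups,
                         spec$out_channels)))
  if (spec$bias) n <- n + length(numeric(spec$out_channels))
  n
}

# Brute-force channel-shuffle oracle: reshape the 0-based index list into a
# (G, N) matrix row-by-row, transpose, flatten.
shuffle_oracle <- function(C, G) {
  idx <- matrix(0:(C - 1), nrow = G, byrow = TRUE)  # (G, N) row-major
  # numpy-style row-major flatten of the transpose == R column-major of idx
  as.vector(idx) + 1L
}

# Independent metrics oracle: rebuild label/prediction vectors from a
# confusion matrix and compute each statistic from indicator vectors
# (MCC via the Pearson correlation identity).
oracle_binary_metrics <- function(cm, k) {
  nc <- nrow(cm)
  counts <- as.vector(t(cm))   # row-major: (true 1, pred 1..nc), (true 2, ...)
  truth <- rep(rep(seq_len(nc), each = nc), counts)
  pred <- rep(rep(seq_len(nc), nc), counts)
  it <- as.numeric(truth == k)
  ip <- as.numeric(pred == k)
  acc <- 100 * mean(it == ip)
  se <- if (sum(it) == 0) 0 else 100 * mean(ip[it == 1] == 1)
  sp <- if (sum(1 - it) == 0) 0 else 100 * mean(ip[it == 0] == 0)
  pr <- if (sum(ip) == 0) 0 else 100 * mean(it[ip == 1] == 1)
  p <- pr / 100; r <- se / 100
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  mcc <- if (length(it) < 2 || stats::sd(it) == 0 || stats::sd(ip) == 0) 0
         else stats::cor(it, ip)
  c(acc = acc, se = se, sp = sp, pr = pr, f1 = f1, mcc = mcc)
}

# Bounding box (row range, col range) of a logical mask.
mask_bbox <- function(mask) {
  list(rows = range(which(rowSums(mask) > 0)),
       cols = range(which(colSums(mask) > 0)))
}
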