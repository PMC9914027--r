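# Synthetic dermoscopy-like image generator. Produces labeled, visually
# separable images for the seven lesion classes so the whole pipeline is
# testable without any dataset download. Images are skin-toned backgrounds
# with a single perturbed-ellipse lesion whose color, border irregularity,
# texture and globule pattern are class-specific.

#' Synthetic generator specification
#'
#' Per-class generative parameters. Classes differ in lesion color (the
#' dominant cue), ellipse eccentricity, border-irregularity amplitude and
#' frequency, texture, and the presence of globule dots:
#' red scaly AK, pearly pink BCC, tan waxy BKL, small dark-brown DF, dark
#' irregular MEL with globules, regular brown NV with globules, and
#' red-purple VASC.
#'
#' @param image_size Square image extent in pixels (64 for tests, up to 256).
#' @param area_range Lesion area as a fraction of the image, drawn uniformly.
#' @param color_jitter Per-image Gaussian sd added to the class lesion color.
#' @return An object of class `synthetic_spec` with a `classes` table.
#' @export
synthetic_spec <- function(image_size = 64L, area_range = c(0.08, 0.35),
                           color_jitter = 0.015) {
  classes <- list(
    AK = list(rgb = c(0.80, 0.32, 0.28), ecc = 1.6, border_amp = 0.25,
               border_freq = 7, tex_freq = 6, tex_amp = 0.06, globules = FALSE),
    BCC = list(rgb = c(0.88, 0.62, 0.58), ecc = 1.3, border_amp = 0.10,
               border_freq = 5, tex_freq = 2, tex_amp = 0.03, globules = FALSE),
    BKL = list(rgb = c(0.62, 0.45, 0.22), ecc = 1.5, border_amp = 0.35,
               border_freq = 9, tex_freq = 8, tex_amp = 0.08, globules = FALSE),
    DF = list(rgb = c(0.42, 0.26, 0.16), ecc = 1.2, border_amp = 0.08,
               border_freq = 4, tex_freq = 3, tex_amp = 0.03, globules = FALSE),
    MEL = list(rgb = c(0.22, 0.16, 0.14), ecc = 2.0, border_amp = 0.45,
               border_freq = 11, tex_freq = 5, tex_amp = 0.05, globules = TRUE),
    NV = list(rgb = c(0.55, 0.34, 0.14), ecc = 1.3, border_amp = 0.12,
               border_freq = 5, tex_freq = 4, tex_amp = 0.04, globules = TRUE),
    VASC = list(rgb = c(0.62, 0.22, 0.42), ecc = 1.4, border_amp = 0.15,
               border_freq = 6, tex_freq = 3, tex_amp = 0.04, globules = FALSE)
  )
  s <- list(image_size = as.integer(image_size),
            area_range = area_range,
            color_jitter = color_jitter,
            skin_rgb = c(0.93, 0.78, 0.70),
            classes = classes)
  class(s) <- "synthetic_spec"
  s
}

#' Generate one synthetic lesion image
#'
#' Draws a skin background with mild gradient and grain, places one
#' class-parameterized lesion (rotated ellipse with a sinusoidally
#' perturbed border, class color with per-image jitter, sinusoidal texture,
#' optional darker globule dots), and returns the image together with the
#' binary lesion mask. Lesion area is constrained to the spec's
#' `area_range` (default 8-35% of the image) and the lesion is always
#' darker than the surrounding skin, so centroid-based ROI selection has
#' signal to work with. Deterministic given `seed`.
#'
#' @param class_label One of [lesion_classes()].
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; `NULL` draws from the current RNG state.
#' @return List with `image` (H, W, 3 array in `[0, 1]`), `mask` (H x W
#'   logical), and `class_label`.
#' @export
generate_image <- function(class_label, spec = synthetic_spec(), seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!class_label %in% names(spec$classes))
    stop("unknown class label: ", class_label)
  if (!is.null(seed)) set.seed(seed)
  p <- spec$classes[[class_label]]
  s <- spec$image_size

  # background: skin tone + vertical illumination gradient + grain
  grad <- matrix(rep(seq(-0.02, 0.02, length.out = s), each = s), s, s)
  img <- array(0, c(s, s, 3))
  for (ch in 1:3)
    img[, , ch] <- spec$skin_rgb[ch] + grad +
      matrix(rnorm(s * s, sd = 0.01), s, s)

  # lesion geometry
  cx <- runif(1, 0.32, 0.68) * s
  cy <- runif(1, 0.32, 0.68) * s
  frac <- runif(1, spec$area_range[1], spec$area_range[2])
  rho <- runif(1, 1, p$ecc)
  ab <- s^2 * frac / pi
  a <- sqrt(ab * rho); b <- sqrt(ab / rho)
  theta <- runif(1, 0, pi)
  phi0 <- runif(1, 0, 2 * pi)
  X <- matrix(seq_len(s), s, s)
  Y <- matrix(seq_len(s), s, s, byrow = TRUE)
  dx <- X - cx; dy <- Y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  t_r <- sqrt((u / a)^2 + (v / b)^2)
  bound <- 1 + p$border_amp * sin(p$border_freq * atan2(v, u) + phi0)
  ratio <- t_r / pmax(bound, 0.3)
  alpha <- pmin(pmax((1 - ratio) / 0.08 + 0.5, 0), 1)   # soft 8%-wide edge
  mask <- alpha > 0.5

  # lesion coloring: class color + jitter + texture
  col <- pmin(1, pmax(0, p$rgb + rnorm(3, sd = spec$color_jitter)))
  tex <- p$tex_amp * sin(2 * pi * p$tex_freq * u / s) *
    sin(2 * pi * p$tex_freq * v / s)
  les <- array(0, c(s, s, 3))
  for (ch in 1:3) les[, , ch] <- col[ch] + tex

  if (p$globules) {
    nd <- sample(4:9, 1)
    inside <- which(mask)
    if (length(inside) > 0) {
      pts <- sample(inside, min(nd, length(inside)))
      gx <- ((pts - 1) %% s) + 1
      gy <- ((pts - 1) %/% s) + 1
      sig <- max(1, 0.03 * s)
      for (q in seq_along(pts)) {
        bump <- exp(-((X - gx[q])^2 + (Y - gy[q])^2) / (2 * sig^2))
        for (ch in 1:3) les[, , ch] <- les[, , ch] - 0.25 * bump
      }
    }
  }

  for (ch in 1:3)
    img[, , ch] <- img[, , ch] * (1 - alpha) + les[, , ch] * alpha
  img <- img + array(rnorm(s * s * 3, sd = 0.008), c(s, s, 3))
  img <- clamp01(img)
  list(image = img, mask = mask, class_label = class_label)
}

#' Class-count presets
#'
#' `"ham10000"` reproduces the archive imbalance used throughout the
#' package: AK 500, BCC 2000, BKL 2000, DF 200, MEL 3000, NV 6000,
#' VASC 300 (14,000 images in total).
#'
#' @param preset Preset name.
#' @return Named integer vector of per-class counts.
#' @export
#' @examples
#' sum(class_count_preset("ham10000")) # 14000
class_count_preset <- function(preset = "ham10000") {
  switch(preset,
    ham10000 = c(AK = 500L, BCC = 2000L, BKL = 2000L, DF = 200L,
                 MEL = 3000L, NV = 6000L, VASC = 300L),
    stop("unknown preset: ", preset)
  )
}

#' Generate a labeled image fixture
#'
#' Writes `counts[k]` synthetic images per class as PNG files under
#' `dir/<class>/` and returns (and writes) the accompanying manifest. Each
#' image gets its own derived seed, so the fixture is reproducible
#' image-by-image.
#'
#' @param counts Named per-class counts, or a preset name for
#'   [class_count_preset()].
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @param seed Base integer seed.
#' @param write_images Write PNGs; `FALSE` returns the manifest only (paths
#'   are still filled in but no files are created).
#' @return The manifest data.frame (columns `id`, `path`, `label`,
#'   `provenance`, `origin_id`, `transform_json`), also written to
#'   `dir/manifest.csv`.
#' @export
make_fixture <- function(counts = "ham10000", spec = synthetic_spec(),
                         dir = tempfile("fixture"), seed = 0L,
                         write_images = TRUE) {
  if (is.character(counts)) counts <- class_count_preset(counts)
  if (any(counts < 1)) stop("all class counts must be positive")
  classes <- names(counts)
  if (!all(classes %in% names(spec$classes)))
    stop("counts name unknown classes: ",
         paste(setdiff(classes, names(spec$classes)), collapse = ", "))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(classes))
  idx <- 0L
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    n <- counts[[ci]]
    cdir <- file.path(dir, cl)
    if (write_images) dir.create(cdir, showWarnings = FALSE)
    ids <- sprintf("%s_%05d", cl, seq_len(n))
    paths <- file.path(cdir, paste0(ids, ".png"))
    if (write_images) {
      for (i in seq_len(n)) {
        g <- generate_image(cl, spec, seed = seed + idx + i)
        png::writePNG(g$image, paths[i])
      }
    }
    idx <- idx + n
    rows[[ci]] <- data.frame(id = ids, path = paths, label = cl,
                             provenance = "original", origin_id = NA_character_,
                             transform_json = NA_character_,
                             stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  manifest
}
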