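# Manifest-driven dataset assembly: ROI cropping, preprocessing, and the
# class-balancing augmentation engine.
#
# A manifest is a data.frame with one row per image record:
#   id, path, label, provenance (original | augmented | downsampled-out),
#   origin_id (the source record of an augmented copy), transform_json
#   (the sampled transform parameters of an augmented copy).

#' Read / write a dataset manifest
#'
#' @param path CSV file with header
#'   `id,path,label,provenance,origin_id,transform_json`.
#' @param manifest A manifest data.frame.
#' @return `read_manifest` returns the data.frame; `write_manifest` returns
#'   `path` invisibly.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(transform_json = "character",
                               origin_id = "character"))
  need <- c("id", "path", "label", "provenance", "origin_id", "transform_json")
  if (!all(need %in% names(m)))
    stop("manifest is missing columns: ",
         paste(setdiff(need, names(m)), collapse = ", "))
  m
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Active per-class counts of a manifest
#'
#' Tallies records that are not marked `downsampled-out`.
#'
#' @param manifest A manifest data.frame.
#' @return Named integer vector, one entry per class present.
#' @export
manifest_counts <- function(manifest) {
  act <- manifest[manifest$provenance != "downsampled-out", ]
  tab <- table(act$label)
  setNames(as.integer(tab), names(tab))
}

#' Load an image from disk
#'
#' @param path PNG or JPEG file.
#' @return Numeric (H, W, 3) array in `[0, 1]`.
#' @export
load_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("png")) {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    EBImage::imageData(EBImage::readImage(path))
  } else stop("unsupported image format: ", ext)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Resize and rescale an image
#'
#' Bilinear resize to a uniform square extent (default 256 x 256 x 3) and
#' intensity rescale by 1/255 into `[0, 1]`.
#'
#' @param image Numeric (H, W, 3) array. Values are assumed to be on the
#'   0-255 scale when `rescale = TRUE`; pass `rescale = FALSE` for images
#'   already in `[0, 1]` (e.g. from [load_image()]).
#' @param size Output extent in pixels.
#' @param rescale Apply the 1/255 intensity rescale.
#' @return Numeric (size, size, 3) array.
#' @export
preprocess <- function(image, size = 256L, rescale = TRUE) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3 || d[3] != 3)
    stop("expected an RGB (H, W, 3) array")
  if (d[1] < 1 || d[2] < 1) stop("zero-size image")
  if (d[1] != size || d[2] != size) {
    img <- EBImage::Image(image, colormode = "Color")
    image <- EBImage::imageData(EBImage::resize(img, w = size, h = size))
  }
  if (rescale) image <- image / 255
  image
}

#' Centroid-based region-of-interest crop
#'
#' Lesions are darker than the surrounding skin, so the lesion position is
#' estimated as the intensity-weighted centroid of (1 - normalized
#' grayscale). The crop is the largest square centered on that centroid
#' that fits inside the image, never smaller than half the short side
#' (the center is shifted inward when necessary). A uniform image falls
#' back to the geometric center.
#'
#' @param image Numeric (H, W, 3) array.
#' @return The cropped (side, side, 3) array with attributes `center`
#'   (the centroid used) and `side`.
#' @export
roi_crop_centroid <- function(image) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3 || d[3] != 3)
    stop("expected an RGB (H, W, 3) array")
  H <- d[1]; W <- d[2]
  gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  rng <- range(gray)
  if (diff(rng) < 1e-8) {
    ci <- (H + 1) / 2
    cj <- (W + 1) / 2
  } else {
    wgt <- 1 - (gray - rng[1]) / diff(rng)
    tot <- sum(wgt)
    ci <- sum(row(gray) * wgt) / tot
    cj <- sum(col(gray) * wgt) / tot
  }
  short <- min(H, W)
  side <- floor(2 * min(ci - 1, H - ci, cj - 1, W - cj)) + 1
  side <- max(side, floor(short / 2))
  side <- min(side, short)
  i0 <- min(max(1, round(ci - side / 2)), H - side + 1)
  j0 <- min(max(1, round(cj - side / 2)), W - side + 1)
  out <- image[i0:(i0 + side - 1), j0:(j0 + side - 1), , drop = FALSE]
  attr(out, "center") <- c(ci, cj)
  attr(out, "side") <- side
  out
}

#' Augmentation configuration
#'
#' The transform parameter ranges of the balancing pipeline: rotation
#' sampled uniformly in +/-30 degrees, brightness factor in `[0.9, 1.1]`,
#' zoom +/-10%, shear +/-10%, horizontal and vertical flips with
#' probability 0.5, Gaussian noise with per-image sigma drawn uniformly
#' from `[0, 0.45]` on `[0, 1]`-scaled pixels, constant black fill for
#' out-of-frame pixels, and a fixed per-run seed.
#'
#' @param rotation_deg Half-width of the uniform rotation range (degrees).
#' @param brightness_range Multiplicative brightness factor range.
#' @param zoom,shear Symmetric half-widths of the zoom and shear ranges.
#' @param hflip,vflip Enable the Bernoulli(0.5) flips.
#' @param rescale Intensity rescale factor used by preprocessing.
#' @param noise Upper bound of the per-image uniform draw of Gaussian sigma.
#' @param fill Constant fill value for pixels mapped from outside the frame.
#' @param seed Integer seed fixed per balancing run.
#' @return An object of class `aug_config`.
#' @export
augmentation_config <- function(rotation_deg = 30, brightness_range = c(0.9, 1.1),
                                zoom = 0.1, shear = 0.1, hflip = TRUE,
                                vflip = TRUE, rescale = 1 / 255, noise = 0.45,
                                fill = 0, seed = 0L) {
  cfg <- list(rotation_deg = rotation_deg, brightness_range = brightness_range,
              zoom = zoom, shear = shear, hflip = isTRUE(hflip),
              vflip = isTRUE(vflip), rescale = rescale, noise = noise,
              fill = fill, seed = as.integer(seed))
  class(cfg) <- "aug_config"
  cfg
}

#' Sample one transform
#'
#' Independently samples every transform parameter from the configured
#' ranges using the current RNG state: rotation U(-r, r), brightness
#' U(lo, hi), zoom factor U(1 - z, 1 + z), shear U(-s, s), the two flips
#' Bernoulli(0.5), and the per-image Gaussian noise sigma U(0, noise). A
#' fresh noise seed is also drawn so the sampled transform replays to
#' bit-identical output.
#'
#' @param cfg An [augmentation_config()].
#' @return An object of class `ds_transform` recording all sampled
#'   parameters.
#' @export
sample_transform <- function(cfg = augmentation_config()) {
  tf <- list(
    rotation = runif(1, -cfg$rotation_deg, cfg$rotation_deg),
    brightness = runif(1, cfg$brightness_range[1], cfg$brightness_range[2]),
    zoom = runif(1, 1 - cfg$zoom, 1 + cfg$zoom),
    shear = runif(1, -cfg$shear, cfg$shear),
    hflip = cfg$hflip && runif(1) < 0.5,
    vflip = cfg$vflip && runif(1) < 0.5,
    noise_sd = runif(1, 0, cfg$noise),
    noise_seed = sample.int(.Machine$integer.max, 1),
    fill = cfg$fill
  )
  class(tf) <- "ds_transform"
  tf
}

#' Apply a sampled transform
#'
#' Flips, then a single bilinear affine warp combining rotation, zoom and
#' shear about the image center (constant fill outside the frame), then
#' the brightness factor, then seeded Gaussian noise; the result is clipped
#' to `[0, 1]`. Replaying the same `ds_transform` on the same image is
#' bit-identical.
#'
#' @param image Numeric (H, W, 3) array in `[0, 1]`.
#' @param tf A [sample_transform()] result.
#' @return Transformed (H, W, 3) array in `[0, 1]`.
#' @export
apply_transform <- function(image, tf) {
  stopifnot(inherits(tf, "ds_transform"))
  d <- dim(image)
  if (tf$hflip) image <- image[, d[2]:1, , drop = FALSE]
  if (tf$vflip) image <- image[d[1]:1, , , drop = FALSE]
  th <- tf$rotation * pi / 180
  # row-vector convention: out = in %*% A + t, composed about the center
  rot <- rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  shr <- rbind(c(1, tf$shear), c(0, 1))
  A <- (rot %*% shr) * tf$zoom
  ctr <- c((d[1] + 1) / 2, (d[2] + 1) / 2)
  off <- ctr - as.vector(ctr %*% A)
  m <- rbind(A, off)
  img <- EBImage::Image(image, colormode = "Color")
  out <- EBImage::imageData(EBImage::affine(img, m, filter = "bilinear",
                                            bg.col = tf$fill))
  out <- out * tf$brightness
  if (tf$noise_sd > 0) {
    rs <- get0(".Random.seed", envir = globalenv())
    set.seed(tf$noise_seed)
    out <- out + array(rnorm(prod(d), sd = tf$noise_sd), d)
    if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
  }
  clamp01(out)
}

#' Balance a dataset by augmentation and downsampling
#'
#' Brings every class to exactly `target_per_class` active records:
#' classes below target keep all originals and add augmented copies
#' (round-robin over the originals, each with a freshly sampled transform);
#' classes above target are subsampled without replacement, with dropped
#' records retained in the manifest under provenance `downsampled-out`.
#' All randomness derives from `cfg$seed`, and classes are processed in
#' sorted label order, so the output is reproducible. Already balanced
#' manifests pass through unchanged.
#'
#' When the manifest has on-disk images and `out_dir` is given, augmented
#' images are materialized as PNGs under `out_dir/<class>/`; otherwise the
#' augmented records carry their transform parameters in `transform_json`
#' and can be materialized later with [apply_transform()].
#'
#' @param manifest A manifest data.frame with at least one record per class.
#' @param target_per_class Target active count per class (default 4000,
#'   giving 28,000 records over the seven classes).
#' @param cfg An [augmentation_config()]; its seed drives the run.
#' @param out_dir Directory for materialized augmented images, or `NULL`
#'   to skip materialization.
#' @return The balanced manifest.
#' @export
balance_augment <- function(manifest, target_per_class = 4000L,
                            cfg = augmentation_config(), out_dir = NULL) {
  classes <- sort(unique(manifest$label[manifest$provenance != "downsampled-out"]))
  counts <- manifest_counts(manifest)
  if (any(counts < 1) || length(classes) == 0)
    stop("balancing requires at least one image per class")
  set.seed(cfg$seed)
  out <- manifest
  for (cl in classes) {
    act <- which(out$label == cl & out$provenance != "downsampled-out")
    n <- length(act)
    if (n == target_per_class) next
    if (n > target_per_class) {
      drop <- act[-sample(n, target_per_class)]
      out$provenance[drop] <- "downsampled-out"
      next
    }
    orig <- out[act[out$provenance[act] == "original"], ]
    if (nrow(orig) == 0) orig <- out[act, ]
    need <- target_per_class - n
    src <- rep(seq_len(nrow(orig)), length.out = need)
    if (!is.null(out_dir)) dir.create(file.path(out_dir, cl),
                                      recursive = TRUE, showWarnings = FALSE)
    new_rows <- vector("list", need)
    for (k in seq_len(need)) {
      o <- orig[src[k], ]
      tf <- sample_transform(cfg)
      nid <- sprintf("%s_aug%04d", o$id, k)
      npath <- if (!is.null(out_dir))
        file.path(out_dir, cl, paste0(nid, ".png")) else NA_character_
      if (!is.null(out_dir)) {
        img <- apply_transform(load_image(o$path), tf)
        png::writePNG(img, npath)
      }
      new_rows[[k]] <- data.frame(
        id = nid, path = npath, label = cl, provenance = "augmented",
        origin_id = o$id,
        transform_json = as.character(jsonlite::toJSON(unclass(tf),
                                                       auto_unbox = TRUE,
                                                       digits = NA)),
        stringsAsFactors = FALSE)
    }
    out <- rbind(out, do.call(rbind, new_rows))
  }
  rownames(out) <- NULL
  out
}

#' Rebuild the image of an augmented record
#'
#' Reads the record's origin image and replays the stored transform;
#' bit-identical to the image written during [balance_augment()].
#'
#' @param manifest The balanced manifest.
#' @param id Record id (must have provenance `augmented`).
#' @return Numeric (H, W, 3) array.
#' @export
replay_augmented <- function(manifest, id) {
  r <- manifest[manifest$id == id, ]
  if (nrow(r) != 1 || r$provenance != "augmented")
    stop("id ", id, " is not an augmented record")
  o <- manifest[manifest$id == r$origin_id, ]
  tf <- jsonlite::fromJSON(r$transform_json)
  class(tf) <- "ds_transform"
  apply_transform(load_image(o$path), tf)
}
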