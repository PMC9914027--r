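# Grad-CAM: class-specific spatial saliency from the gradient of a class
# logit with respect to a late convolutional feature map.

# Layer names that hold a spatial activation map and can be tapped.
gradcam_taps <- function(model) {
  nm <- names(model$layers)
  nm[grepl("^(stem|stage)", nm)]
}

#' Grad-CAM heatmap
#'
#' Runs the image forward, backpropagates the target-class logit down to
#' the tapped layer (default: the stage-4 SE output, the last spatial map
#' before pooling), averages the gradient spatially into per-channel
#' weights, and forms the ReLU of the weighted channel sum. The raw map is
#' bilinearly upsampled to the input resolution and min-max normalized to
#' `[0, 1]`; an identically zero map stays zero.
#'
#' @param model A built (ideally trained) network.
#' @param image Preprocessed (H, W, 3) array in `[0, 1]` with extent
#'   matching the model's expectations.
#' @param target_class Class index, class code, or `NULL` for the
#'   predicted class.
#' @param layer Name of the tapped layer.
#' @return An object of class `gradcam_map`: list with `heatmap` (H x W in
#'   `[0, 1]`), `raw` (the un-upsampled map), `target_class`, `layer`.
#' @export
gradcam <- function(model, image, target_class = NULL, layer = "stage4_se") {
  taps <- gradcam_taps(model)
  if (!layer %in% taps)
    stop("unknown tap layer '", layer, "'; valid taps: ",
         paste(taps, collapse = ", "))
  d <- dim(image)
  x <- image
  dim(x) <- c(d[1], d[2], d[3], 1L)

  nm <- names(model$layers)
  k <- match(layer, nm)
  act <- NULL
  for (i in seq_along(nm)) {
    x <- model$layers[[i]]$forward(x, training = FALSE)
    if (i == k) act <- x
  }
  logits <- x
  classes <- if (model$config$n_classes == 7) lesion_classes()
             else as.character(seq_len(model$config$n_classes))
  if (is.null(target_class)) {
    tc <- which.max(logits[, 1])
  } else if (is.character(target_class)) {
    tc <- match(target_class, classes)
    if (is.na(tc)) stop("unknown class: ", target_class)
  } else tc <- as.integer(target_class)

  dy <- matrix(0, model$config$n_classes, 1)
  dy[tc, 1] <- 1
  for (i in rev(seq(k + 1, length(nm)))) dy <- model$layers[[i]]$backward(dy)

  A <- act[, , , 1, drop = FALSE]
  G <- dy[, , , 1, drop = FALSE]
  C <- dim(A)[3]
  alpha <- colMeans(matrix(G, ncol = C))       # spatial mean per channel
  raw <- matrix(matrix(A, ncol = C) %*% alpha, dim(A)[1], dim(A)[2])
  raw <- pmax(raw, 0)
  up <- EBImage::imageData(EBImage::resize(EBImage::Image(raw),
                                           w = d[1], h = d[2]))
  mx <- max(up)
  if (mx > 0) up <- up / mx
  r <- list(heatmap = up, raw = raw, target_class = classes[tc],
            layer = layer)
  class(r) <- "gradcam_map"
  r
}

#' Heatmap mass centroid
#'
#' @param map A [gradcam()] result or plain matrix.
#' @return Numeric `(row, col)` of the intensity-weighted centroid.
#' @export
heatmap_centroid <- function(map) {
  h <- if (inherits(map, "gradcam_map")) map$heatmap else map
  tot <- sum(h)
  if (tot == 0) return(c(nrow(h) + 1, ncol(h) + 1) / 2)
  c(sum(row(h) * h), sum(col(h) * h)) / tot
}

#' Write Grad-CAM output images
#'
#' Writes the raw heatmap as a single-band PNG and an RGB overlay
#' (fixed blue-to-red colormap, alpha-blended onto the input).
#'
#' @param map A [gradcam()] result.
#' @param image The input (H, W, 3) array the map was computed on.
#' @param heat_path,overlay_path Output PNG paths (`NULL` skips either).
#' @param alpha Overlay blend weight of the colormap.
#' @return `map`, invisibly.
#' @export
gradcam_write <- function(map, image, heat_path = NULL, overlay_path = NULL,
                          alpha = 0.4) {
  stopifnot(inherits(map, "gradcam_map"))
  h <- map$heatmap
  if (!is.null(heat_path)) png::writePNG(h, heat_path)
  if (!is.null(overlay_path)) {
    # blue (cold) -> red (hot) ramp
    col <- array(0, dim(image))
    col[, , 1] <- h
    col[, , 3] <- 1 - h
    col[, , 2] <- 0.2 * (1 - abs(2 * h - 1))
    ov <- clamp01((1 - alpha) * image + alpha * col)
    png::writePNG(ov, overlay_path)
  }
  invisible(map)
}
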