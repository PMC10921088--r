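# Preprocessing: CLAHE contrast enhancement (applied to the 8-bit image at
# native resolution, before resizing), resize + [0,1] normalization, and
# class-balanced stochastic augmentation that applies the identical
# geometric transform to image and mask (brightness to the image only).

#' CLAHE parameters
#'
#' @param clip_limit contrast clip limit (> 0); the common default for
#'   8-bit medical images is 2.
#' @param tile_grid `c(rows, cols)` of the local-histogram tiles.
#' @return a `clahe_params` list.
#' @export
clahe_params <- function(clip_limit = 2, tile_grid = c(8L, 8L)) {
  if (clip_limit <= 0) stop("clip_limit must be > 0")
  if (any(tile_grid < 1)) stop("tile_grid dims must be >= 1")
  structure(list(clip_limit = clip_limit, tile_grid = as.integer(tile_grid)),
            class = "clahe_params")
}

#' Contrast-limited adaptive histogram equalization
#'
#' Enhances a grayscale image by equalizing local (tiled) histograms with a
#' clip limit that bounds contrast amplification, the standard remedy for
#' the low, spatially varying contrast of speckle images. Deterministic for
#' fixed input.
#'
#' @param image grayscale matrix with values in `[0, 255]`.
#' @param params a [clahe_params()].
#' @return enhanced image, same shape, values in `[0, 255]`.
#' @export
clahe_enhance <- function(image, params = clahe_params()) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric grayscale matrix")
  if (min(image) < 0 || max(image) > 255)
    stop("image values must lie in [0, 255]")
  if (max(image) - min(image) < .Machine$double.eps)
    return(image)  # constant image: no contrast to redistribute
  h <- nrow(image); w <- ncol(image)
  ny <- params$tile_grid[1]; nx <- params$tile_grid[2]
  # the tiled implementation needs dims divisible by twice the tile counts;
  # pad by edge replication and crop back
  ph <- (2 * ny - h %% (2 * ny)) %% (2 * ny)
  pw <- (2 * nx - w %% (2 * nx)) %% (2 * nx)
  padded <- image[c(seq_len(h), rep(h, ph)), c(seq_len(w), rep(w, pw))]
  img <- EBImage::Image(t(padded) / 255)
  out <- EBImage::clahe(img, nx = nx, ny = ny, bins = 256,
                        limit = params$clip_limit)
  res <- .from_ebi(out)[seq_len(h), seq_len(w)] * 255
  pmin(pmax(res, 0), 255)
}

#' Resize an image/mask pair and normalize to `[0, 1]`
#'
#' The image is resampled with bilinear interpolation and scaled by 1/255;
#' the mask is resampled with nearest-neighbor so its values stay strictly
#' in `{0, 1}`.
#'
#' @param image grayscale matrix in `[0, 255]`.
#' @param mask binary matrix, same shape as `image`.
#' @param target `c(H, W)` output size (default `c(128, 128)`).
#' @return list with `image` (values in `[0, 1]`) and `mask` (values in
#'   `{0, 1}`), each `target`-sized.
#' @export
resize_normalize <- function(image, mask, target = c(128L, 128L)) {
  if (!all(dim(image) == dim(mask)))
    stop("image and mask must have the same shape")
  if (any(target < 1)) stop("target dims must be >= 1")
  img <- EBImage::resize(EBImage::Image(t(image)), w = target[2],
                         h = target[1], filter = "bilinear")
  msk <- EBImage::resize(EBImage::Image(t(mask)), w = target[2],
                         h = target[1], filter = "none")
  list(image = pmin(pmax(.from_ebi(img) / 255, 0), 1),
       mask = (.from_ebi(msk) > 0.5) + 0L)
}

#' Augmentation parameters
#'
#' Ranges of the stochastic augmentation draws. The magnitudes default to
#' conservative values (aggressive brightness or zoom changes destroy
#' diagnostic detail in ultrasound); every range is configurable.
#'
#' @param rotation_range max absolute rotation, degrees.
#' @param zoom_range multiplicative scale interval.
#' @param horizontal_flip allow a random horizontal flip.
#' @param width_shift,height_shift max absolute shift as a fraction of
#'   width/height.
#' @param shear max absolute shear, radians.
#' @param brightness_range multiplicative intensity interval (image only,
#'   never applied to the mask).
#' @return an `augment_params` list.
#' @export
augment_params <- function(rotation_range = 15, zoom_range = c(0.9, 1.1),
                           horizontal_flip = TRUE,
                           width_shift = 0.1, height_shift = 0.1,
                           shear = 0.1, brightness_range = c(0.8, 1.2)) {
  if (zoom_range[1] > zoom_range[2] ||
      brightness_range[1] > brightness_range[2])
    stop("intervals must be non-empty")
  structure(list(rotation_range = rotation_range, zoom_range = zoom_range,
                 horizontal_flip = horizontal_flip,
                 width_shift = width_shift, height_shift = height_shift,
                 shear = shear, brightness_range = brightness_range),
            class = "augment_params")
}

# 3x3 affine (homogeneous, EBImage (x, y) = (col, row) convention) composed
# about the image center
.make_affine <- function(h, w, angle = 0, zoom = 1, flip = FALSE,
                         shift_x = 0, shift_y = 0, shear = 0) {
  # pixel centers sit at (i - 0.5), so the geometric image center is
  # (w/2, h/2) in the warp's coordinate frame
  cx <- w / 2; cy <- h / 2
  tc <- rbind(c(1, 0, cx), c(0, 1, cy), c(0, 0, 1))
  tci <- rbind(c(1, 0, -cx), c(0, 1, -cy), c(0, 0, 1))
  rot <- rbind(c(cos(angle), -sin(angle), 0),
               c(sin(angle), cos(angle), 0), c(0, 0, 1))
  shr <- rbind(c(1, shear, 0), c(0, 1, 0), c(0, 0, 1))
  scl <- rbind(c(zoom, 0, 0), c(0, zoom, 0), c(0, 0, 1))
  flp <- if (flip) rbind(c(-1, 0, 0), c(0, 1, 0), c(0, 0, 1)) else diag(3)
  tsh <- rbind(c(1, 0, shift_x), c(0, 1, shift_y), c(0, 0, 1))
  tsh %*% tc %*% flp %*% rot %*% shr %*% scl %*% tci
}

# warp a matrix with a 3x3 forward transform (input -> output coords),
# bilinear or nearest, zero fill outside the frame
.warp <- function(m, trans, interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  filt <- if (interpolation == "bilinear") "bilinear" else "none"
  img <- EBImage::Image(t(m))
  out <- EBImage::affine(img, m = t(trans[1:2, ]), filter = filt,
                         bg.col = 0, antialias = FALSE)
  .from_ebi(out)
}

# EBImage Image (x = columns) back to a plain (rows x cols) matrix
.from_ebi <- function(img) {
  m <- t(EBImage::imageData(img))
  dim(m) <- dim(m)[1:2]
  unclass(as.matrix(m))
}

#' Replay a recorded augmentation transform
#'
#' @param image matrix to transform.
#' @param transform the `transform` element returned by [augment_pair()]
#'   (a 3x3 forward affine matrix).
#' @param interpolation `"bilinear"` for images, `"nearest"` for masks.
#' @return the warped matrix.
#' @export
apply_transform <- function(image, transform,
                            interpolation = c("bilinear", "nearest")) {
  .warp(image, transform, match.arg(interpolation))
}

#' Augment an image/mask pair
#'
#' Draws one random geometric transform (rotation, zoom, optional
#' horizontal flip, shifts, shear) and applies it identically to image and
#' mask; the mask is warped with nearest-neighbor and re-binarized at 0.5.
#' A brightness factor is applied to the image only. Out-of-frame pixels
#' are filled with 0, matching the black sector background of ultrasound
#' frames. Draws come from the current RNG state, so a seed set by the
#' caller makes the augmentation reproducible.
#'
#' @param image grayscale matrix (any intensity scale).
#' @param mask binary matrix, same shape.
#' @param params an [augment_params()].
#' @return list with `image`, `mask`, `transform` (the 3x3 forward affine
#'   matrix, replayable with [apply_transform()]) and `brightness`.
#' @export
augment_pair <- function(image, mask, params = augment_params()) {
  if (!all(dim(image) == dim(mask)))
    stop("image and mask must have the same shape")
  h <- nrow(image); w <- ncol(image)
  ang <- runif(1, -params$rotation_range, params$rotation_range) * pi / 180
  zm <- runif(1, params$zoom_range[1], params$zoom_range[2])
  flip <- params$horizontal_flip && runif(1) < 0.5
  sx <- runif(1, -params$width_shift, params$width_shift) * w
  sy <- runif(1, -params$height_shift, params$height_shift) * h
  sh <- runif(1, -params$shear, params$shear)
  br <- runif(1, params$brightness_range[1], params$brightness_range[2])
  trans <- .make_affine(h, w, ang, zm, flip, sx, sy, sh)
  img <- .warp(image, trans, "bilinear") * br
  top <- max(image)
  if (top <= 1) img <- pmin(pmax(img, 0), 1) else img <- pmin(pmax(img, 0), 255)
  msk <- (.warp(mask, trans, "nearest") > 0.5) + 0L
  list(image = img, mask = msk, transform = trans, brightness = br)
}

#' Balance classes by per-class augmentation
#'
#' Brings every class of a sample list to exactly `target_count` members:
#' classes above the target are subsampled (without replacement), classes
#' below it are topped up with augmented copies of randomly chosen members.
#'
#' @param samples list of `phantom_sample` objects (fields `image`, `mask`,
#'   `label`).
#' @param target_count desired per-class count.
#' @param params an [augment_params()].
#' @return list of samples with exactly `target_count` per class present in
#'   the input.
#' @export
balance_classes <- function(samples, target_count,
                            params = augment_params()) {
  labels <- vapply(samples, function(s) s$label, character(1))
  out <- list()
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) >= target_count) {
      keep <- idx[sample.int(length(idx), target_count)]
      out <- c(out, samples[keep])
    } else {
      out <- c(out, samples[idx])
      extra <- sample(idx, target_count - length(idx), replace = TRUE)
      for (i in extra) {
        s <- samples[[i]]
        a <- augment_pair(s$image, s$mask, params)
        out <- c(out, list(structure(
          list(image = a$image, mask = a$mask, label = s$label),
          class = "phantom_sample")))
      }
    }
  }
  out
}
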