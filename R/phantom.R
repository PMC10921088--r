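# Synthetic B-mode-style ultrasound phantoms: speckle-textured grayscale
# frames with hypoechoic lesions and paired binary masks, in three classes
# (no_mass / benign / malignant) so that every downstream stage is testable
# without clinical data.
#
# Speckle model: two independent smoothed Gaussian fields combined as a
# Rayleigh-like envelope sqrt(u^2 + v^2), normalized to unit mean and used
# as multiplicative noise on a slowly shaded tissue background. Benign
# lesions are smooth ellipses; malignant lesions are ellipses perturbed by
# random angular harmonics of orders 3-8 plus a few narrow spicules, giving
# the two classes distinguishable boundary statistics. Lesions are
# hypoechoic: intensity inside is multiplied by `lesion_contrast` < 1.

.phantom_classes <- c("no_mass", "benign", "malignant")

#' Configuration of the phantom generator
#'
#' @param n_samples number of frames to generate.
#' @param class_proportions non-negative fractions for (no_mass, benign,
#'   malignant), summing to 1. The default mirrors a 2048/820/950 frame mix.
#' @param image_size `c(H, W)` in pixels.
#' @param lesion_area_range interval of lesion area as a fraction of the
#'   image area; must lie inside (0, 0.5).
#' @param speckle_smoothing Gaussian blur radius (pixels) of the latent
#'   speckle fields; larger values give coarser speckle grain.
#' @param lesion_contrast multiplicative hypoechoic factor in (0, 1);
#'   intensity inside the lesion is scaled by this value.
#' @param seed integer seed; the full dataset is a deterministic function of
#'   the configuration.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(n_samples = 100L,
                           class_proportions = c(no_mass = 2048, benign = 820,
                                                 malignant = 950) / 3818,
                           image_size = c(128L, 128L),
                           lesion_area_range = c(0.05, 0.20),
                           speckle_smoothing = 1.5,
                           lesion_contrast = 0.45,
                           seed = 1L) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (length(class_proportions) != 3 || any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must be 3 non-negative fractions summing to 1")
  if (length(lesion_area_range) != 2 || lesion_area_range[1] <= 0 ||
      lesion_area_range[2] >= 0.5 ||
      lesion_area_range[1] >= lesion_area_range[2])
    stop("lesion_area_range must be an increasing interval inside (0, 0.5)")
  if (lesion_contrast <= 0 || lesion_contrast >= 1)
    stop("lesion_contrast must lie in (0, 1)")
  names(class_proportions) <- .phantom_classes
  structure(list(
    n_samples = as.integer(n_samples),
    class_proportions = class_proportions,
    image_size = as.integer(image_size),
    lesion_area_range = lesion_area_range,
    speckle_smoothing = speckle_smoothing,
    lesion_contrast = lesion_contrast,
    seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Apportion counts by the largest-remainder method
#'
#' Splits `n` into integer counts proportional to `proportions`, preserving
#' the exact total: each class gets the floor of its share, and the
#' remaining units go to the classes with the largest fractional remainders.
#'
#' @param n total count.
#' @param proportions non-negative weights (normalized internally).
#' @return integer vector of counts summing to `n`.
#' @export
largest_remainder <- function(n, proportions) {
  p <- proportions / sum(proportions)
  shares <- n * p
  counts <- floor(shares)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(shares - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

# unit-mean Rayleigh-like speckle field
.speckle_field <- function(h, w, sigma) {
  u <- matrix(rnorm(h * w), h, w)
  v <- matrix(rnorm(h * w), h, w)
  if (sigma > 0) {
    u <- EBImage::gblur(u, sigma)
    v <- EBImage::gblur(v, sigma)
  }
  env <- sqrt(u^2 + v^2)
  env / mean(env)
}

# radial boundary perturbation for a malignant lesion: low-order angular
# harmonics plus narrow spicules; returns a vectorized function of angle
.malignant_perturbation <- function() {
  ks <- 3:8
  wk <- runif(length(ks)); wk <- wk / sum(wk)
  amp <- runif(1, 0.15, 0.30) * wk
  phase <- runif(length(ks), 0, 2 * pi)
  ns <- sample(2:4, 1)
  s_ang <- runif(ns, 0, 2 * pi)
  s_amp <- runif(ns, 0.15, 0.35)
  s_wid <- runif(ns, 0.08, 0.15)
  function(theta) {
    p <- 0
    for (i in seq_along(ks)) p <- p + amp[i] * cos(ks[i] * theta + phase[i])
    for (i in seq_len(ns)) {
      d <- abs((theta - s_ang[i] + pi) %% (2 * pi) - pi)
      p <- p + s_amp[i] * exp(-0.5 * (d / s_wid[i])^2)
    }
    p
  }
}

# 4-connected component of `mask` containing (ci, cj), by repeated
# dilation-and-mask from the seed pixel
.component4 <- function(mask, ci, cj) {
  h <- nrow(mask); w <- ncol(mask)
  reach <- matrix(FALSE, h, w)
  reach[ci, cj] <- mask[ci, cj] > 0
  m <- mask > 0
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-h, ]
    grown[-h, ] <- grown[-h, ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -w]
    grown[, -w] <- grown[, -w] | reach[, -1]
    grown <- grown & m
    if (identical(grown, reach)) break
    reach <- grown
  }
  reach
}

#' Generate one phantom sample
#'
#' Draws a speckle-textured frame and its ground-truth mask for the given
#' class. `no_mass` frames have an all-zero mask; `benign` frames carry one
#' smooth hypoechoic ellipse; `malignant` frames carry one irregular,
#' spiculated hypoechoic region. The rasterized lesion is rescaled until its
#' pixel-count area fraction lies inside `lesion_area_range`, and the mask
#' is reduced to the single 4-connected component containing the lesion
#' center.
#'
#' @param config a [phantom_config()].
#' @param label one of `"no_mass"`, `"benign"`, `"malignant"`.
#' @param seed optional integer; if given, the sample is a deterministic
#'   function of `(config, label, seed)`.
#' @return a `phantom_sample`: list with `image` (H x W matrix, integer
#'   values in 0..255), `mask` (H x W matrix in {0, 1}) and `label`.
#' @export
generate_sample <- function(config, label, seed = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  label <- match.arg(label, .phantom_classes)
  if (!is.null(seed)) set.seed(seed)
  h <- config$image_size[1]; w <- config$image_size[2]

  rowfrac <- matrix((seq_len(h) - 0.5) / h, h, w)
  base <- 115 * (1 - 0.15 * rowfrac)          # mild depth attenuation
  env <- .speckle_field(h, w, config$speckle_smoothing)

  mask <- matrix(0L, h, w)
  if (label != "no_mass") {
    rng <- config$lesion_area_range
    pad <- 0.05 * diff(rng)
    f_target <- runif(1, rng[1] + pad, rng[2] - pad)
    q <- runif(1, 0.55, 0.95)                 # ellipse aspect ratio
    phi <- runif(1, 0, pi)
    pert <- if (label == "malignant") .malignant_perturbation() else
      function(theta) rep(0, length(theta))
    th <- seq(0, 2 * pi, length.out = 721)[-721]
    rho <- 1 + pmax(pert(th), -0.6)
    area_coef <- q * 0.5 * sum(rho^2) * (2 * pi / 720)  # area = coef * a^2
    # largest scale whose perturbed outline (plus a 2 px safety margin)
    # still fits; the target fraction is clamped to what fits
    a_cap <- (min(h, w) / 2 - 3) / max(rho)
    f_cap <- area_coef * a_cap^2 / (h * w)
    if (f_cap < rng[1])
      stop(sprintf(paste0("degenerate config: a lesion of minimum area ",
                          "fraction %.3f does not fit in a %d x %d image"),
                   rng[1], h, w))
    f_target <- min(f_target, f_cap)
    a0 <- sqrt(f_target * h * w / area_coef)
    rmax <- a0 * max(rho) + 2
    ci <- runif(1, rmax + 0.5, h - rmax - 0.5)
    cj <- runif(1, rmax + 0.5, w - rmax - 0.5)
    jj <- matrix(seq_len(w), h, w, byrow = TRUE) - cj
    ii <- matrix(seq_len(h), h, w) - ci
    xr <- cos(phi) * jj + sin(phi) * ii
    yr <- -sin(phi) * jj + cos(phi) * ii
    theta <- atan2(yr, xr)
    bound <- 1 + pmax(pert(theta), -0.6)
    a <- a0
    for (iter in 1:8) {
      rell <- sqrt((xr / a)^2 + (yr / (q * a))^2)
      mask <- (rell <= bound) + 0L
      dim(mask) <- c(h, w)
      mask <- .component4(mask, round(ci), round(cj)) + 0L
      f <- sum(mask) / (h * w)
      if (f >= rng[1] && f <= rng[2]) break
      a <- a * sqrt(f_target / max(f, 1e-9))
    }
    msoft <- EBImage::gblur(mask + 0, 0.7)
    msoft <- pmin(pmax(msoft, 0), 1)
    base <- base * (1 - (1 - config$lesion_contrast) * msoft)
  }
  img <- round(pmin(pmax(base * env, 0), 255))
  structure(list(image = img, mask = mask, label = label),
            class = "phantom_sample")
}

#' Generate a phantom dataset
#'
#' Class counts follow the largest-remainder apportionment of `n_samples`
#' by `class_proportions`; sample order is shuffled (seeded). With `dir`
#' given, 8-bit grayscale PNG pairs (`sample_0001.png`,
#' `sample_0001_mask.png`) and a `manifest.csv` are written; otherwise the
#' samples are returned in memory.
#'
#' @param config a [phantom_config()].
#' @param dir optional output directory.
#' @return a `phantom_dataset`: list with `samples` (list of
#'   `phantom_sample`, `NULL` when written to disk), `manifest` (data.frame
#'   with `image_path`, `mask_path`, `label`) and `config`.
#' @export
generate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  counts <- largest_remainder(config$n_samples, config$class_proportions)
  labels <- rep(.phantom_classes, counts)
  set.seed(config$seed)
  labels <- labels[sample.int(length(labels))]
  seeds <- sample.int(.Machine$integer.max - 1, config$n_samples)
  samples <- vector("list", config$n_samples)
  for (i in seq_len(config$n_samples))
    samples[[i]] <- generate_sample(config, labels[i], seed = seeds[i])
  manifest <- data.frame(
    image_path = NA_character_, mask_path = NA_character_,
    label = labels, stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
      stop("cannot create output directory: ", dir)
    for (i in seq_along(samples)) {
      stem <- sprintf("sample_%04d", i)
      ip <- file.path(dir, paste0(stem, ".png"))
      mp <- file.path(dir, paste0(stem, "_mask.png"))
      png::writePNG(samples[[i]]$image / 255, ip)
      png::writePNG(samples[[i]]$mask + 0, mp)
      manifest$image_path[i] <- ip
      manifest$mask_path[i] <- mp
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    samples <- NULL
  }
  structure(list(samples = samples, manifest = manifest, config = config),
            class = "phantom_dataset")
}

#' Read a phantom dataset back from a manifest
#'
#' @param manifest a data.frame with `image_path`, `mask_path`, `label`
#'   columns, or the path of a `manifest.csv`.
#' @return a `phantom_dataset` with samples in memory.
#' @export
read_dataset <- function(manifest) {
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- round(png::readPNG(manifest$image_path[i]) * 255)
    msk <- (png::readPNG(manifest$mask_path[i]) > 0.5) + 0L
    structure(list(image = img, mask = msk, label = manifest$label[i]),
              class = "phantom_sample")
  })
  structure(list(samples = samples, manifest = manifest, config = NULL),
            class = "phantom_dataset")
}
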