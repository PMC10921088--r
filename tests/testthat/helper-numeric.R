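# central-difference gradient and relative-error helpers for the layer checks

num_grad <- function(f, x, eps = 1e-5) {
  g <- if (is.null(dim(x))) numeric(length(x)) else array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}

# tiny in-memory phantom batch for training-path tests
tiny_batch <- function(n = 8, size = 16, seed = 1) {
  cfg <- phantom_config(n_samples = n, image_size = c(size, size),
                        lesion_area_range = c(0.05, 0.2),
                        class_proportions = c(0.25, 0.375, 0.375),
                        seed = seed)
  ds <- generate_dataset(cfg)
  samples_to_batch(ds$samples)
}
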