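# Phantom generator: class semantics, determinism, area control, lesion
# topology/contrast, apportionment, and PNG round-tripping.

test_that("no_mass samples have empty masks; lesions are nonempty", {
  cfg <- phantom_config(n_samples = 4, image_size = c(32, 32),
                        lesion_area_range = c(0.05, 0.2), seed = 1)
  s <- generate_sample(cfg, "no_mass", seed = 5)
  expect_identical(sum(s$mask), 0L)
  expect_gt(sum(generate_sample(cfg, "benign", seed = 6)$mask), 0)
})

test_that("same config and seed reproduce samples bitwise", {
  cfg <- phantom_config(n_samples = 4, image_size = c(32, 32), seed = 2)
  for (lab in c("no_mass", "benign", "malignant")) {
    s1 <- generate_sample(cfg, lab, seed = 9)
    s2 <- generate_sample(cfg, lab, seed = 9)
    expect_identical(s1, s2)
  }
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  cfg2 <- phantom_config(n_samples = 4, image_size = c(32, 32), seed = 3)
  expect_false(identical(generate_dataset(cfg2)$samples, d1$samples))
})

test_that("lesion area fraction lands inside the configured range", {
  cfg <- phantom_config(n_samples = 4, image_size = c(64, 64),
                        lesion_area_range = c(0.05, 0.15), seed = 4)
  for (i in 1:6) {
    for (lab in c("benign", "malignant")) {
      s <- generate_sample(cfg, lab, seed = 100 + i)
      f <- sum(s$mask) / (64 * 64)
      expect_gte(f, 0.05)
      expect_lte(f, 0.15)
    }
  }
})

test_that("lesion masks are a single 4-connected component", {
  ns <- asNamespace("watunet")
  cfg <- phantom_config(n_samples = 4, image_size = c(48, 48),
                        lesion_area_range = c(0.05, 0.2), seed = 5)
  for (i in 1:5) for (lab in c("benign", "malignant")) {
    s <- generate_sample(cfg, lab, seed = 200 + i)
    seedpx <- which(s$mask == 1, arr.ind = TRUE)[1, ]
    comp <- ns$.component4(s$mask, seedpx[1], seedpx[2])
    expect_identical(sum(comp), sum(s$mask))
  }
})

test_that("lesions are hypoechoic (darker inside than outside)", {
  cfg <- phantom_config(n_samples = 4, image_size = c(48, 48), seed = 6)
  for (i in 1:5) for (lab in c("benign", "malignant")) {
    s <- generate_sample(cfg, lab, seed = 300 + i)
    expect_lt(mean(s$image[s$mask == 1]), mean(s$image[s$mask == 0]))
  }
})

test_that("degenerate configs (lesion larger than image) are rejected", {
  cfg <- phantom_config(n_samples = 1, image_size = c(16, 16),
                        lesion_area_range = c(0.4, 0.49), seed = 7)
  expect_error(generate_sample(cfg, "malignant", seed = 1), "degenerate")
})

test_that("largest-remainder apportionment reproduces stated counts", {
  expect_identical(largest_remainder(3818, c(2048, 820, 950) / 3818),
                   c(2048L, 820L, 950L))
  expect_identical(largest_remainder(3, rep(1 / 3, 3)), c(1L, 1L, 1L))
  expect_identical(largest_remainder(10, c(0.5, 0.3, 0.2)), c(5L, 3L, 2L))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(3); p <- p / sum(p)
    n <- sample(1:500, 1)
    cnt <- largest_remainder(n, p)
    expect_identical(sum(cnt), as.integer(n))
    expect_true(all(abs(cnt - n * p) < 1))
  }
})

test_that("dataset respects class proportions and writes valid PNG pairs", {
  cfg <- phantom_config(n_samples = 10,
                        class_proportions = c(0.5, 0.3, 0.2),
                        image_size = c(32, 32), seed = 9)
  dir <- withr::local_tempdir()
  ds <- generate_dataset(cfg, dir = dir)
  counts <- table(factor(ds$manifest$label,
                         levels = c("no_mass", "benign", "malignant")))
  expect_identical(as.integer(counts), c(5L, 3L, 2L))
  expect_true(all(file.exists(ds$manifest$image_path)))
  expect_true(all(grepl("_mask\\.png$", ds$manifest$mask_path)))
  back <- read_dataset(file.path(dir, "manifest.csv"))
  mem <- generate_dataset(cfg)
  for (i in seq_len(10)) {
    expect_identical(back$samples[[i]]$image, mem$samples[[i]]$image)
    expect_identical(back$samples[[i]]$mask + 0L, mem$samples[[i]]$mask)
  }
})

test_that("invalid configurations are rejected with diagnostics", {
  expect_error(phantom_config(n_samples = 0), "n_samples")
  expect_error(phantom_config(class_proportions = c(0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(phantom_config(lesion_area_range = c(0.2, 0.6)),
               "lesion_area_range")
  expect_error(phantom_config(lesion_contrast = 1.5), "lesion_contrast")
})
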