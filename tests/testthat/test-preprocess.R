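# Preprocessing: CLAHE contracts, resize/normalize contracts, and the
# paired-augmentation guarantees (identical geometry on image and mask,
# brightness on the image only, reproducibility, replayability).

test_that("CLAHE is deterministic, range-preserving, and boosts contrast", {
  set.seed(1)
  img <- matrix(runif(64 * 64, 80, 120), 64, 64)
  e1 <- clahe_enhance(img)
  e2 <- clahe_enhance(img)
  expect_identical(e1, e2)
  expect_true(all(e1 >= 0 & e1 <= 255))
  expect_identical(dim(e1), dim(img))
  # constant image: nothing to redistribute
  expect_equal(clahe_enhance(matrix(100, 40, 40)), matrix(100, 40, 40),
               tolerance = 1)
  # low-contrast ramp: output standard deviation >= input's
  ramp <- matrix(rep(seq(100, 140, length.out = 64), each = 64), 64, 64)
  expect_gte(sd(clahe_enhance(ramp)), sd(ramp))
})

test_that("CLAHE rejects invalid input and parameters", {
  expect_error(clahe_enhance(matrix(-5, 8, 8)), "\\[0, 255\\]")
  expect_error(clahe_enhance(array(0, c(4, 4, 2))), "matrix")
  expect_error(clahe_params(clip_limit = 0), "clip_limit")
  expect_error(clahe_params(tile_grid = c(0, 8)), "tile_grid")
})

test_that("resize_normalize keeps masks binary and scales images to [0,1]", {
  set.seed(2)
  img <- matrix(runif(40 * 50) * 255, 40, 50)
  msk <- matrix(0L, 40, 50); msk[10:25, 15:35] <- 1L
  out <- resize_normalize(img, msk, target = c(32, 32))
  expect_identical(dim(out$image), c(32L, 32L))
  expect_true(all(out$mask %in% c(0L, 1L)))
  expect_true(all(out$image >= 0 & out$image <= 1))
  # identity resize: image unchanged up to the 1/255 scaling
  same <- resize_normalize(img[1:32, 1:32], msk[1:32, 1:32],
                           target = c(32, 32))
  expect_equal(same$image, img[1:32, 1:32] / 255, tolerance = 1e-9)
  expect_identical(same$mask, msk[1:32, 1:32])
  # all-255 image maps to all-1
  ones <- resize_normalize(matrix(255, 20, 20), matrix(0L, 20, 20),
                           target = c(10, 10))
  expect_true(all(ones$image == 1))
  expect_error(resize_normalize(img, msk, target = c(0, 10)), "target")
  expect_error(resize_normalize(img, msk[1:20, ]), "same shape")
})

test_that("identity augmentation parameters leave the pair unchanged", {
  set.seed(3)
  img <- matrix(runif(32 * 32) * 255, 32, 32)
  msk <- matrix(0L, 32, 32); msk[8:20, 10:22] <- 1L
  idp <- augment_params(rotation_range = 0, zoom_range = c(1, 1),
                        horizontal_flip = FALSE, width_shift = 0,
                        height_shift = 0, shear = 0,
                        brightness_range = c(1, 1))
  a <- augment_pair(img, msk, idp)
  expect_equal(a$image, img, tolerance = 1e-9)
  expect_identical(a$mask, msk)
})

test_that("a horizontal flip applied twice restores the original pair", {
  set.seed(4)
  img <- matrix(runif(32 * 32) * 255, 32, 32)
  msk <- matrix(0L, 32, 32); msk[5:12, 20:30] <- 1L
  flip_only <- augment_params(rotation_range = 0, zoom_range = c(1, 1),
                              horizontal_flip = TRUE, width_shift = 0,
                              height_shift = 0, shear = 0,
                              brightness_range = c(1, 1))
  # draw until the flip triggers, then replay it twice
  repeat {
    a <- augment_pair(img, msk, flip_only)
    if (!isTRUE(all.equal(a$image, img))) break
  }
  twice <- apply_transform(a$image, a$transform, "bilinear")
  expect_equal(twice, img, tolerance = 1e-9)
  expect_equal(a$image, img[, ncol(img):1], tolerance = 1e-9)
})

test_that("augmentation applies identical geometry to image and mask", {
  set.seed(5)
  img <- matrix(runif(32 * 32) * 255, 32, 32)
  msk <- matrix(0L, 32, 32); msk[8:20, 10:22] <- 1L
  for (i in 1:5) {
    a <- augment_pair(img, msk, augment_params())
    expect_true(all(a$mask %in% c(0L, 1L)))
    replay <- (apply_transform(msk, a$transform, "nearest") > 0.5) + 0L
    expect_identical(replay, a$mask)
  }
})

test_that("brightness affects the image only and draws are seeded", {
  img <- matrix(100, 16, 16)
  msk <- matrix(1L, 16, 16)
  bright <- augment_params(rotation_range = 0, zoom_range = c(1, 1),
                           horizontal_flip = FALSE, width_shift = 0,
                           height_shift = 0, shear = 0,
                           brightness_range = c(1.2, 1.2))
  a <- augment_pair(img, msk, bright)
  expect_equal(a$image, img * 1.2, tolerance = 1e-9)
  expect_identical(a$mask, msk)
  set.seed(6); a1 <- augment_pair(img, msk, augment_params())
  set.seed(6); a2 <- augment_pair(img, msk, augment_params())
  expect_identical(a1, a2)
})

test_that("balance_classes yields exactly the target count per class", {
  cfg <- phantom_config(n_samples = 9, image_size = c(32, 32),
                        class_proportions = c(1, 1, 1) / 3, seed = 7)
  ds <- generate_dataset(cfg)
  set.seed(8)
  bal <- balance_classes(ds$samples, target_count = 5)
  labs <- vapply(bal, function(s) s$label, character(1))
  expect_true(all(table(labs) == 5))
  set.seed(9)
  down <- balance_classes(ds$samples, target_count = 2)
  expect_true(all(table(vapply(down, function(s) s$label,
                               character(1))) == 2))
})
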