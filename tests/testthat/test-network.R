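# Network assembly: gradient correctness of the composed model, parameter
# accounting, shape/sigmoid contracts, build determinism, and gradient flow
# to the first encoder block for every skip mode.

test_that("layer primitives pass central-difference gradient checks", {
  ns <- asNamespace("watunet")
  set.seed(1)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  l <- ns$new_conv(2, 3)
  y <- l$fwd(x)
  dx <- l$bwd(cos(y))
  expect_lt(rel_err(dx, num_grad(function(z) sum(sin(l$fwd(z))), x)), 1e-6)
  expect_lt(rel_err(l$dW, num_grad(function(w) {
    l2 <- ns$new_conv(2, 3); l2$W <- w; l2$b <- l$b
    sum(sin(l2$fwd(x)))
  }, l$W)), 1e-6)

  lt <- ns$new_convt(2, 3)
  xt <- array(rnorm(4 * 5 * 2 * 2), c(4, 5, 2, 2))
  yt <- lt$fwd(xt)
  expect_identical(dim(yt), c(8L, 10L, 3L, 2L))
  expect_lt(rel_err(lt$bwd(cos(yt)),
                    num_grad(function(z) sum(sin(lt$fwd(z))), xt)), 1e-6)

  lb <- ns$new_bn(2)
  lb$gamma <- runif(2, 0.5, 1.5); lb$beta <- rnorm(2)
  xb <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  yb <- lb$fwd(xb, training = TRUE)
  expect_lt(rel_err(lb$bwd(cos(yb)), num_grad(function(z) {
    l2 <- ns$new_bn(2); l2$gamma <- lb$gamma; l2$beta <- lb$beta
    sum(sin(l2$fwd(z, training = TRUE)))
  }, xb)), 1e-5)
})

test_that("full watunet model gradients match finite differences", {
  ns <- asNamespace("watunet")
  cfg <- network_config(depth = 1, base_channels = 2, skip_mode = "watunet",
                        input_size = c(8, 8),
                        encoder_dropout = 0, decoder_dropout = 0)
  m <- build_model(cfg, seed = 11)
  set.seed(12)
  x <- array(runif(8 * 8 * 2), c(8, 8, 1, 2))
  y <- (array(runif(8 * 8 * 2), c(8, 8, 1, 2)) > 0.5) + 0
  p <- ns$model_forward(m, x, training = TRUE)
  ns$model_backward(m, ns$.combined_loss_grad(p, y))
  check <- function(layer, pname, k = 3) {
    ana <- layer[[paste0("d", pname)]]
    idx <- sample(length(layer[[pname]]), min(k, length(layer[[pname]])))
    for (i in idx) {
      eps <- 1e-5
      orig <- layer[[pname]][i]
      layer[[pname]][i] <- orig + eps
      lp <- combined_loss(ns$model_forward(m, x, training = TRUE), y)
      layer[[pname]][i] <- orig - eps
      lm <- combined_loss(ns$model_forward(m, x, training = TRUE), y)
      layer[[pname]][i] <- orig
      expect_lt(abs((lp - lm) / (2 * eps) - ana[i]) /
                  max(1e-8, abs(ana[i])), 1e-4)
    }
  }
  set.seed(13)
  check(m$layers[[1]], "W")                     # first encoder conv
  ag <- Filter(function(l) l$type == "attention_gate", m$layers)[[1]]
  check(ag, "Wx"); check(ag, "Ws")
  cvt <- Filter(function(l) l$type == "convt", m$layers)[[1]]
  check(cvt, "W")
  bn <- Filter(function(l) l$type == "bn", m$layers)[[1]]
  check(bn, "gamma", k = 2)
})

test_that("forward pass has the output shape and sigmoid range", {
  for (mode in c("plain", "attention", "sharpen", "watunet")) {
    cfg <- network_config(depth = 2, base_channels = 4, skip_mode = mode,
                          input_size = c(16, 16))
    m <- build_model(cfg, seed = 5)
    p <- model_predict(m, array(runif(16 * 16 * 2), c(16, 16, 1, 2)))
    expect_identical(dim(p), c(16L, 16L, 1L, 2L))
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("identical seeds give identical builds and outputs", {
  cfg <- network_config(depth = 2, base_channels = 4, skip_mode = "plain",
                        input_size = c(16, 16))
  m1 <- build_model(cfg, seed = 21)
  m2 <- build_model(cfg, seed = 21)
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  expect_identical(model_predict(m1, x), model_predict(m2, x))
  m3 <- build_model(cfg, seed = 22)
  expect_false(identical(model_predict(m1, x), model_predict(m3, x)))
})

test_that("per-sample predictions are invariant to batch composition", {
  cfg <- network_config(depth = 2, base_channels = 4, skip_mode = "watunet",
                        input_size = c(16, 16))
  m <- build_model(cfg, seed = 31)
  set.seed(32)
  x <- array(runif(16 * 16 * 3), c(16, 16, 1, 3))
  p_all <- model_predict(m, x)
  p_one <- model_predict(m, x[, , 1, 2, drop = FALSE])
  expect_equal(p_all[, , 1, 2], p_one[, , 1, 1], tolerance = 1e-12)
})

test_that("trainable parameter count matches hand-computed layer arithmetic", {
  cfg <- network_config(depth = 2, base_channels = 4, skip_mode = "plain",
                        input_size = c(16, 16), convs_per_block = 2)
  m <- build_model(cfg, seed = 1)
  conv_p <- function(cin, cout, k = 3) k * k * cin * cout + cout
  bn_p <- function(c) 2 * c
  block_p <- function(cin, cout) conv_p(cin, cout) + bn_p(cout) +
    conv_p(cout, cout) + bn_p(cout)
  expected <- block_p(1, 4) + block_p(4, 8) +      # encoder
    block_p(8, 16) +                               # bottleneck
    conv_p(16, 8) + block_p(16, 8) +               # decoder level 2
    conv_p(8, 4) + block_p(8, 4) +                 # decoder level 1
    conv_p(4, 1, k = 1)                            # head
  expect_identical(n_parameters(m), expected)
})

test_that("watunet skip tensor has 4x channels and the model runs at depth 4", {
  cfg <- network_config(depth = 4, base_channels = 2, skip_mode = "watunet",
                        input_size = c(64, 64))
  m <- build_model(cfg, seed = 2)
  expect_identical(m$dec[[1]]$skip_channels, 4L * 2L)
  p <- model_predict(m, array(runif(64 * 64), c(64, 64, 1, 1)))
  expect_identical(dim(p), c(64L, 64L, 1L, 1L))
})

test_that("indivisible input sizes are rejected at config time", {
  expect_error(network_config(depth = 4, input_size = c(100, 100),
                              skip_mode = "watunet"), "divisible")
  expect_error(network_config(depth = 3, input_size = c(20, 20),
                              skip_mode = "plain"), "divisible")
})

test_that("one optimization step changes the first encoder block (all modes)", {
  ns <- asNamespace("watunet")
  b <- tiny_batch(n = 4, size = 16, seed = 3)
  for (mode in c("plain", "attention", "sharpen", "watunet")) {
    cfg <- network_config(depth = 2, base_channels = 4, skip_mode = mode,
                          input_size = c(16, 16))
    m <- build_model(cfg, seed = 4)
    w_before <- m$layers[[1]]$W
    fit <- train_model(m, b, b, train_config(epochs = 1, batch_size = 4,
                                             seed = 5))
    expect_gt(max(abs(m$layers[[1]]$W - w_before)), 0)
  }
})
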