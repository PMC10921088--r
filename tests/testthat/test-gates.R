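# Attention gate and wavelet gate: closed-form scalar cases, saturation
# limits, coefficient range, shape bookkeeping, and determinism.

test_that("swish matches its closed form", {
  expect_identical(swish(0), 0)
  expect_equal(swish(-1), -1 / (1 + exp(1)), tolerance = 1e-12)
  expect_equal(swish(-1), -0.26894, tolerance = 1e-4)
  v <- 50
  expect_equal(swish(v), v, tolerance = 1e-12)  # asymptote
  x <- matrix(rnorm(20), 4, 5)
  expect_equal(swish(x), x * (1 / (1 + exp(-x))), tolerance = 1e-12)
})

test_that("zero projection weights give a = 0.5 everywhere", {
  p <- attention_gate_params(2, 2, Wx = matrix(0, 2, 2),
                             Wg = matrix(0, 2, 2), Ws = matrix(0, 2, 1))
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  g <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  out <- attention_gate(x, g, p)
  expect_equal(unclass(out), 0.5 * x, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(attr(out, "coefficients") == 0.5))
})

test_that("saturating weights drive x_out toward x", {
  big <- 50
  p <- attention_gate_params(1, 1, Wx = matrix(big, 1, 1),
                             Wg = matrix(big, 1, 1), Ws = matrix(big, 1, 1))
  x <- array(abs(rnorm(16)) + 0.5, c(4, 4, 1))
  g <- array(abs(rnorm(16)) + 0.5, c(4, 4, 1))
  out <- attention_gate(x, g, p)
  expect_lt(max(abs(out - x)), 1e-8)
})

test_that("single-pixel unit-weight case follows the composed formula", {
  p <- attention_gate_params(1, 1, Wx = matrix(1, 1, 1),
                             Wg = matrix(1, 1, 1), Ws = matrix(1, 1, 1))
  x <- array(1, c(4, 4, 1))   # even dims keep downstream shapes simple
  g <- array(1, c(4, 4, 1))
  sig <- function(v) 1 / (1 + exp(-v))
  a_expect <- sig(swish(2))   # Wx*x + Wg*g = 2 -> swish -> Ws -> sigmoid
  out <- attention_gate(x, g, p)
  expect_equal(out[1, 1, 1], a_expect * 1, tolerance = 1e-12)
})

test_that("attention coefficients lie strictly in (0, 1) and bound x_out", {
  set.seed(3)
  for (rep in 1:5) {
    p <- attention_gate_params(3, 2)
    x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
    g <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
    out <- attention_gate(x, g, p)
    a <- attr(out, "coefficients")
    expect_true(all(a > 0 & a < 1))
    expect_true(all(abs(out) <= abs(x) + 1e-12))
  }
})

test_that("spatial mismatch between x and g is rejected with shapes", {
  p <- attention_gate_params(1, 1)
  expect_error(
    attention_gate(array(0, c(4, 4, 1)), array(0, c(2, 2, 1)), p),
    "spatial mismatch")
})

test_that("wavelet gate has the documented shape arithmetic", {
  set.seed(9)
  p <- wavelet_gate_params(2, 4)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  g <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  out <- wavelet_gate(x, g, p)
  expect_identical(dim(out), c(16L, 16L, 6L))  # 3C channels at x resolution
  # with HH kept: 4C channels
  p4 <- wavelet_gate_params(2, 4, include_hh = TRUE)
  expect_identical(dim(wavelet_gate(x, g, p4))[3], 8L)
})

test_that("wavelet gate is deterministic and linear detail path zeros out", {
  set.seed(10)
  p <- wavelet_gate_params(1, 1)
  x <- array(5, c(8, 8, 1))                 # constant -> LH = HL = 0
  g <- array(rnorm(16), c(4, 4, 1))
  o1 <- wavelet_gate(x, g, p)
  o2 <- wavelet_gate(x, g, p)
  expect_identical(o1, o2)
  # before upsampling, the concatenated detail channels are exactly zero:
  b <- dwt_bands(x[, , 1])
  expect_lt(max(abs(b$LH)), 1e-12)
  expect_lt(max(abs(b$HL)), 1e-12)
})

test_that("sharpening filter preserves constants and sharpens edges", {
  expect_equal(sharpen_filter(matrix(7, 6, 6)), matrix(7, 6, 6),
               tolerance = 1e-12)
  step <- matrix(rep(c(0, 1), each = 24), 6, 8)
  sh <- sharpen_filter(step)
  expect_gt(max(abs(sh)), 1)   # overshoot at the edge
})

test_that("skip_tensor covers all four modes with correct channels", {
  set.seed(11)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  d_up <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  d_coarse <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  expect_identical(skip_tensor("plain", x), x)
  expect_identical(dim(skip_tensor("sharpen", x)), dim(x))
  agp <- attention_gate_params(2, 2)
  expect_identical(dim(skip_tensor("attention", x, list(d_up = d_up), agp)),
                   dim(x))
  wat <- skip_tensor("watunet", x,
                     list(d_up = d_up, d_coarse = d_coarse),
                     list(ag = agp, wg = wavelet_gate_params(2, 4)))
  expect_identical(dim(wat), c(8L, 8L, 8L))  # 3C (wavelet) + C (attention)
  expect_error(skip_tensor("nope", x), "unknown skip mode")
})
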