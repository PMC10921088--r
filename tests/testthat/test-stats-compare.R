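# McNemar + Benjamini-Hochberg: hand-enumerated discordance cases, the
# chi-squared(1) statistic against an independent normal-tail evaluation,
# and the step-up procedure against both hand-worked examples and the
# stock BH adjustment.

test_that("discordance matches hand enumeration and is antisymmetric", {
  gt <- c(1, 1, 1, 0, 0, 0)
  A <- c(1, 1, 1, 1, 0, 0)   # wrong only at pixel 4
  B <- c(1, 0, 1, 0, 0, 0)   # wrong only at pixel 2
  d <- discordance(A, B, gt)
  expect_identical(c(d$b, d$c, d$n_pixels), c(1L, 1L, 6L))
  dr <- discordance(B, A, gt)
  expect_identical(c(dr$b, dr$c), c(d$c, d$b))
  expect_identical(discordance(A, A, gt)$b + discordance(A, A, gt)$c, 0L)
  # pooling over image lists
  dl <- discordance(list(A, B), list(B, A), list(gt, gt))
  expect_identical(dl$n_pixels, 12L)
  expect_identical(c(dl$b, dl$c), c(2L, 2L))
  expect_error(discordance(A, B[1:3], gt), "mismatch")
})

test_that("McNemar statistic and p-value match an independent evaluation", {
  t1 <- mcnemar_test(list(b = 8, c = 2))
  expect_equal(t1$statistic, 3.6, tolerance = 1e-12)
  expect_equal(t1$p_value, 0.0578, tolerance = 1e-3)
  # independent route: chi2(1) tail = 2 * upper normal tail at sqrt(stat)
  set.seed(1)
  for (i in 1:100) {
    b <- sample(0:50, 1); c_ <- sample(0:50, 1)
    if (b + c_ == 0) next
    t_ <- mcnemar_test(list(b = b, c = c_))
    expect_equal(t_$statistic, (b - c_)^2 / (b + c_), tolerance = 1e-12)
    expect_equal(t_$p_value,
                 2 * pnorm(sqrt(t_$statistic), lower.tail = FALSE),
                 tolerance = 1e-10)
    tsw <- mcnemar_test(list(b = c_, c = b))
    expect_equal(tsw$statistic, t_$statistic, tolerance = 1e-12)
  }
})

test_that("b = c gives statistic 0, p = 1; no discordance is flagged", {
  t_ <- mcnemar_test(list(b = 5, c = 5))
  expect_identical(t_$statistic, 0)
  expect_identical(t_$p_value, 1)
  expect_false(t_$no_discordance)
  t0 <- mcnemar_test(list(b = 0, c = 0))
  expect_identical(t0$p_value, 1)
  expect_true(t0$no_discordance)
  expect_error(mcnemar_test(list(b = -1, c = 2)), "non-negative")
})

test_that("the continuity correction is available and matches stats::", {
  d <- list(b = 8, c = 2)
  tc <- mcnemar_test(d, correction = TRUE)
  ref <- stats::mcnemar.test(matrix(c(5, 2, 8, 5), 2, 2), correct = TRUE)
  expect_equal(tc$statistic, unname(ref$statistic), tolerance = 1e-12)
  ref0 <- stats::mcnemar.test(matrix(c(5, 2, 8, 5), 2, 2), correct = FALSE)
  expect_equal(mcnemar_test(d)$p_value, unname(ref0$p.value),
               tolerance = 1e-12)
})

test_that("BH critical values are (i/m) * alpha", {
  tab <- bh_procedure(runif(10), alpha = 0.05)
  expect_equal(tab$critical_value, seq(0.005, 0.050, by = 0.005),
               tolerance = 1e-12)
  expect_true(all(diff(tab$critical_value) > 0))
})

test_that("the step-up rule matches hand-worked examples", {
  tab <- bh_procedure(c(a = 0.001, b = 0.04, c = 0.9), alpha = 0.05)
  expect_equal(tab$critical_value, c(1, 2, 3) / 3 * 0.05, tolerance = 1e-9)
  expect_identical(tab$significant, c(TRUE, FALSE, FALSE))
  expect_identical(tab$pair, c("a", "b", "c"))
  all1 <- bh_procedure(rep(1, 6))
  expect_false(any(all1$significant))
  # step-up: a late small critical failure does not block earlier ranks
  tab2 <- bh_procedure(c(0.01, 0.012, 0.013, 0.9), alpha = 0.05)
  expect_identical(tab2$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_error(bh_procedure(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the Bonferroni option matches p.adjust", {
  set.seed(5)
  p <- runif(8)^2
  tab <- bh_procedure(p, alpha = 0.05, method = "bonferroni")
  expect_true(all(tab$critical_value == 0.05 / 8))
  expect_identical(sum(tab$significant),
                   sum(p.adjust(p, "bonferroni") <= 0.05))
})

test_that("BH agrees with p.adjust and is bracketed by naive/Bonferroni", {
  set.seed(2)
  for (i in 1:25) {
    m <- sample(3:12, 1)
    p <- runif(m)^sample(1:3, 1)
    tab <- bh_procedure(p, alpha = 0.05)
    q <- p.adjust(p, method = "BH")
    expect_identical(sum(tab$significant), sum(q <= 0.05))
    n_naive <- sum(p <= 0.05)
    n_bonf <- sum(p.adjust(p, "bonferroni") <= 0.05)
    expect_lte(sum(tab$significant), n_naive)
    expect_gte(sum(tab$significant), n_bonf)
    # order invariance
    tab_perm <- bh_procedure(sample(p), alpha = 0.05)
    expect_identical(sum(tab_perm$significant), sum(tab$significant))
  }
})

test_that("comparison_table has C(k,2) rows and consistent BH columns", {
  set.seed(3)
  gt <- lapply(1:3, function(i) matrix(rbinom(64, 1, 0.3), 8, 8))
  preds <- lapply(1:4, function(k)
    lapply(gt, function(g) {
      flip <- matrix(rbinom(64, 1, 0.05 * k), 8, 8)
      (g + flip) %% 2
    }))
  names(preds) <- paste0("m", 1:4)
  tab <- comparison_table(preds, gt)
  expect_identical(nrow(tab), 6L)             # C(4,2)
  expect_identical(tab$rank, 1:6)
  expect_true(all(diff(tab$critical_value) > 0))
  expect_true(!is.unsorted(tab$p_value))
  expect_error(comparison_table(preds[1], gt), "at least two")
})
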