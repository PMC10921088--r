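# Pairwise model comparison: pixelwise McNemar tests over the pooled test
# set with Benjamini-Hochberg control of the false discovery rate. Each
# pair of models yields one global 2x2 discordance table (pixels pooled over
# all test images), the plain chi-squared(1 df) McNemar statistic
# (b - c)^2 / (b + c), and an upper-tail p-value; the BH step-up procedure
# then assigns per-rank critical values (i/m) * alpha.

#' Discordance counts between two models
#'
#' Pixels are scored correct/incorrect against the ground truth; `b` counts
#' pixels where model A is correct and model B wrong, `c` the reverse.
#' Inputs may be single masks or lists of masks (pooled over all images).
#'
#' @param predA,predB binarized predictions (masks or lists of masks).
#' @param gt ground-truth mask(s), same shapes.
#' @return a list with `b`, `c` and `n_pixels`.
#' @export
discordance <- function(predA, predB, gt) {
  if (!is.list(predA)) { predA <- list(predA); predB <- list(predB); gt <- list(gt) }
  if (length(predA) != length(predB) || length(predA) != length(gt))
    stop("predA, predB and gt must have the same length")
  b <- 0L; c_ <- 0L; n <- 0L
  for (i in seq_along(gt)) {
    if (length(predA[[i]]) != length(gt[[i]]) ||
        length(predB[[i]]) != length(gt[[i]]))
      stop("shape mismatch between predictions and ground truth at image ", i)
    okA <- predA[[i]] == gt[[i]]
    okB <- predB[[i]] == gt[[i]]
    b <- b + sum(okA & !okB)
    c_ <- c_ + sum(!okA & okB)
    n <- n + length(gt[[i]])
  }
  list(b = b, c = c_, n_pixels = n)
}

#' McNemar test on discordance counts
#'
#' Plain (uncorrected) McNemar statistic `(b - c)^2 / (b + c)` referred to
#' the chi-squared distribution with 1 degree of freedom. With huge pixel
#' counts the continuity correction is immaterial, but it is available.
#'
#' @param counts a list with `b` and `c` (as from [discordance()]).
#' @param correction apply the Edwards continuity correction
#'   (`(|b-c|-1)^2 / (b+c)`).
#' @return list with `statistic`, `p_value`, `b`, `c` and `no_discordance`
#'   (TRUE when `b + c = 0`, in which case `p_value` is 1).
#' @export
mcnemar_test <- function(counts, correction = FALSE) {
  b <- counts$b; c_ <- counts$c
  if (b < 0 || c_ < 0) stop("b and c must be non-negative")
  if (b + c_ == 0)
    return(list(statistic = 0, p_value = 1, b = b, c = c_,
                no_discordance = TRUE))
  stat <- if (correction) (abs(b - c_) - 1)^2 / (b + c_) else
    (b - c_)^2 / (b + c_)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       b = b, c = c_, no_discordance = FALSE)
}

#' Benjamini-Hochberg step-up procedure
#'
#' Sorts the p-values ascending, assigns rank `i` and critical value
#' `(i/m) * alpha`, and flags as significant every pair with rank at most
#' `i*`, the largest `i` with `p_(i) <= (i/m) * alpha`.
#'
#' @param p_values numeric vector of p-values (optionally named by pair).
#' @param alpha target false discovery rate (default 0.05).
#' @param method `"bh"` (default) for the step-up FDR procedure, or
#'   `"bonferroni"` for the family-wise-error alternative, where every rank
#'   uses the single critical value `alpha / m`.
#' @return a `data.frame` with columns `pair`, `p_value`, `rank`,
#'   `critical_value`, `significant`, ordered by rank.
#' @export
bh_procedure <- function(p_values, alpha = 0.05,
                         method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (length(p_values) < 1) stop("need at least one p-value")
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  m <- length(p_values)
  nm <- names(p_values)
  if (is.null(nm)) nm <- paste0("pair", seq_len(m))
  o <- order(p_values)
  ps <- p_values[o]
  if (method == "bonferroni") {
    crit <- rep(alpha / m, m)
    sig <- ps <= crit
  } else {
    crit <- seq_len(m) / m * alpha
    below <- which(ps <= crit)
    istar <- if (length(below)) max(below) else 0L
    sig <- seq_len(m) <= istar
  }
  data.frame(
    pair = nm[o],
    p_value = unname(ps),
    rank = seq_len(m),
    critical_value = crit,
    significant = sig,
    row.names = NULL)
}

#' Pairwise McNemar comparison table for a set of models
#'
#' Builds the full `C(k, 2)`-row comparison table: for every pair of models,
#' the pooled pixel discordance counts, the McNemar chi-squared statistic
#' and p-value, and the Benjamini-Hochberg rank/critical value/significance
#' at the requested FDR level.
#'
#' @param predictions named list (one entry per model) of binarized
#'   prediction mask lists.
#' @param gt list of ground-truth masks.
#' @param alpha target false discovery rate (default 0.05).
#' @param correction passed to [mcnemar_test()].
#' @return a `data.frame` with columns `pair`, `b`, `c`, `statistic`,
#'   `p_value`, `rank`, `critical_value`, `significant`.
#' @export
comparison_table <- function(predictions, gt, alpha = 0.05,
                             correction = FALSE) {
  k <- length(predictions)
  if (k < 2) stop("need at least two models to compare")
  nms <- names(predictions)
  if (is.null(nms)) nms <- paste0("model", seq_len(k))
  rows <- list()
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    d <- discordance(predictions[[i]], predictions[[j]], gt)
    t_ <- mcnemar_test(d, correction)
    rows[[length(rows) + 1]] <- data.frame(
      pair = paste0("(", nms[i], ", ", nms[j], ")"),
      b = d$b, c = d$c, statistic = t_$statistic, p_value = t_$p_value)
  }
  tab <- do.call(rbind, rows)
  bh <- bh_procedure(stats::setNames(tab$p_value, tab$pair), alpha)
  out <- merge(tab, bh[, c("pair", "rank", "critical_value", "significant")],
               by = "pair", sort = FALSE)
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  out
}
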