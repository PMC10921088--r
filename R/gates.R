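# Skip-connection gates: the additive attention gate and the wavelet gate.
#
# Attention gate (per spatial site i, channels projected by 1x1 convs):
#   a_i  = sigmoid( Ws' swish( Wx' x_i + Wg' g_i + b_g ) + b_s )
#   out  = x_i * a_i          (a_i is a single channel, broadcast over x)
# with b_g = b_s = 0, fixed and non-trainable.
#
# Wavelet gate: single-level Db2 DWT of the encoder map; the LL band is
# attention-gated by the coarse decoder feature (1x1-projected, it already
# lives at LL resolution), the LH/HL detail bands are concatenated to the
# gated LL, HH is discarded, and the 3C-channel stack is returned to the
# encoder resolution by a learned 3x3 stride-2 transposed convolution.

#' Swish activation
#'
#' The smooth, non-monotonic activation `v * sigmoid(v)` used throughout the
#' network and as the inner nonlinearity of the attention gate.
#'
#' @param v numeric vector/array.
#' @return `v * sigmoid(v)`, elementwise, same shape as `v`.
#' @examples
#' swish(0)   # 0
#' swish(-1)  # approx -0.26894
#' @export
swish <- function(v) v * .sigmoid(v)

#' Parameters of one additive attention gate
#'
#' Creates (or wraps) the trainable 1x1 channel projections of an attention
#' gate: `Wx` (skip input, `channels_x` -> `channels_inter`), `Wg` (gating
#' signal, `channels_g` -> `channels_inter`) and `Ws`
#' (`channels_inter` -> 1, the single attention channel). The biases of the
#' gate are fixed at zero and are not trainable.
#'
#' @param channels_x channels of the skip feature map.
#' @param channels_g channels of the gating signal.
#' @param channels_inter channels of the intermediate projection; defaults
#'   to `channels_x` (the projections keep the channel count of the inputs).
#' @param Wx,Wg,Ws optional explicit matrices overriding random
#'   initialization (He-uniform, drawn from the current RNG state).
#' @return an object of class `attention_gate_params`.
#' @export
attention_gate_params <- function(channels_x, channels_g,
                                  channels_inter = channels_x,
                                  Wx = NULL, Wg = NULL, Ws = NULL) {
  if (is.null(Wx)) Wx <- .he_uniform(c(channels_x, channels_inter), channels_x)
  if (is.null(Wg)) Wg <- .he_uniform(c(channels_g, channels_inter), channels_g)
  if (is.null(Ws)) Ws <- .he_uniform(c(channels_inter, 1), channels_inter)
  Wx <- as.matrix(Wx); Wg <- as.matrix(Wg); Ws <- as.matrix(Ws)
  if (ncol(Wx) != ncol(Wg))
    stop("Wx and Wg must project to the same channel count")
  if (nrow(Ws) != ncol(Wx))
    stop("Ws must accept the intermediate channel count")
  structure(list(Wx = Wx, Wg = Wg, Ws = Ws, b_g = 0, b_s = 0),
            class = "attention_gate_params")
}

# trainable attention-gate layer on (H,W,C,N) tensors
new_attention_gate <- function(cx, cg, ci = cx, params = NULL) {
  self <- new.env(parent = emptyenv())
  self$type <- "attention_gate"
  if (is.null(params)) params <- attention_gate_params(cx, cg, ci)
  self$Wx <- params$Wx; self$Wg <- params$Wg; self$Ws <- params$Ws
  self$pnames <- c("Wx", "Wg", "Ws")
  self$fwd <- function(x, g, training = FALSE) {
    dx <- dim(x); dg <- dim(g)
    if (any(dx[c(1, 2, 4)] != dg[c(1, 2, 4)]))
      stop(sprintf("attention gate: spatial mismatch between x (%s) and g (%s)",
                   paste(dx, collapse = "x"), paste(dg, collapse = "x")))
    self$x <- x; self$g <- g; self$d <- dx
    hwn <- dx[c(1, 2, 4)]
    q <- .chmat(x) %*% self$Wx + .chmat(g) %*% self$Wg   # (HWN, ci)
    self$q <- q
    self$sq <- .sigmoid(q)
    s <- q * self$sq                                      # swish
    self$s <- s
    t_ <- s %*% self$Ws                                   # (HWN, 1)
    a <- .sigmoid(t_)
    self$a <- a
    self$amap <- .chunmat(a, hwn, 1L)
    x * .bc_map(self$amap, dx)
  }
  self$bwd <- function(dy) {
    d <- self$d
    abc <- .bc_map(self$amap, d)
    dx <- dy * abc
    # gradient into the single attention channel: sum over x's channels
    da_map <- .csum_channels(dy * self$x)                 # (H,W,1,N)
    da <- .chmat(da_map)                                  # (HWN, 1)
    dt <- da * self$a * (1 - self$a)
    self$dWs <- crossprod(self$s, dt)
    ds <- dt %*% t(self$Ws)
    dq <- ds * (self$sq + self$q * self$sq * (1 - self$sq))
    self$dWx <- crossprod(.chmat(self$x), dq)
    self$dWg <- crossprod(.chmat(self$g), dq)
    dx <- dx + .chunmat(dq %*% t(self$Wx), d[c(1, 2, 4)], nrow(self$Wx))
    dg <- .chunmat(dq %*% t(self$Wg), d[c(1, 2, 4)], nrow(self$Wg))
    list(dx = dx, dg = dg)
  }
  self
}

# broadcast an (H,W,1,N) map over C channels
.bc_map <- function(a, d) {
  out <- array(0, d)
  for (c_ in seq_len(d[3])) out[, , c_, ] <- a[, , 1, ]
  out
}

.csum_channels <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1], d[2], 1, d[4]))
  for (c_ in seq_len(d[3])) out[, , 1, ] <- out[, , 1, ] + x[, , c_, ]
  out
}

# concat / split along the channel dimension of (H,W,C,N) arrays
.cat_channels <- function(lst) {
  d <- dim(lst[[1]])
  cs <- vapply(lst, function(a) dim(a)[3], numeric(1))
  out <- array(0, c(d[1], d[2], sum(cs), d[4]))
  at <- 0
  for (a in lst) {
    out[, , at + seq_len(dim(a)[3]), ] <- a
    at <- at + dim(a)[3]
  }
  out
}

.split_channels <- function(x, sizes) {
  at <- 0
  lapply(sizes, function(s) {
    a <- x[, , at + seq_len(s), , drop = FALSE]
    at <<- at + s
    a
  })
}

#' Apply an additive attention gate to a feature map
#'
#' Computes the attention coefficients
#' `a = sigmoid(Ws' swish(Wx' x + Wg' g))` (one coefficient per spatial
#' site, biases fixed at zero) and returns `x * a` with `a` broadcast over
#' the channels of `x`. `x` and `g` must share spatial dimensions.
#'
#' @param x skip feature map, array (height x width x channels) or a matrix.
#' @param g gating signal, same spatial dimensions as `x`.
#' @param params an [attention_gate_params()] object.
#' @return the gated feature map, same shape as `x`, with the coefficient
#'   map attached as attribute `"coefficients"` (values strictly in (0,1)).
#' @export
attention_gate <- function(x, g, params) {
  if (!inherits(params, "attention_gate_params"))
    stop("params must be an attention_gate_params object")
  x4 <- .as_hwcn(x); g4 <- .as_hwcn(g)
  ag <- new_attention_gate(dim(x4)[3], dim(g4)[3], params = params)
  out <- ag$fwd(x4, g4)
  a <- ag$amap
  out <- .from_hwcn(out, x)
  attr(out, "coefficients") <- .from_hwcn(a, if (is.matrix(x)) x else a[, , , 1])
  out
}

.as_hwcn <- function(x) {
  if (is.matrix(x)) return(array(x, c(dim(x), 1L, 1L)))
  d <- dim(x)
  if (length(d) == 3L) return(array(x, c(d, 1L)))
  if (length(d) == 4L) return(x)
  stop("expected a matrix or an array with 3 or 4 dimensions")
}

.from_hwcn <- function(y, like) {
  if (is.matrix(like)) return(y[, , 1, 1])
  if (length(dim(like)) == 3L) return(array(y, dim(y)[1:3]))
  y
}

#' Parameters of one wavelet gate
#'
#' A wavelet gate owns three trainable pieces: the 1x1 projection taking the
#' coarse decoder feature to the encoder channel count, an internal
#' [attention_gate_params()] acting on the LL sub-band, and a learned 3x3
#' stride-2 transposed convolution that returns the concatenated
#' (gated-LL, LH, HL) stack to the encoder resolution.
#'
#' @param channels_x channels of the encoder feature map entering the gate.
#' @param channels_g channels of the coarse decoder (gating) feature.
#' @param include_hh if `TRUE` the HH (diagonal detail) band is kept in the
#'   concatenation as well; the default discards it as noise-dominated.
#' @return an object of class `wavelet_gate_params`.
#' @export
wavelet_gate_params <- function(channels_x, channels_g, include_hh = FALSE) {
  nb <- if (include_hh) 4L else 3L
  structure(list(
    proj_W = .he_uniform(c(1, 1, channels_g, channels_x), channels_g),
    proj_b = numeric(channels_x),
    ag = attention_gate_params(channels_x, channels_x),
    up_W = .he_uniform(c(3, 3, nb * channels_x, nb * channels_x),
                       9 * nb * channels_x),
    up_b = numeric(nb * channels_x),
    include_hh = include_hh
  ), class = "wavelet_gate_params")
}

# trainable wavelet-gate layer
new_wavelet_gate <- function(cx, cg, params = NULL, include_hh = FALSE) {
  self <- new.env(parent = emptyenv())
  self$type <- "wavelet_gate"
  if (is.null(params)) params <- wavelet_gate_params(cx, cg, include_hh)
  self$include_hh <- params$include_hh
  nb <- if (self$include_hh) 4L else 3L
  self$proj <- new_conv(cg, cx, k = 1L)
  self$proj$W <- params$proj_W; self$proj$b <- params$proj_b
  self$ag <- new_attention_gate(cx, cx, params = params$ag)
  self$up <- new_convt(nb * cx, nb * cx)
  self$up$W <- params$up_W; self$up$b <- params$up_b
  self$cx <- cx
  self$pnames <- character(0)  # parameters live in sub-layers
  self$fwd <- function(x, g_coarse, training = FALSE) {
    self$bands <- .dwt_fwd_batch(x)
    gp <- self$proj$fwd(g_coarse, training)
    gated <- self$ag$fwd(self$bands$LL, gp, training)
    parts <- list(gated, self$bands$LH, self$bands$HL)
    if (self$include_hh) parts <- c(parts, list(self$bands$HH))
    self$up$fwd(.cat_channels(parts), training)
  }
  self$bwd <- function(dy) {
    dcat <- self$up$bwd(dy)
    nb <- if (self$include_hh) 4L else 3L
    parts <- .split_channels(dcat, rep(self$cx, nb))
    agg <- self$ag$bwd(parts[[1]])
    dg_coarse <- self$proj$bwd(agg$dg)
    dbands <- list(LL = agg$dx, LH = parts[[2]], HL = parts[[3]],
                   HH = if (self$include_hh) parts[[4]] else 0 * self$bands$HH)
    list(dx = .dwt_bwd_batch(dbands), dg = dg_coarse)
  }
  self
}

#' Apply a wavelet gate to an encoder feature map
#'
#' Decomposes `x` with a single-level Db2 DWT, attention-gates the LL band
#' with the (projected) coarse gating feature, concatenates the gated LL
#' with the LH and HL detail bands (HH is discarded unless the parameters
#' say otherwise), and upsamples the stack back to the resolution of `x`
#' with a learned transposed convolution.
#'
#' @param x encoder feature map, (height x width x channels) array or
#'   matrix, with even spatial dimensions.
#' @param g_coarse coarse gating feature at half the resolution of `x`.
#' @param params a [wavelet_gate_params()] object.
#' @return a feature map with the spatial dimensions of `x` and `3 *`
#'   (or `4 *`, with HH kept) the channels of `x`.
#' @export
wavelet_gate <- function(x, g_coarse, params) {
  if (!inherits(params, "wavelet_gate_params"))
    stop("params must be a wavelet_gate_params object")
  x4 <- .as_hwcn(x); g4 <- .as_hwcn(g_coarse)
  wg <- new_wavelet_gate(dim(x4)[3], dim(g4)[3], params = params)
  out <- wg$fwd(x4, g4)
  if (is.matrix(x)) return(array(out, dim(out)[1:3]))
  if (length(dim(x)) == 3L) return(array(out, dim(out)[1:3]))
  out
}

#' Fixed Laplacian sharpening filter
#'
#' Convolves each channel with the 3x3 sharpening kernel
#' `[[-1,-1,-1],[-1,9,-1],[-1,-1,-1]]` (sum 1, so flat regions are
#' preserved). Periodic boundary handling keeps the operator exactly
#' self-adjoint, which its backward pass exploits.
#'
#' @param x matrix or (height x width x channels [x batch]) array.
#' @return the sharpened map, same shape as `x`.
#' @export
sharpen_filter <- function(x) {
  x4 <- .as_hwcn(x)
  out <- .sharpen_op(x4)
  .from_hwcn(out, x)
}

.sharpen_op <- function(x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]
  acc <- 9 * x
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ri <- ((seq_len(H) - 1 + di) %% H) + 1
    rj <- ((seq_len(W) - 1 + dj) %% W) + 1
    acc <- acc - x[ri, rj, , , drop = FALSE]
  }
  acc
}
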