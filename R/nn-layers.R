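# Layer primitives for the segmentation networks. Each layer is a mutable
# environment with $fwd(x, training) and $bwd(dy); $bwd returns the input
# gradient and leaves parameter gradients in the layer (dW, db, ...).
# Tensors are (H, W, C, N) arrays. Every layer is used exactly once per
# forward pass, so gradients are assigned, not accumulated.

.he_uniform <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(runif(prod(dims), -lim, lim), dims)
}

# reshape (H,W,C,N) -> (H*W*N, C) matrix for channel-wise linear algebra
.chmat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
}

.chunmat <- function(m, hwn, C) {
  aperm(array(m, c(hwn, C)), c(1, 2, 4, 3))
}

# broadcast a per-channel vector over an (H,W,C,N) array (column-major
# recycling: the length H*W*C pattern repeats across samples)
.bc <- function(v, d) rep(rep(v, each = d[1] * d[2]), times = 1)

.csum <- function(x) {
  d <- dim(x)
  colSums(matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3]))
}

new_conv <- function(cin, cout, k = 3L, stride = 1L, pad = as.integer(k %/% 2),
                     bias = TRUE) {
  self <- new.env(parent = emptyenv())
  self$type <- "conv"
  self$k <- as.integer(k); self$stride <- as.integer(stride)
  self$pad <- as.integer(pad)
  self$W <- .he_uniform(c(k, k, cin, cout), fan_in = k * k * cin)
  self$b <- numeric(cout)
  self$pnames <- if (bias) c("W", "b") else "W"
  self$fwd <- function(x, training = FALSE) {
    self$x <- x
    .conv2d_fwd(x, self$W, self$b, self$stride, self$pad)
  }
  self$bwd <- function(dy) {
    g <- .conv2d_bwd(self$x, self$W, dy, self$stride, self$pad)
    self$dW <- g$dw
    self$db <- g$db
    g$dx
  }
  self
}

new_convt <- function(cin, cout, k = 3L, stride = 2L, pad = 1L, opad = 1L) {
  self <- new.env(parent = emptyenv())
  self$type <- "convt"
  self$k <- as.integer(k); self$stride <- as.integer(stride)
  self$pad <- as.integer(pad); self$opad <- as.integer(opad)
  self$W <- .he_uniform(c(k, k, cin, cout), fan_in = k * k * cin)
  self$b <- numeric(cout)
  self$pnames <- c("W", "b")
  self$fwd <- function(x, training = FALSE) {
    self$x <- x
    .convt2d_fwd(x, self$W, self$b, self$stride, self$pad, self$opad)
  }
  self$bwd <- function(dy) {
    g <- .convt2d_bwd(self$x, self$W, dy, self$stride, self$pad)
    self$dW <- g$dw
    self$db <- g$db
    g$dx
  }
  self
}

new_bn <- function(C, momentum = 0.9, eps = 1e-5) {
  self <- new.env(parent = emptyenv())
  self$type <- "bn"
  self$gamma <- rep(1, C); self$beta <- rep(0, C)
  self$running_mean <- rep(0, C); self$running_var <- rep(1, C)
  self$momentum <- momentum; self$eps <- eps
  self$pnames <- c("gamma", "beta")
  self$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    if (training) {
      mu <- .csum(x) / (d[1] * d[2] * d[4])
      xc <- x - .bc(mu, d)
      v <- .csum(xc * xc) / (d[1] * d[2] * d[4])
      self$running_mean <- self$momentum * self$running_mean + (1 - self$momentum) * mu
      self$running_var <- self$momentum * self$running_var + (1 - self$momentum) * v
      self$mu <- mu; self$v <- v
      self$xhat <- xc * .bc(1 / sqrt(v + self$eps), d)
      self$xhat * .bc(self$gamma, d) + .bc(self$beta, d)
    } else {
      xh <- (x - .bc(self$running_mean, d)) *
        .bc(1 / sqrt(self$running_var + self$eps), d)
      xh * .bc(self$gamma, d) + .bc(self$beta, d)
    }
  }
  self$bwd <- function(dy) {
    d <- dim(dy)
    m <- d[1] * d[2] * d[4]
    self$dgamma <- .csum(dy * self$xhat)
    self$dbeta <- .csum(dy)
    istd <- 1 / sqrt(self$v + self$eps)
    dxhat <- dy * .bc(self$gamma, d)
    # compact orthogonalized form of the batch-norm gradient
    t1 <- .csum(dxhat) / m
    t2 <- .csum(dxhat * self$xhat) / m
    (dxhat - .bc(t1, d) - self$xhat * .bc(t2, d)) * .bc(istd, d)
  }
  self
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

new_act <- function(name = "swish") {
  self <- new.env(parent = emptyenv())
  self$type <- paste0("act_", name)
  self$pnames <- character(0)
  if (name == "swish") {
    self$fwd <- function(x, training = FALSE) {
      self$s <- .sigmoid(x); self$x <- x
      x * self$s
    }
    self$bwd <- function(dy) dy * (self$s + self$x * self$s * (1 - self$s))
  } else if (name == "relu") {
    self$fwd <- function(x, training = FALSE) {
      self$m <- x > 0
      x * self$m
    }
    self$bwd <- function(dy) dy * self$m
  } else if (name == "sigmoid") {
    self$fwd <- function(x, training = FALSE) {
      self$y <- .sigmoid(x)
      self$y
    }
    self$bwd <- function(dy) dy * self$y * (1 - self$y)
  } else stop("unknown activation: ", name)
  self
}

new_pool <- function() {
  self <- new.env(parent = emptyenv())
  self$type <- "maxpool"
  self$pnames <- character(0)
  self$fwd <- function(x, training = FALSE) {
    self$hw <- dim(x)[1:2]
    r <- .maxpool2_fwd(x)
    self$idx <- r$idx
    r$y
  }
  self$bwd <- function(dy) .maxpool2_bwd(dy, self$idx, self$hw[1], self$hw[2])
  self
}

new_dropout <- function(rate) {
  self <- new.env(parent = emptyenv())
  self$type <- "dropout"
  self$rate <- rate
  self$pnames <- character(0)
  self$fwd <- function(x, training = FALSE) {
    if (!training || self$rate <= 0) {
      self$m <- NULL
      return(x)
    }
    m <- array((runif(length(x)) >= self$rate) / (1 - self$rate), dim(x))
    self$m <- m
    x * m
  }
  self$bwd <- function(dy) if (is.null(self$m)) dy else dy * self$m
  self
}

# sequential container
new_seq <- function(layers) {
  self <- new.env(parent = emptyenv())
  self$type <- "seq"
  self$layers <- layers
  self$pnames <- character(0)
  self$fwd <- function(x, training = FALSE) {
    for (l in self$layers) x <- l$fwd(x, training)
    x
  }
  self$bwd <- function(dy) {
    for (l in rev(self$layers)) dy <- l$bwd(dy)
    dy
  }
  self
}

# conv -> BN -> activation, repeated nconv times
new_conv_block <- function(cin, cout, nconv = 2L, activation = "swish") {
  layers <- list()
  for (i in seq_len(nconv)) {
    layers <- c(layers, list(
      new_conv(if (i == 1) cin else cout, cout, k = 3L),
      new_bn(cout),
      new_act(activation)
    ))
  }
  new_seq(layers)
}

# Collect every parameter-bearing leaf layer of a container/gate tree.
.leaf_layers <- function(l) {
  if (l$type == "seq") return(unlist(lapply(l$layers, .leaf_layers)))
  if (l$type == "attention_gate") return(list(l))
  if (l$type == "wavelet_gate")
    return(c(.leaf_layers(l$proj), .leaf_layers(l$ag), .leaf_layers(l$up)))
  if (length(l$pnames)) list(l) else list()
}

# --- Adam ------------------------------------------------------------------

new_adam <- function(layers, lr = 0.001, beta1 = 0.9, beta2 = 0.9,
                     eps = 1e-7) {
  self <- new.env(parent = emptyenv())
  self$layers <- layers
  self$lr <- lr; self$beta1 <- beta1; self$beta2 <- beta2; self$eps <- eps
  self$t <- 0L
  self$m <- list(); self$v <- list()
  for (i in seq_along(layers)) for (p in layers[[i]]$pnames) {
    key <- paste0(i, ".", p)
    self$m[[key]] <- 0 * layers[[i]][[p]]
    self$v[[key]] <- self$m[[key]]
  }
  self$step <- function() {
    self$t <- self$t + 1L
    bc1 <- 1 - self$beta1^self$t
    bc2 <- 1 - self$beta2^self$t
    for (i in seq_along(self$layers)) {
      l <- self$layers[[i]]
      for (p in l$pnames) {
        g <- l[[paste0("d", p)]]
        if (is.null(g)) next
        key <- paste0(i, ".", p)
        self$m[[key]] <- self$beta1 * self$m[[key]] + (1 - self$beta1) * g
        self$v[[key]] <- self$beta2 * self$v[[key]] + (1 - self$beta2) * g * g
        l[[p]] <- l[[p]] - self$lr * (self$m[[key]] / bc1) /
          (sqrt(self$v[[key]] / bc2) + self$eps)
      }
    }
    invisible(NULL)
  }
  self
}

# snapshot / restore trainable + batch-norm state (best-model checkpointing)
.layer_state <- function(layers) {
  lapply(layers, function(l) {
    s <- lapply(l$pnames, function(p) l[[p]])
    names(s) <- l$pnames
    if (l$type == "bn") {
      s$running_mean <- l$running_mean
      s$running_var <- l$running_var
    }
    s
  })
}

.restore_state <- function(layers, state) {
  for (i in seq_along(layers)) {
    for (p in names(state[[i]])) layers[[i]][[p]] <- state[[i]][[p]]
  }
  invisible(NULL)
}
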