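# Assembly of the segmentation networks. All four variants share one
# encoder/decoder backbone (conv blocks of 3x3 stride-1 convolutions, each
# followed by batch normalization and the configured activation; 2x2 max
# pooling on the way down; 3x3 stride-2 transposed convolutions on the way
# up; a bottleneck conv block in between; dropout after every block) and
# differ only in how the skip tensor handed to the decoder is produced:
#
#   plain     - the encoder feature unchanged (classic UNet)
#   attention - additive attention gate over the encoder feature
#   sharpen   - fixed 3x3 Laplacian sharpening of the encoder feature
#   watunet   - wavelet gate and attention gate in parallel, concatenated

#' Network configuration
#'
#' @param depth number of down/up-sampling blocks (the published model uses
#'   four).
#' @param base_channels channels of the first encoder block; doubled at each
#'   deeper level. 64 for full fidelity, small values (8-16) for CPU-scale
#'   work.
#' @param convs_per_block convolution/BN/activation triplets per block.
#' @param encoder_dropout,decoder_dropout dropout rates after encoder and
#'   decoder blocks (published values 0.1 and 0.5).
#' @param skip_mode one of `"plain"`, `"attention"`, `"sharpen"`,
#'   `"watunet"`.
#' @param activation activation function name (`"swish"` or `"relu"`).
#' @param input_size `c(H, W)` of the (single-channel) input images. Must be
#'   divisible by `2^depth`; the wavelet gate additionally requires
#'   divisibility by `2^(depth+1)` so every level's DWT sees even dims.
#' @param wavelet_levels for `skip_mode = "watunet"`, which encoder levels
#'   carry a wavelet gate (default: all of them).
#' @param include_hh keep the HH (diagonal detail) band in the wavelet gate
#'   instead of discarding it.
#' @return a `network_config` list.
#' @export
network_config <- function(depth = 4L, base_channels = 16L,
                           convs_per_block = 2L,
                           encoder_dropout = 0.1, decoder_dropout = 0.5,
                           skip_mode = c("watunet", "plain", "attention",
                                         "sharpen"),
                           activation = "swish", input_size = c(128L, 128L),
                           wavelet_levels = seq_len(depth),
                           include_hh = FALSE) {
  skip_mode <- match.arg(skip_mode)
  stopifnot(depth >= 1, base_channels >= 1, convs_per_block >= 1)
  if (encoder_dropout < 0 || encoder_dropout >= 1 ||
      decoder_dropout < 0 || decoder_dropout >= 1)
    stop("dropout rates must lie in [0, 1)")
  input_size <- as.integer(input_size)
  div <- if (skip_mode == "watunet") 2L^(depth + 1L) else 2L^depth
  if (any(input_size %% div != 0))
    stop(sprintf(
      "input_size %s must be divisible by %d for depth %d with skip_mode '%s'",
      paste(input_size, collapse = "x"), div, depth, skip_mode))
  structure(list(
    depth = as.integer(depth), base_channels = as.integer(base_channels),
    convs_per_block = as.integer(convs_per_block),
    encoder_dropout = encoder_dropout, decoder_dropout = decoder_dropout,
    skip_mode = skip_mode, activation = activation,
    input_size = input_size,
    wavelet_levels = as.integer(wavelet_levels),
    include_hh = include_hh
  ), class = "network_config")
}

# skip-tensor channel multiplicity per mode (x C_level)
.skip_mult <- function(mode, wavelet = TRUE, include_hh = FALSE) {
  switch(mode,
    plain = 1L, attention = 1L, sharpen = 1L,
    watunet = if (wavelet) (if (include_hh) 4L else 3L) + 1L else 1L + 1L)
}

#' Build a segmentation model
#'
#' Constructs the encoder/decoder network described by a [network_config()]:
#' `depth` encoder blocks (3x3 convolutions + batch norm + activation, 2x2
#' max pooling, dropout), a bottleneck block, `depth` decoder blocks (3x3
#' stride-2 transposed convolution, concatenation with the skip tensor of
#' the configured mode, conv block, dropout) and a final 1x1 convolution
#' with a sigmoid, producing a single-channel probability map the size of
#' the input. Convolution weights use seeded He-uniform initialization.
#'
#' @param config a [network_config()].
#' @param seed integer seed for parameter initialization; two builds with
#'   the same seed are identical.
#' @return an object of class `watunet_model`.
#' @export
build_model <- function(config, seed = NULL) {
  stopifnot(inherits(config, "network_config"))
  if (!is.null(seed)) set.seed(seed)
  depth <- config$depth
  ch <- as.integer(config$base_channels * 2^(seq_len(depth) - 1))
  cb <- as.integer(config$base_channels * 2^depth)
  act <- config$activation

  enc <- vector("list", depth)
  cin <- 1L
  for (l in seq_len(depth)) {
    enc[[l]] <- list(
      block = new_conv_block(cin, ch[l], config$convs_per_block, act),
      pool = new_pool(),
      drop = new_dropout(config$encoder_dropout))
    cin <- ch[l]
  }
  bottleneck <- list(
    block = new_conv_block(ch[depth], cb, config$convs_per_block, act),
    drop = new_dropout(config$encoder_dropout))

  dec <- vector("list", depth)
  for (l in seq(depth, 1L)) {
    c_below <- if (l == depth) cb else ch[l + 1L]
    has_wg <- config$skip_mode == "watunet" && l %in% config$wavelet_levels
    entry <- list(upc = new_convt(c_below, ch[l]), has_wg = has_wg)
    if (config$skip_mode %in% c("attention", "watunet"))
      entry$ag <- new_attention_gate(ch[l], ch[l])
    if (has_wg)
      entry$wg <- new_wavelet_gate(ch[l], c_below,
                                   include_hh = config$include_hh)
    mult <- .skip_mult(config$skip_mode, has_wg, config$include_hh)
    entry$skip_channels <- as.integer(mult * ch[l])
    entry$block <- new_conv_block(ch[l] + entry$skip_channels, ch[l],
                                  config$convs_per_block, act)
    entry$drop <- new_dropout(config$decoder_dropout)
    dec[[l]] <- entry
  }
  final <- new_conv(ch[1], 1L, k = 1L)
  outact <- new_act("sigmoid")

  layers <- list()
  for (l in seq_len(depth)) layers <- c(layers, .leaf_layers(enc[[l]]$block))
  layers <- c(layers, .leaf_layers(bottleneck$block))
  for (l in seq(depth, 1L)) {
    e <- dec[[l]]
    layers <- c(layers, list(e$upc))
    if (!is.null(e$ag)) layers <- c(layers, list(e$ag))
    if (isTRUE(e$has_wg)) layers <- c(layers, .leaf_layers(e$wg))
    layers <- c(layers, .leaf_layers(e$block))
  }
  layers <- c(layers, list(final))

  model <- new.env(parent = emptyenv())
  model$config <- config
  model$channels <- ch
  model$enc <- enc
  model$bottleneck <- bottleneck
  model$dec <- dec
  model$final <- final
  model$outact <- outact
  model$layers <- layers
  class(model) <- c("watunet_model", "environment")
  model
}

#' @export
print.watunet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<watunet_model> skip_mode=%s depth=%d base_channels=%d input=%dx%d\n",
    cfg$skip_mode, cfg$depth, cfg$base_channels,
    cfg$input_size[1], cfg$input_size[2]))
  cat(sprintf("  trainable parameters: %d\n", n_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters of a model
#' @param model a `watunet_model`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$layers, function(l)
    sum(vapply(l$pnames, function(p) length(l[[p]]), numeric(1))),
    numeric(1)))
}

# full forward pass; x is (H, W, 1, N)
model_forward <- function(model, x, training = FALSE) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L)
    stop("input must be an (H, W, 1, N) array")
  if (any(d[1:2] != model$config$input_size))
    stop(sprintf("input is %dx%d but the model was built for %dx%d",
                 d[1], d[2], model$config$input_size[1],
                 model$config$input_size[2]))
  depth <- model$config$depth
  mode <- model$config$skip_mode
  cache <- list(skips = vector("list", depth))
  h <- x
  for (l in seq_len(depth)) {
    e <- model$enc[[l]]
    s <- e$block$fwd(h, training)
    cache$skips[[l]] <- s
    h <- e$drop$fwd(e$pool$fwd(s, training), training)
  }
  h <- model$bottleneck$drop$fwd(
    model$bottleneck$block$fwd(h, training), training)
  for (l in seq(depth, 1L)) {
    e <- model$dec[[l]]
    d_coarse <- h
    d_up <- e$upc$fwd(h, training)
    x_enc <- cache$skips[[l]]
    s <- switch(mode,
      plain = x_enc,
      sharpen = .sharpen_op(x_enc),
      attention = e$ag$fwd(x_enc, d_up, training),
      watunet = {
        ag_out <- e$ag$fwd(x_enc, d_up, training)
        if (isTRUE(e$has_wg))
          .cat_channels(list(e$wg$fwd(x_enc, d_coarse, training), ag_out))
        else ag_out
      })
    h <- e$drop$fwd(e$block$fwd(.cat_channels(list(d_up, s)), training),
                    training)
  }
  model$cache <- cache
  model$outact$fwd(model$final$fwd(h, training), training)
}

# full backward pass from the gradient of the loss wrt the probability map;
# parameter gradients are left in the layers
model_backward <- function(model, dprob) {
  depth <- model$config$depth
  mode <- model$config$skip_mode
  ch <- model$channels
  dy <- model$final$bwd(model$outact$bwd(dprob))
  dskips <- vector("list", depth)
  for (l in seq_len(depth)) {
    e <- model$dec[[l]]
    dh <- e$block$bwd(e$drop$bwd(dy))
    parts <- .split_channels(dh, c(ch[l], e$skip_channels))
    dd_up <- parts[[1]]
    ds <- parts[[2]]
    dd_coarse <- NULL
    dskip <- switch(mode,
      plain = ds,
      sharpen = .sharpen_op(ds),   # self-adjoint under periodic padding
      attention = {
        r <- e$ag$bwd(ds)
        dd_up <- dd_up + r$dg
        r$dx
      },
      watunet = {
        if (isTRUE(e$has_wg)) {
          nb <- if (model$config$include_hh) 4L else 3L
          sp <- .split_channels(ds, c(nb * ch[l], ch[l]))
          rw <- e$wg$bwd(sp[[1]])
          ra <- e$ag$bwd(sp[[2]])
          dd_up <- dd_up + ra$dg
          dd_coarse <- rw$dg
          rw$dx + ra$dx
        } else {
          r <- e$ag$bwd(ds)
          dd_up <- dd_up + r$dg
          r$dx
        }
      })
    dskips[[l]] <- dskip
    dy <- e$upc$bwd(dd_up)
    if (!is.null(dd_coarse)) dy <- dy + dd_coarse
  }
  dy <- model$bottleneck$block$bwd(model$bottleneck$drop$bwd(dy))
  for (l in seq(depth, 1L)) {
    e <- model$enc[[l]]
    dy <- e$pool$bwd(e$drop$bwd(dy))
    dy <- e$block$bwd(dy + dskips[[l]])
  }
  invisible(dy)
}

#' Predict probability maps for a batch of images
#'
#' Runs the model in evaluation mode (batch norm uses running statistics,
#' dropout disabled), so predictions are deterministic and independent of
#' batch composition.
#'
#' @param model a `watunet_model`.
#' @param images an (H, W, 1, N) array, an (H, W) matrix, or a list of
#'   (H, W) matrices of inputs scaled to `[0, 1]`.
#' @return an (H, W, 1, N) array of probabilities in (0, 1).
#' @export
model_predict <- function(model, images) {
  x <- .as_input_batch(images)
  model_forward(model, x, training = FALSE)
}

.as_input_batch <- function(images) {
  if (is.list(images)) {
    d <- dim(images[[1]])
    x <- array(0, c(d[1], d[2], 1, length(images)))
    for (i in seq_along(images)) x[, , 1, i] <- images[[i]]
    return(x)
  }
  if (is.matrix(images)) return(array(images, c(dim(images), 1L, 1L)))
  if (length(dim(images)) == 4L) return(images)
  stop("images must be a matrix, a list of matrices, or an (H,W,1,N) array")
}

#' Produce the skip tensor for one decoder level
#'
#' The four skip-connection variants shared by the model family: `plain`
#' passes the encoder feature through unchanged; `sharpen` convolves each
#' channel with the fixed 3x3 Laplacian sharpening kernel; `attention`
#' applies an additive attention gate using the upsampled decoder feature
#' as gating signal; `watunet` concatenates the wavelet-gate output (gated
#' LL + LH + HL, upsampled) with the attention-gate output, so its channel
#' count is 4x the encoder feature's.
#'
#' @param mode skip mode string.
#' @param x_enc encoder feature map (height x width x channels array).
#' @param decoder_state a list with `d_up` (decoder feature upsampled to the
#'   resolution of `x_enc`) and, for `watunet`, `d_coarse` (the coarse
#'   decoder feature at half resolution).
#' @param params gate parameters: [attention_gate_params()] for
#'   `attention`; a list with elements `ag` and `wg` for `watunet`.
#' @return the skip feature map.
#' @export
skip_tensor <- function(mode, x_enc, decoder_state = NULL, params = NULL) {
  if (!mode %in% c("plain", "attention", "sharpen", "watunet"))
    stop("unknown skip mode: ", mode)
  switch(mode,
    plain = x_enc,
    sharpen = sharpen_filter(x_enc),
    attention = attention_gate(x_enc, decoder_state$d_up, params),
    watunet = {
      wg_out <- wavelet_gate(x_enc, decoder_state$d_coarse, params$wg)
      ag_out <- attention_gate(x_enc, decoder_state$d_up, params$ag)
      x3 <- .as_hwcn(x_enc); n3 <- length(dim(x_enc)) == 3L || is.matrix(x_enc)
      out <- .cat_channels(list(.as_hwcn(wg_out), .as_hwcn(ag_out)))
      if (n3) array(out, dim(out)[1:3]) else out
    })
}
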