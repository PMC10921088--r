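# End-to-end orchestration: dataset splitting, the training loop with Adam
# and best-model selection by validation Dice, evaluation, and the
# multi-model comparison experiment.

#' Split specification
#'
#' @param train_frac,val_frac,test_frac fractions summing to 1 (default
#'   80:10:10).
#' @param stratify_by_class stratify the split by class label.
#' @param seed integer seed for the shuffle.
#' @return a `split_spec` list.
#' @export
split_spec <- function(train_frac = 0.8, val_frac = 0.1, test_frac = 0.1,
                       stratify_by_class = TRUE, seed = 1L) {
  if (abs(train_frac + val_frac + test_frac - 1) > 1e-9)
    stop("split fractions must sum to 1")
  structure(list(train_frac = train_frac, val_frac = val_frac,
                 test_frac = test_frac,
                 stratify_by_class = stratify_by_class,
                 seed = as.integer(seed)),
            class = "split_spec")
}

# target sizes: floor(frac * n) for val and test (at least 1 when the
# fraction is positive), remainder to train; reproduces 3818 -> 3056/381/381
.split_sizes <- function(n, spec) {
  nv <- if (spec$val_frac > 0) max(1L, floor(spec$val_frac * n)) else 0L
  nt <- if (spec$test_frac > 0) max(1L, floor(spec$test_frac * n)) else 0L
  ntr <- n - nv - nt
  if (ntr < 1 || (spec$train_frac > 0 && ntr < 1))
    stop("split would leave an empty training set (n = ", n, ")")
  c(train = ntr, val = nv, test = nt)
}

#' Split a dataset manifest into train/validation/test
#'
#' Validation and test receive `floor(frac * n)` samples each (never less
#' than one for a positive fraction) and the remainder goes to training;
#' assignment follows a seeded shuffle, optionally stratified by class so
#' each split mirrors the class mix.
#'
#' @param manifest data.frame with one row per sample (a `label` column is
#'   required for stratification).
#' @param spec a [split_spec()].
#' @return list of three manifests (`train`, `val`, `test`), each carrying
#'   the original row indices in column `.row`.
#' @export
split_dataset <- function(manifest, spec = split_spec()) {
  n <- nrow(manifest)
  if (is.null(n) || n < 1) stop("manifest is empty")
  sizes <- .split_sizes(n, spec)
  set.seed(spec$seed)
  assign_ <- character(n)
  if (spec$stratify_by_class && !is.null(manifest$label)) {
    labels <- manifest$label
    classes <- unique(labels)
    cn <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
    pick <- function(target, cap) {
      share <- target * cn / n
      base <- pmin(floor(share), cap)
      short <- target - sum(base)
      if (short > 0) {
        o <- order(share - base, decreasing = TRUE)
        for (i in o) {
          if (short == 0) break
          if (base[i] < cap[i]) { base[i] <- base[i] + 1; short <- short - 1 }
        }
      }
      base
    }
    nv_c <- pick(sizes["val"], cn)
    nt_c <- pick(sizes["test"], cn - nv_c)
    for (ci in seq_along(classes)) {
      idx <- which(labels == classes[ci])
      idx <- idx[sample.int(length(idx))]
      v <- idx[seq_len(nv_c[ci])]
      t_ <- idx[nv_c[ci] + seq_len(nt_c[ci])]
      assign_[v] <- "val"; assign_[t_] <- "test"
      assign_[setdiff(idx, c(v, t_))] <- "train"
    }
  } else {
    idx <- sample.int(n)
    assign_[idx[seq_len(sizes["val"])]] <- "val"
    assign_[idx[sizes["val"] + seq_len(sizes["test"])]] <- "test"
    assign_[assign_ == ""] <- "train"
  }
  out <- lapply(c(train = "train", val = "val", test = "test"), function(s) {
    m <- manifest[assign_ == s, , drop = FALSE]
    m$.row <- which(assign_ == s)
    m
  })
  if (any(vapply(out, nrow, numeric(1)) == 0))
    stop("split left an empty subset; use more samples or larger fractions")
  out
}

#' Training configuration
#'
#' Defaults follow the published protocol: Adam with learning rate 0.001,
#' beta1 = 0.9, beta2 = 0.9, epsilon = 1e-7; batch size 32; 300 epochs;
#' shuffling on; best model selected by validation Dice coefficient.
#'
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters.
#' @param shuffle reshuffle the training set every epoch.
#' @param seed integer seed covering shuffling and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 300L, batch_size = 32L,
                         learning_rate = 0.001, beta1 = 0.9, beta2 = 0.9,
                         epsilon = 1e-7, shuffle = TRUE, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, shuffle = isTRUE(shuffle),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Assemble preprocessed samples into network input arrays
#'
#' Optionally applies CLAHE (on the 8-bit image at native resolution),
#' resizes image and mask to `target`, and stacks them into the
#' (H, W, 1, N) arrays the network consumes, with images in `[0, 1]`.
#'
#' @param samples list of `phantom_sample` objects.
#' @param target `c(H, W)`; defaults to the native sample size.
#' @param clahe `NULL` to skip enhancement, or a [clahe_params()].
#' @return list with arrays `x` (images) and `y` (masks) and the `labels`.
#' @export
samples_to_batch <- function(samples, target = NULL, clahe = NULL) {
  stopifnot(length(samples) >= 1)
  if (is.null(target)) target <- dim(samples[[1]]$image)
  n <- length(samples)
  x <- array(0, c(target[1], target[2], 1, n))
  y <- array(0, c(target[1], target[2], 1, n))
  for (i in seq_len(n)) {
    img <- samples[[i]]$image
    top <- max(img)
    if (top <= 1) img <- img * 255   # tolerate already-normalized input
    if (!is.null(clahe)) img <- clahe_enhance(img, clahe)
    rn <- resize_normalize(img, samples[[i]]$mask, target)
    x[, , 1, i] <- rn$image
    y[, , 1, i] <- rn$mask
  }
  list(x = x, y = y,
       labels = vapply(samples, function(s) s$label, character(1)))
}

# chunked eval-mode forward pass (bounds peak memory)
.predict_chunked <- function(model, x, chunk = 32L) {
  n <- dim(x)[4]
  out <- array(0, dim(x))
  at <- 1L
  while (at <= n) {
    take <- seq(at, min(at + chunk - 1L, n))
    out[, , 1, take] <- model_forward(model, x[, , 1, take, drop = FALSE],
                                      training = FALSE)
    at <- at + chunk
  }
  out
}

.metrics_row <- function(prob, gt, threshold = 0.4) {
  m <- compute_metrics(prob, gt, threshold)
  m[, c("accuracy", "loss", "dice_loss", "precision", "f1", "sensitivity",
        "specificity", "dice_coefficient")]
}

#' Train a segmentation model
#'
#' Minibatch training with Adam on the combined BCE + Dice loss. After
#' every epoch the model is evaluated on the validation set and the
#' parameter state achieving the highest validation Dice coefficient is
#' kept; the returned model carries that best state. The per-epoch history
#' tracks all eight monitored quantities (accuracy, loss, Dice loss, Dice
#' coefficient, sensitivity, specificity, F1, precision) on both splits.
#'
#' @param model a `watunet_model` (modified in place).
#' @param train_data,val_data lists with arrays `x` and `y` as produced by
#'   [samples_to_batch()].
#' @param config a [train_config()].
#' @param threshold binarization threshold for the monitored metrics.
#' @param verbose print one line per epoch.
#' @return list with `model`, `history` (data.frame, one row per epoch and
#'   split), `best_epoch` and `best_val_dice`.
#' @export
train_model <- function(model, train_data, val_data,
                        config = train_config(), threshold = 0.4,
                        verbose = FALSE) {
  set.seed(config$seed)
  n <- dim(train_data$x)[4]
  opt <- new_adam(model$layers, lr = config$learning_rate,
                  beta1 = config$beta1, beta2 = config$beta2,
                  eps = config$epsilon)
  history <- list()
  best <- list(dice = -Inf, epoch = 0L, state = NULL)
  for (epoch in seq_len(config$epochs)) {
    idx <- if (config$shuffle) sample.int(n) else seq_len(n)
    tr_prob <- array(0, dim(train_data$x))
    at <- 1L
    while (at <= n) {
      take <- idx[seq(at, min(at + config$batch_size - 1L, n))]
      xb <- train_data$x[, , 1, take, drop = FALSE]
      yb <- train_data$y[, , 1, take, drop = FALSE]
      p <- model_forward(model, xb, training = TRUE)
      loss <- combined_loss(p, yb)
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d, batch starting %d",
                     epoch, at))
      model_backward(model, .combined_loss_grad(p, yb))
      opt$step()
      tr_prob[, , 1, take] <- p
      at <- at + config$batch_size
    }
    tr <- .metrics_row(tr_prob, train_data$y, threshold)
    va_prob <- .predict_chunked(model, val_data$x)
    va <- .metrics_row(va_prob, val_data$y, threshold)
    history[[length(history) + 1]] <- cbind(
      data.frame(epoch = epoch, split = "train"), tr)
    history[[length(history) + 1]] <- cbind(
      data.frame(epoch = epoch, split = "val"), va)
    if (isTRUE(va$dice_coefficient > best$dice)) {
      best$dice <- va$dice_coefficient
      best$epoch <- epoch
      best$state <- .layer_state(model$layers)
    }
    if (verbose)
      message(sprintf(
        "epoch %3d  train loss %.4f dice %.4f | val loss %.4f dice %.4f",
        epoch, tr$loss, tr$dice_coefficient, va$loss, va$dice_coefficient))
  }
  if (!is.null(best$state)) .restore_state(model$layers, best$state)
  list(model = model, history = do.call(rbind, history),
       best_epoch = best$epoch, best_val_dice = best$dice)
}

#' Evaluate a trained model on a test set
#'
#' Deterministic evaluation-mode forward pass; metrics are micro-averaged
#' (confusion counts pooled over all test pixels). Per-image metrics and
#' the binarized predicted masks (inputs to the McNemar comparison) are
#' returned as well.
#'
#' @param model a trained `watunet_model`.
#' @param test_data list with arrays `x` and `y`.
#' @param threshold binarization threshold (default 0.4).
#' @return list with `metrics` (one-row data.frame), `per_image`
#'   (data.frame) and `masks` (list of binary matrices).
#' @export
evaluate_model <- function(model, test_data, threshold = 0.4) {
  prob <- .predict_chunked(model, test_data$x)
  n <- dim(prob)[4]
  metrics <- .metrics_row(prob, test_data$y, threshold)
  per_image <- do.call(rbind, lapply(seq_len(n), function(i)
    cbind(data.frame(image = i),
          .metrics_row(prob[, , 1, i], test_data$y[, , 1, i], threshold))))
  masks <- lapply(seq_len(n), function(i)
    binarize(prob[, , 1, i], threshold))
  list(metrics = metrics, per_image = per_image, masks = masks)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the network configuration and every trainable and
#' batch-norm state array; a JSON sidecar (`<path>.json`) records the
#' configuration and build seed for provenance.
#'
#' @param model a `watunet_model`.
#' @param path checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a rebuilt `watunet_model`.
#' @export
save_checkpoint <- function(model, path) {
  cfg <- model$config
  saveRDS(list(config = unclass(cfg), state = .layer_state(model$layers),
               seed = model$seed), path)
  jsonlite::write_json(list(config = unclass(cfg), seed = model$seed),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(network_config, ck$config[setdiff(names(ck$config), NULL)])
  model <- build_model(cfg, seed = 1L)
  .restore_state(model$layers, ck$state)
  model$seed <- ck$seed
  model
}

#' Run a multi-model comparison experiment
#'
#' The full workflow on phantom data: generate a dataset, split it
#' (identically for every variant), train one model per skip mode, evaluate
#' each on the shared test set, and compare all pairs with pixelwise
#' McNemar tests under Benjamini-Hochberg FDR control. Produces a
#' metrics table (one row per model) and a comparison table (one row per
#' model pair, `C(k, 2)` rows for `k` models).
#'
#' @param phantom a [phantom_config()].
#' @param skip_modes character vector of at least two skip modes.
#' @param net a [network_config()] used as template (its `skip_mode` is
#'   overridden per variant).
#' @param train a [train_config()].
#' @param split a [split_spec()].
#' @param clahe `NULL` or [clahe_params()] applied during batch assembly.
#' @param augment `NULL`, or an [augment_params()]: the training split (and
#'   only the training split) is then class-balanced to its largest class
#'   count with augmented copies before batching.
#' @param seed master seed; fans out to data generation, splitting,
#'   initialization, augmentation and shuffling.
#' @param outdir optional directory for CSV outputs (`metrics.csv`,
#'   `comparison.csv`, `history_<mode>.csv`).
#' @param verbose print progress.
#' @return list with `metrics`, `comparison`, `histories`, `evaluations`
#'   and the `split` sizes.
#' @export
run_experiment <- function(phantom, skip_modes = c("watunet", "plain"),
                           net = network_config(
                             depth = 3, base_channels = 8,
                             input_size = phantom$image_size),
                           train = train_config(epochs = 10L,
                                                batch_size = 8L),
                           split = split_spec(),
                           clahe = clahe_params(), augment = NULL,
                           seed = 1L, outdir = NULL, verbose = FALSE) {
  if (length(skip_modes) < 2) stop("need at least two skip modes to compare")
  phantom$seed <- seed
  ds <- generate_dataset(phantom)
  split$seed <- seed + 1L
  parts <- split_dataset(ds$manifest, split)
  subsets <- lapply(parts, function(m) ds$samples[m$.row])
  if (!is.null(augment)) {
    # augmentation touches the training split only
    set.seed(seed + 4L)
    tlab <- vapply(subsets$train, function(s) s$label, character(1))
    subsets$train <- balance_classes(subsets$train, max(table(tlab)),
                                     augment)
  }
  batches <- lapply(subsets, function(s) samples_to_batch(s, clahe = clahe))
  metrics <- list(); histories <- list(); evals <- list()
  for (mode in skip_modes) {
    cfg <- net
    cfg$skip_mode <- mode
    if (mode != "watunet" &&
        any(cfg$input_size %% 2^cfg$depth != 0))
      stop("input size incompatible with depth")
    model <- build_model(cfg, seed = seed + 2L)
    model$seed <- seed + 2L
    tcfg <- train
    tcfg$seed <- seed + 3L
    if (verbose) message("training skip_mode = ", mode)
    fit <- train_model(model, batches$train, batches$val, tcfg,
                       verbose = verbose)
    ev <- evaluate_model(fit$model, batches$test)
    metrics[[mode]] <- cbind(data.frame(model = mode), ev$metrics,
                             best_epoch = fit$best_epoch,
                             best_val_dice = fit$best_val_dice)
    histories[[mode]] <- fit$history
    evals[[mode]] <- ev
  }
  gt <- lapply(seq_len(dim(batches$test$y)[4]), function(i)
    batches$test$y[, , 1, i])
  comparison <- comparison_table(lapply(evals, function(e) e$masks), gt)
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(outdir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(comparison, file.path(outdir, "comparison.csv"),
                     row.names = FALSE)
    for (mode in names(histories))
      utils::write.csv(histories[[mode]],
                       file.path(outdir, paste0("history_", mode, ".csv")),
                       row.names = FALSE)
  }
  list(metrics = metrics, comparison = comparison, histories = histories,
       evaluations = evals,
       split = vapply(parts, nrow, numeric(1)),
       n_train_used = dim(batches$train$x)[4])
}
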