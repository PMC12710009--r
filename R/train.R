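#' Target scaling for yield regression
#'
#' The Huber threshold delta = 0.10 is dimensionless, so yields are
#' z-scored with statistics of the training fold only (mean and the 1/n
#' population SD, the convention under which the two-point fold
#' (2000, 3000) maps to (-1, +1)). Validation folds are always transformed
#' with the training statistics, and all reported metrics are
#' back-transformed to kg/ha.
#'
#' @param y training-fold yields (kg/ha).
#' @return a `target_scaler`: list with `center` and `scale`.
#' @export
target_scaler <- function(y) {
  stopifnot(length(y) >= 2)
  ctr <- mean(y)
  sc <- sqrt(mean((y - ctr)^2))
  if (sc == 0) stop("zero SD: targets are constant, cannot scale", call. = FALSE)
  structure(list(center = ctr, scale = sc), class = "target_scaler")
}

#' @rdname target_scaler
#' @param scaler a `target_scaler`.
#' @export
scaler_transform <- function(scaler, y) (y - scaler$center) / scaler$scale

#' @rdname target_scaler
#' @param s scaled values.
#' @export
scaler_inverse <- function(scaler, s) s * scaler$scale + scaler$center

#' Huber regression loss
#'
#' Batch mean of the piecewise form: `e^2/2` for `|e| <= delta`,
#' `delta*|e| - delta^2/2` beyond; `delta = 0.10` on the scaled-target axis.
#'
#' @param pred,target numeric vectors on the scaled axis.
#' @param delta quadratic/linear threshold.
#' @return scalar loss.
#' @export
huber_loss <- function(pred, target, delta = 0.10) {
  stopifnot(delta > 0, length(pred) == length(target),
            all(is.finite(pred)), all(is.finite(target)))
  e <- abs(pred - target)
  mean(ifelse(e <= delta, e^2 / 2, delta * e - delta^2 / 2))
}

#' @rdname huber_loss
#' @return `huber_grad()`: the analytic gradient with respect to `pred`.
#' @export
huber_grad <- function(pred, target, delta = 0.10) {
  e <- pred - target
  ifelse(abs(e) <= delta, e, delta * sign(e)) / length(e)
}

#' Classification losses
#'
#' Batch-mean negative log likelihood: binary cross entropy on
#' sigmoid-transformed logits (both `y ln f` and `(1-y) ln(1-f)` terms) or
#' multiclass cross entropy on softmax logits. Log arguments are guarded
#' at 1e-12.
#'
#' @param logits binary: numeric vector; multiclass: matrix with one row
#'   per sample and one column per class.
#' @param labels binary: 0/1; multiclass: class indices `0..C-1`.
#' @param mode `"binary"` or `"multiclass"`.
#' @return scalar loss.
#' @export
classification_loss <- function(logits, labels, mode = c("binary", "multiclass")) {
  mode <- match.arg(mode)
  if (mode == "binary") {
    if (!all(labels %in% c(0, 1))) stop("binary labels must be 0/1", call. = FALSE)
    p <- 1 / (1 + exp(-as.vector(logits)))
    -mean(labels * log(pmax(p, 1e-12)) + (1 - labels) * log(pmax(1 - p, 1e-12)))
  } else {
    logits <- as.matrix(logits)
    k <- as.integer(labels)
    if (any(k < 0L | k >= ncol(logits))) {
      stop("label outside class range 0..", ncol(logits) - 1, call. = FALSE)
    }
    p <- softmax_rows(logits)
    -mean(log(pmax(p[cbind(seq_along(k), k + 1L)], 1e-12)))
  }
}

#' @rdname classification_loss
#' @return `classification_grad()`: analytic gradient with respect to the
#'   logits (same shape as `logits`).
#' @export
classification_grad <- function(logits, labels, mode = c("binary", "multiclass")) {
  mode <- match.arg(mode)
  if (mode == "binary") {
    p <- 1 / (1 + exp(-as.vector(logits)))
    (p - labels) / length(labels)
  } else {
    logits <- as.matrix(logits)
    p <- softmax_rows(logits)
    k <- as.integer(labels)
    p[cbind(seq_along(k), k + 1L)] <- p[cbind(seq_along(k), k + 1L)] - 1
    p / length(k)
  }
}

#' Multi-task loss fusion
#'
#' Fixed mode: the weighted sum of per-task losses with weights keyed by
#' task name (never by position). Dynamic mode (homoscedastic-uncertainty
#' weighting): `sum_i exp(-2 s_i)/2 * L_i + s_i` where `s_i = log(sigma_i)`
#' is learnable and initialized to 1.0; tasks with larger uncertainty get
#' smaller weight `1/(2 sigma_i^2)`.
#'
#' @param losses named numeric vector of per-task losses (names among
#'   `yield`, `lodging5`, `lodging2`).
#' @param weights named non-negative weights for fixed mode, or the string
#'   `"dynamic"`.
#' @param log_sigma named log-sigma values for dynamic mode.
#' @return list: `total`, per-task `weights` actually applied, and
#'   `penalty` (dynamic mode's `sum s_i`, else 0).
#' @export
multitask_loss <- function(losses, weights = "dynamic",
                           log_sigma = c(yield = 1, lodging5 = 1, lodging2 = 1)) {
  stopifnot(all(is.finite(losses)))
  bad <- setdiff(names(losses), task_names)
  if (length(bad) > 0L) {
    stop("unknown task name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (identical(weights, "dynamic")) {
    s <- log_sigma[names(losses)]
    w <- exp(-2 * s) / 2
    list(total = sum(w * losses + s), weights = w, penalty = sum(s))
  } else {
    bw <- setdiff(names(weights), task_names)
    if (length(bw) > 0L || is.null(names(weights))) {
      stop("weights must be named by task; unknown: ",
           paste(bw, collapse = ", "), call. = FALSE)
    }
    w <- weights[names(losses)]
    w[is.na(w)] <- 0
    list(total = sum(w * losses), weights = w, penalty = 0)
  }
}

#' @rdname multitask_loss
#' @return `multitask_grad()`: list with `d_loss` (gradient of the total
#'   with respect to each task loss) and, in dynamic mode, `d_log_sigma`.
#' @export
multitask_grad <- function(losses, weights = "dynamic",
                           log_sigma = c(yield = 1, lodging5 = 1, lodging2 = 1)) {
  if (identical(weights, "dynamic")) {
    s <- log_sigma[names(losses)]
    list(d_loss = exp(-2 * s) / 2,
         d_log_sigma = -exp(-2 * s) * losses + 1)
  } else {
    w <- weights[names(losses)]
    w[is.na(w)] <- 0
    list(d_loss = w, d_log_sigma = NULL)
  }
}

#' Learning-rate schedule
#'
#' Cosine decay from `lr0` to `lr_min` over the run (default), or step
#' decay (x0.1 at 50% and 75% of the epochs). Epochs are 1-based;
#' `lr_schedule(1, ...)` is exactly `lr0` and the sequence is
#' non-increasing.
#'
#' @param epoch current epoch (1-based).
#' @param epochs total epochs.
#' @param lr0 initial learning rate.
#' @param schedule `"cosine"` or `"step"`.
#' @param lr_min floor of the cosine schedule.
#' @return learning rate for `epoch`.
#' @export
lr_schedule <- function(epoch, epochs, lr0 = 0.02,
                        schedule = c("cosine", "step"), lr_min = 1e-4) {
  schedule <- match.arg(schedule)
  if (schedule == "cosine") {
    t <- if (epochs > 1) (epoch - 1) / (epochs - 1) else 0
    lr_min + (lr0 - lr_min) * (1 + cos(pi * t)) / 2
  } else {
    lr0 * 0.1^(findInterval((epoch - 1) / epochs, c(0.5, 0.75)))
  }
}

# Build engine targets from a label tibble.
label_targets <- function(labels, scaler) {
  list(y = scaler_transform(scaler, labels$yield),
       y5 = as.integer(labels$class5),
       y2 = as.integer(labels$class2))
}

#' Bundle processed clouds with their labels
#'
#' Builds the training records [soy_fit()] and [cross_validate()] consume:
#' one `list(cloud, label)` per plot, in label-table order.
#' @param clouds list of canopy [plot_cloud()]s sampled to the configured
#'   point count.
#' @param labels label tibble (one row per cloud, same order).
#' @return list of records.
#' @export
entries_from <- function(clouds, labels) {
  stopifnot(length(clouds) == nrow(labels))
  lapply(seq_along(clouds), function(i) {
    list(cloud = clouds[[i]], label = labels[i, ])
  })
}

#' Feature clouds for a set of records
#'
#' Normalizes each record's cloud (ground-referenced conditioning by
#' default, which keeps canopy height in the z channel; see
#' [normalize_cloud()]) and assembles the 13-channel input; when `spec` is
#' given, a fresh augmentation draw is applied first (training use only).
#' @param entries records from [entries_from()].
#' @param spec optional [augment_spec()].
#' @param normalize_mode passed to [normalize_cloud()].
#' @return list of `feature_cloud`s.
#' @export
entry_features <- function(entries, spec = NULL, normalize_mode = "ground") {
  lapply(entries, function(e) {
    cl <- e$cloud
    if (!is.null(spec)) cl <- augment_cloud(cl, spec)
    assemble_feature_cloud(normalize_cloud(cl, mode = normalize_mode))
  })
}

#' Label table of a set of records
#' @param entries records from [entries_from()].
#' @return label tibble, one row per record.
#' @export
entry_labels <- function(entries) {
  dplyr::bind_rows(lapply(entries, function(e) e$label))
}

#' Train a model on processed plot clouds
#'
#' Momentum SGD over shuffled mini-batches with the configured
#' learning-rate decay; no early stopping — the final-epoch model is
#' returned. Training entries are (optionally) re-augmented every epoch
#' (geometry first, then color, with vegetation indices recomputed after
#' the color jitter); the yield scaler is fitted on the training fold only.
#' Fully deterministic for a fixed `config$seed` in single-threaded runs.
#'
#' @param entries training records: list of `list(cloud, label)` where
#'   `cloud` is a canopy [plot_cloud()] already sampled to
#'   `config$n_points` (see [entries_from()], [preprocess_cloud()]).
#' @param config a [run_config()].
#' @param arch an [arch_spec()]; defaults follow `config$model` and
#'   `config$pooling`.
#' @param augment logical: re-draw augmentations each epoch.
#' @param augment_spec_ an [augment_spec()].
#' @param oversample oversample minority five-class grades in the training
#'   entries before each run.
#' @param validation optional validation records (never augmented, never
#'   oversampled; scaled with the training statistics).
#' @param eval_every validate every this many epochs (when `validation`).
#' @param precision engine precision.
#' @param verbose print per-epoch losses.
#' @return a `soy_fit`: list with `model` (trained `soy_model`), `history`
#'   (per-epoch tibble: epoch, lr, loss and per-task losses, optional
#'   validation metrics), `config`.
#' @export
soy_fit <- function(entries, config, arch = NULL, augment = TRUE,
                    augment_spec_ = augment_spec(), oversample = TRUE,
                    validation = NULL, eval_every = 10, precision = "float",
                    verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(arch)) {
    arch <- arch_spec(variant = config$model,
                      pooling = if (config$task == "multitask" &&
                                    config$pooling == "per_task") "per_task"
                                else config$pooling)
  }
  set.seed(derive_seed(config$seed, "init"))
  model <- soy_model(task = config$task, arch = arch,
                     n_points = config$n_points, momentum = config$momentum,
                     weight_decay = config$weight_decay, precision = precision)

  labs <- entry_labels(entries)
  model$scaler <- target_scaler(labs$yield)

  if (oversample) {
    entries <- oversample_minority(entries, spec = augment_spec_,
                                   seed = derive_seed(config$seed, "oversample"))
  }
  n <- length(entries)
  weight_mode <- 0L
  wfixed <- c(1, 1, 1)
  if (config$task == "multitask") {
    if (identical(config$loss_weights, "dynamic")) weight_mode <- 1L
    else wfixed <- unname(config$loss_weights[task_names])
  }

  val_f <- NULL
  if (!is.null(validation)) {
    val_f <- entry_features(validation)
    val_labs <- entry_labels(validation)
  }

  static_f <- if (!augment) entry_features(entries) else NULL
  history <- vector("list", config$epochs)
  set.seed(derive_seed(config$seed, "epochs"))
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_schedule(epoch, config$epochs, config$lr, config$lr_schedule)
    f <- if (augment) entry_features(entries, augment_spec_) else static_f
    ord <- sample.int(n)
    bstarts <- seq(1, n, by = config$batch_size)
    ep <- c(loss = 0, loss_yield = 0, loss_lodging5 = 0, loss_lodging2 = 0)
    for (bs in bstarts) {
      ix <- ord[bs:min(bs + config$batch_size - 1, n)]
      X <- stack_feature_clouds(f[ix], config$n_points)
      tl <- label_targets(entry_labels(entries[ix]), model$scaler)
      r <- eng_train_batch(model$ptr, X, length(ix), tl$y, tl$y5, tl$y2,
                           lr, weight_mode, wfixed, 0.10)
      ep <- ep + unlist(r)[names(ep)] * length(ix)
    }
    row <- tibble::as_tibble(as.list(ep / n))
    row$epoch <- epoch
    row$lr <- lr
    if (!is.null(val_f) &&
        (epoch %% eval_every == 0 || epoch == config$epochs)) {
      pr <- predict(model, val_f)
      if ("yield_pred" %in% names(pr)) {
        row$val_rmse <- sqrt(mean((pr$yield_pred - val_labs$yield)^2))
      }
      if ("class5_pred" %in% names(pr)) {
        row$val_acc5 <- mean(pr$class5_pred == val_labs$class5)
      }
      if ("class2_pred" %in% names(pr)) {
        row$val_acc2 <- mean(pr$class2_pred == val_labs$class2)
      }
    }
    if (!is.finite(row$loss)) {
      stop("training diverged (non-finite loss) at epoch ", epoch, call. = FALSE)
    }
    if (verbose) {
      message(sprintf("epoch %3d  lr %.5f  loss %.4f", epoch, lr, row$loss))
    }
    history[[epoch]] <- row
  }
  # refresh batch-norm running statistics at the final weights (a few
  # forward passes in training mode, no parameter updates), so eval-mode
  # predictions reflect the converged activation distribution
  f <- if (augment) entry_features(entries, augment_spec_) else static_f
  for (pass in 1:8) {
    for (bs in seq(1, n, by = config$batch_size)) {
      ix <- bs:min(bs + config$batch_size - 1, n)
      X <- stack_feature_clouds(f[ix], config$n_points)
      eng_forward(model$ptr, X, length(ix), TRUE)
    }
  }
  structure(list(model = model, history = dplyr::bind_rows(history),
                 config = config),
            class = "soy_fit")
}

#' @export
print.soy_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<soy_fit> %s/%s, %d epochs, final loss %.4f\n",
              x$config$model, x$config$task, nrow(h), h$loss[nrow(h)]))
  invisible(x)
}

#' Stratified k-fold assignment
#'
#' Folds stratified by five-class lodging grade; falls back to plain
#' shuffled folds with a warning when some grade has fewer members than
#' `k`.
#'
#' @param class5 integer class per plot.
#' @param k folds.
#' @param seed integer seed.
#' @return integer fold id (1..k) per plot.
#' @export
make_folds <- function(class5, k = 5, seed = 1L) {
  set.seed(as.integer(seed))
  n <- length(class5)
  fold <- integer(n)
  if (any(table(class5) < k)) {
    warning("a grade has fewer than k members; falling back to unstratified folds")
    fold <- sample(rep_len(seq_len(k), n))
  } else {
    for (cl in unique(class5)) {
      ix <- which(class5 == cl)
      fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
  }
  fold
}

#' k-fold cross-validation with pooled (micro-averaged) predictions
#'
#' Folds are stratified by five-class lodging grade; each plot lands in
#' exactly one validation fold. Oversampling and augmentation apply only
#' inside training folds; validation folds are scored untouched with the
#' training fold's target scaling. Predictions from all validation folds
#' are pooled so metrics are computed once on the pool (micro-averaging).
#'
#' @inheritParams soy_fit
#' @param k number of folds.
#' @return list: `predictions` (pooled tibble, one row per plot, with fold
#'   ids and true labels joined), `fits` (per-fold `soy_fit`s), `folds`.
#' @export
cross_validate <- function(entries, config, k = 5, arch = NULL,
                           augment = TRUE, augment_spec_ = augment_spec(),
                           oversample = TRUE, precision = "float",
                           verbose = FALSE) {
  labs <- entry_labels(entries)
  fold <- make_folds(labs$class5, k, seed = derive_seed(config$seed, "folds"))
  fits <- vector("list", k)
  preds <- vector("list", k)
  for (fk in seq_len(k)) {
    tr <- entries[fold != fk]
    va <- entries[fold == fk]
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("fold", fk))
    fit <- soy_fit(tr, cfg, arch = arch, augment = augment,
                   augment_spec_ = augment_spec_, oversample = oversample,
                   precision = precision, verbose = verbose)
    p <- predict(fit$model, entry_features(va))
    p$fold <- fk
    preds[[fk]] <- p
    fits[[fk]] <- fit
  }
  pooled <- dplyr::bind_rows(preds)
  pooled <- dplyr::left_join(pooled, labs, by = "plot_id")
  list(predictions = pooled, fits = fits, folds = fold)
}
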