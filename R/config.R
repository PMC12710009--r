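#' Run configuration
#'
#' Validated bundle of the knobs a full run needs: downsampling level, task,
#' architecture, pooling, loss weighting, optimizer settings and the master
#' seed. Every field is checked on construction; unknown fields in a YAML
#' file are rejected with a warning so typos cannot silently change a run.
#'
#' @param n_points downsampling level, one of 256, 512, 1024, 2048, 3072, 4096.
#' @param task `"yield"`, `"lodging5"`, `"lodging2"` or `"multitask"`.
#' @param model `"soynet"` or `"soynet_res"`.
#' @param pooling `"max"`, `"mean"`, or `"per_task"` (multi-task: mean pool
#'   feeds the regression head, max pool the classification heads).
#' @param loss_weights named per-task weights (names among `yield`,
#'   `lodging5`, `lodging2`), the string `"dynamic"` for
#'   homoscedastic-uncertainty weighting, or one of the presets
#'   `"weighted1"` (yield 1.0, lodging5 1.0, lodging2 0.1) and
#'   `"weighted2"` (yield 0.89, lodging5 0.10, lodging2 0.01).
#' @param epochs,batch_size,lr,momentum,weight_decay optimizer protocol
#'   (defaults: 200 epochs, batch 25, initial learning rate 0.02, momentum
#'   0.9, weight decay 1e-4).
#' @param lr_schedule `"cosine"` (default) or `"step"`.
#' @param seed master integer seed; all randomness derives from it.
#' @return an object of class `run_config` (a validated named list).
#' @export
run_config <- function(n_points = 512, task = "yield", model = "soynet_res",
                       pooling = "mean", loss_weights = NULL,
                       epochs = 200, batch_size = 25, lr = 0.02,
                       momentum = 0.9, weight_decay = 1e-4,
                       lr_schedule = "cosine", seed = 1L) {
  allowed_n <- c(256, 512, 1024, 2048, 3072, 4096)
  if (!n_points %in% allowed_n) {
    stop("n_points must be one of ", paste(allowed_n, collapse = ", "), call. = FALSE)
  }
  task <- match.arg(task, c("yield", "lodging5", "lodging2", "multitask"))
  model <- match.arg(model, c("soynet", "soynet_res"))
  pooling <- match.arg(pooling, c("max", "mean", "per_task"))
  if (task == "multitask" && is.null(loss_weights)) loss_weights <- "dynamic"
  loss_weights <- normalize_loss_weights(loss_weights)
  for (nm in c("epochs", "batch_size", "lr", "momentum", "weight_decay")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("`", nm, "` must be a single positive number", call. = FALSE)
    }
  }
  lr_schedule <- match.arg(lr_schedule, c("cosine", "step"))
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be an integer", call. = FALSE)
  structure(list(
    n_points = as.integer(n_points), task = task, model = model,
    pooling = pooling, loss_weights = loss_weights,
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    lr = lr, momentum = momentum, weight_decay = weight_decay,
    lr_schedule = lr_schedule, seed = seed
  ), class = "run_config")
}

task_names <- c("yield", "lodging5", "lodging2")

normalize_loss_weights <- function(w) {
  if (is.null(w)) return(NULL)
  if (is.character(w) && length(w) == 1L) {
    return(switch(w,
      dynamic = "dynamic",
      unweighted = c(yield = 1, lodging5 = 1, lodging2 = 1),
      weighted1 = c(yield = 1.0, lodging5 = 1.0, lodging2 = 0.1),
      weighted2 = c(yield = 0.89, lodging5 = 0.10, lodging2 = 0.01),
      stop("unknown loss_weights preset: ", w, call. = FALSE)))
  }
  w <- unlist(w)
  unknown <- setdiff(names(w), task_names)
  if (length(unknown) > 0L) {
    stop("unknown task name(s) in loss_weights: ", paste(unknown, collapse = ", "),
         "; weights are keyed by task name (", paste(task_names, collapse = ", "), ")",
         call. = FALSE)
  }
  if (is.null(names(w)) || any(names(w) == "")) {
    stop("loss_weights must be named by task (never positional)", call. = FALSE)
  }
  if (any(w < 0) || all(w == 0)) {
    stop("loss_weights must be non-negative with at least one positive", call. = FALSE)
  }
  full <- stats::setNames(numeric(length(task_names)), task_names)
  full[names(w)] <- w
  full
}

#' Read a run configuration from YAML
#'
#' Unknown top-level keys are dropped with a warning; known keys are passed
#' to [run_config()] for validation.
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0L) {
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
    y <- y[intersect(names(y), known)]
  }
  do.call(run_config, y)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  lw <- x$loss_weights
  lw_txt <- if (is.null(lw)) "-" else if (identical(lw, "dynamic")) "dynamic" else
    paste(names(lw), lw, sep = "=", collapse = " ")
  cat(sprintf("  task %s | model %s | pooling %s | n_points %d\n",
              x$task, x$model, x$pooling, x$n_points))
  cat(sprintf("  loss_weights %s\n", lw_txt))
  cat(sprintf("  epochs %d | batch %d | lr %g (%s) | momentum %g | wd %g | seed %d\n",
              x$epochs, x$batch_size, x$lr, x$lr_schedule, x$momentum,
              x$weight_decay, x$seed))
  invisible(x)
}

#' Derive a purpose-specific sub-seed from a master seed
#'
#' Deterministic mixing of the master seed with a purpose string, so the
#' generator, fold assignment, initialization and augmentation each get an
#' independent, reproducible stream. The result is always below 2^31.
#' @param seed master integer seed.
#' @param purpose short string naming the consumer.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, purpose) {
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  as.integer((as.numeric(seed) * 48271 + h * 2654435) %% 2147483647)
}
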