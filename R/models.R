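#' Architecture specification
#'
#' Describes a point-cloud network variant. `soynet` is the PointNet-basic
#' design without the T-Net alignment modules: shared per-point MLPs
#' 64-64 then 64-128-1024, max pooling to a 1024-d global feature, and a
#' 512-256 post-pooling MLP. `soynet_res` lifts the input with one CBR
#' block (pointwise dense + batch norm + LeakyReLU) and three residual
#' CBR blocks staged 64-64-128-256 (linear projection on the shortcut when
#' widths change, internal expansion factor `res_k`), pools to a 256-d
#' global feature, and uses a 256-256 post-pooling MLP. All variants end in
#' LeakyReLU + dropout before the task heads (256-1 regression, 256-1
#' binary logit, 256-5 five-class logits).
#'
#' @param variant `"soynet"` or `"soynet_res"`.
#' @param pooling `"max"`, `"mean"`, or `"per_task"` (multi-task only:
#'   mean-pooled features feed the regression head, max-pooled features the
#'   classification heads, through a shared post-pooling MLP).
#' @param res_k expansion multiple of the residual blocks' dimension-raising
#'   MLP.
#' @param dropout dropout rate before the heads.
#' @param leaky_slope negative slope of every LeakyReLU.
#' @return an `arch_spec` list.
#' @export
arch_spec <- function(variant = c("soynet_res", "soynet"),
                      pooling = c("max", "mean", "per_task"),
                      res_k = 2, dropout = 0.6, leaky_slope = 0.01) {
  variant <- match.arg(variant)
  pooling <- match.arg(pooling)
  stopifnot(res_k >= 1, dropout >= 0, dropout < 1, leaky_slope >= 0)
  structure(list(variant = variant, pooling = pooling, res_k = as.integer(res_k),
                 dropout = dropout, leaky_slope = leaky_slope),
            class = "arch_spec")
}

#' Create a point-cloud phenotyping model
#'
#' Instantiates the network with freshly initialized weights (He-scaled
#' normal draws from R's RNG, so `set.seed()` makes initialization
#' reproducible). Inputs are always n x 13 fused feature clouds.
#'
#' @param task `"yield"`, `"lodging5"`, `"lodging2"`, or `"multitask"`
#'   (all three heads on a shared backbone).
#' @param arch an [arch_spec()].
#' @param n_points points per cloud the model is built for.
#' @param momentum,weight_decay optimizer constants compiled into the
#'   engine's update rule.
#' @param precision `"float"` (training speed) or `"double"`.
#' @return an object of class `soy_model`.
#' @export
soy_model <- function(task = c("yield", "lodging5", "lodging2", "multitask"),
                      arch = arch_spec(), n_points = 512,
                      momentum = 0.9, weight_decay = 1e-4,
                      precision = c("float", "double")) {
  task <- match.arg(task)
  precision <- match.arg(precision)
  stopifnot(inherits(arch, "arch_spec"))
  pooling <- arch$pooling
  if (task == "multitask" && pooling != "per_task") {
    # single pooled path is allowed, but per-task pooling is the default MDL
    pooling <- pooling
  }
  if (task != "multitask" && pooling == "per_task") {
    stop("per_task pooling is only meaningful for the multitask model",
         call. = FALSE)
  }
  ptr <- eng_create(arch$variant, task, pooling, as.integer(n_points),
                    arch$res_k, arch$leaky_slope, arch$dropout,
                    momentum, weight_decay, precision)
  structure(list(ptr = ptr, task = task, arch = arch,
                 n_points = as.integer(n_points),
                 momentum = momentum, weight_decay = weight_decay,
                 precision = precision, scaler = NULL),
            class = "soy_model")
}

#' @export
print.soy_model <- function(x, ...) {
  cat(sprintf("<soy_model> %s | %s | pooling %s | n_points %d | %s params\n",
              x$arch$variant, x$task, x$arch$pooling, x$n_points,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#' @param model a `soy_model`.
#' @return parameter count (numeric).
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "soy_model"))
  eng_nparams(model$ptr)
}

#' Learned task uncertainties
#'
#' The per-task `log(sigma)` of the homoscedastic-uncertainty loss
#' (yield, five-class lodging, binary lodging). Meaningful after training a
#' multitask model with dynamic weights; initialized to 1.0.
#' @param model a `soy_model`.
#' @return named numeric vector of log-sigma values.
#' @export
task_log_sigma <- function(model) {
  stopifnot(inherits(model, "soy_model"))
  stats::setNames(as.vector(eng_log_sigma(model$ptr)), task_names)
}

# Stack feature clouds into the (B*n) x 13 engine input.
stack_feature_clouds <- function(fclouds, n_points) {
  xs <- lapply(fclouds, function(fc) {
    stopifnot(inherits(fc, "feature_cloud"))
    if (nrow(fc$x) != n_points) {
      stop("feature cloud ", fc$plot_id, " has ", nrow(fc$x),
           " points; model expects ", n_points, call. = FALSE)
    }
    fc$x
  })
  do.call(rbind, xs)
}

#' Raw network forward pass
#'
#' Evaluation-mode (deterministic) forward unless `training = TRUE`.
#' Yield output is on the model's scaled-target axis.
#'
#' @param model a `soy_model`.
#' @param fclouds a `feature_cloud` or list of them.
#' @param training propagate in training mode (batch statistics, dropout).
#' @return list with the active heads (`yield`, `logits5`, `logit2`) and
#'   the pooled `global_feature` matrix (one row per cloud).
#' @export
model_forward <- function(model, fclouds, training = FALSE) {
  stopifnot(inherits(model, "soy_model"))
  if (inherits(fclouds, "feature_cloud")) fclouds <- list(fclouds)
  X <- stack_feature_clouds(fclouds, model$n_points)
  eng_forward(model$ptr, X, length(fclouds), training)
}

#' Predict phenotypes for feature clouds
#'
#' @param object a trained `soy_model` (with a fitted target scaler for
#'   yield tasks).
#' @param fclouds a `feature_cloud` or list of them.
#' @param batch_size clouds per forward pass.
#' @param ... unused.
#' @return a tibble with one row per cloud: `plot_id`, and per active head
#'   `yield_pred` (kg/ha), class probabilities `p5_0..p5_4` with `class5_pred`,
#'   and `p2` with `class2_pred`.
#' @export
predict.soy_model <- function(object, fclouds, batch_size = 50, ...) {
  if (inherits(fclouds, "feature_cloud")) fclouds <- list(fclouds)
  ids <- vapply(fclouds, function(f) f$plot_id, character(1))
  n <- length(fclouds)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  rows <- lapply(chunks, function(ix) {
    out <- model_forward(object, fclouds[ix], training = FALSE)
    d <- tibble::tibble(plot_id = ids[ix])
    if (!is.null(out$yield)) {
      y <- as.vector(out$yield)
      if (!is.null(object$scaler)) y <- scaler_inverse(object$scaler, y)
      d$yield_pred <- y
    }
    if (!is.null(out$logits5)) {
      p <- softmax_rows(out$logits5)
      colnames(p) <- paste0("p5_", 0:4)
      d <- dplyr::bind_cols(d, tibble::as_tibble(p))
      d$class5_pred <- max.col(p, ties.method = "first") - 1L
    }
    if (!is.null(out$logit2)) {
      d$p2 <- 1 / (1 + exp(-as.vector(out$logit2)))
      d$class2_pred <- as.integer(d$p2 > 0.5)
    }
    d
  })
  dplyr::bind_rows(rows)
}

softmax_rows <- function(L) {
  m <- apply(L, 1, max)
  e <- exp(L - m)
  e / rowSums(e)
}

#' Save / load model weights
#'
#' Weights, batch-norm running statistics, task log-sigmas, the
#' architecture spec and the target scaler are written as an RDS
#' checkpoint; [load_model()] rebuilds the engine and restores them.
#'
#' @param model a `soy_model`.
#' @param path checkpoint path (`.rds`).
#' @return `path` invisibly; `load_model()` returns the restored model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "soy_model"))
  saveRDS(list(params = eng_get_params(model$ptr), task = model$task,
               arch = model$arch, n_points = model$n_points,
               momentum = model$momentum, weight_decay = model$weight_decay,
               precision = model$precision, scaler = model$scaler), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  s <- readRDS(path)
  m <- soy_model(task = s$task, arch = s$arch, n_points = s$n_points,
                 momentum = s$momentum, weight_decay = s$weight_decay,
                 precision = s$precision)
  eng_set_params(m$ptr, s$params)
  m$scaler <- s$scaler
  m
}
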