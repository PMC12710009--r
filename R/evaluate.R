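#' Yield regression metrics
#'
#' RMSE, the agreement statistic `r = 1 - sqrt(SSE/SST)` (dimensionless,
#' at most 1, negative when predictions are worse than the mean —
#' note this is not the Pearson correlation, which is reported alongside
#' as `pearson_r` and never conflated with it), relative RMSE
#' (100 * RMSE / mean of the supplied measured values) and MAPE. Zero
#' measured values are excluded from MAPE with the exclusion count
#' reported.
#'
#' @param y measured yields (kg/ha), length >= 2, not all equal.
#' @param yhat predicted yields (kg/ha).
#' @return a 1-row tibble: `rmse`, `r_eq`, `pearson_r`, `rrmse`, `mape`,
#'   `mape_excluded`, `n`, `mean_y`.
#' @export
regression_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  if (stats::sd(y) == 0) stop("measured values are all equal", call. = FALSE)
  e <- y - yhat
  rmse <- sqrt(mean(e^2))
  sse <- sum(e^2)
  sst <- sum((y - mean(y))^2)
  nz <- y != 0
  tibble::tibble(
    rmse = rmse,
    r_eq = 1 - sqrt(sse / sst),
    pearson_r = if (stats::sd(yhat) > 0) stats::cor(y, yhat) else NA_real_,
    rrmse = 100 * rmse / mean(y),
    mape = 100 * mean(abs(e[nz] / y[nz])),
    mape_excluded = sum(!nz),
    n = length(y),
    mean_y = mean(y)
  )
}

#' Top-k accuracies
#'
#' Fraction of samples whose true class is among the k highest-probability
#' classes, for k = 1..C; probability ties are broken by class index
#' (lower index ranks first).
#'
#' @param labels true class indices `0..C-1`.
#' @param probs matrix of class probabilities, one row per sample.
#' @return named numeric vector `top1..topC` (non-decreasing, `topC` = 1).
#' @export
top_k_accuracy <- function(labels, probs) {
  probs <- as.matrix(probs)
  C <- ncol(probs)
  k <- as.integer(labels)
  ranks <- t(apply(probs, 1, function(p) order(-p, seq_along(p))))
  pos <- vapply(seq_along(k), function(i) which(ranks[i, ] == k[i] + 1L),
                integer(1))
  acc <- vapply(seq_len(C), function(kk) mean(pos <= kk), numeric(1))
  stats::setNames(acc, paste0("top", seq_len(C)))
}

#' Classification metrics (micro-averaged)
#'
#' Confusion matrix plus micro-averaged accuracy/precision/recall/F1 from
#' globally pooled TP/FP/FN counts (for single-label multiclass these four
#' coincide), a per-class precision/recall table, and top-k accuracies
#' when probabilities are supplied. Classes that are never predicted and
#' never true are dropped from the per-class table with a note; the micro
#' metrics are unaffected.
#'
#' @param labels true class indices `0..n_classes-1`.
#' @param predictions predicted class indices; derived from `probs` rows
#'   (argmax, ties to the lower class index) when omitted.
#' @param probs optional probability matrix (rows sum to 1 within 1e-6).
#' @param n_classes number of classes.
#' @return a `classification_report`: list with `confusion` (matrix),
#'   `metrics` (1-row tibble: accuracy, precision, recall, f1, n),
#'   `per_class` (tibble), `top_k` (named vector or NULL),
#'   `dropped_classes`.
#' @export
classification_metrics <- function(labels, predictions = NULL, probs = NULL,
                                   n_classes = 5) {
  k <- as.integer(labels)
  if (any(k < 0L | k >= n_classes)) stop("label outside class range", call. = FALSE)
  if (is.null(predictions)) {
    if (is.null(probs)) stop("need predictions or probs", call. = FALSE)
    probs <- as.matrix(probs)
    if (any(abs(rowSums(probs) - 1) > 1e-6)) {
      stop("probability rows must sum to 1", call. = FALSE)
    }
    predictions <- max.col(probs, ties.method = "first") - 1L
  }
  p <- as.integer(predictions)
  lev <- 0:(n_classes - 1)
  conf <- table(factor(k, levels = lev), factor(p, levels = lev))
  conf <- unclass(conf)
  dimnames(conf) <- list(true = lev, pred = lev)
  tp <- sum(diag(conf)); total <- sum(conf)
  acc <- tp / total
  # pooled micro counts: FP and FN both equal the off-diagonal total
  fp <- total - tp; fn <- total - tp
  prec <- tp / (tp + fp); rec <- tp / (tp + fn)
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  cls_tp <- diag(conf)
  cls_fp <- colSums(conf) - cls_tp
  cls_fn <- rowSums(conf) - cls_tp
  present <- (rowSums(conf) + colSums(conf)) > 0
  per_class <- tibble::tibble(
    class = lev[present],
    precision = ifelse(cls_tp + cls_fp > 0, cls_tp / (cls_tp + cls_fp), NA)[present],
    recall = ifelse(cls_tp + cls_fn > 0, cls_tp / (cls_tp + cls_fn), NA)[present],
    support = rowSums(conf)[present]
  )
  tk <- if (!is.null(probs)) top_k_accuracy(k, probs) else NULL
  structure(list(
    confusion = conf,
    metrics = tibble::tibble(accuracy = acc, precision = prec, recall = rec,
                             f1 = f1, n = total),
    per_class = per_class,
    top_k = tk,
    dropped_classes = lev[!present]
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<classification_report> n=%d  acc %.3f  P %.3f  R %.3f  F1 %.3f\n",
              m$n, m$accuracy, m$precision, m$recall, m$f1))
  if (!is.null(x$top_k)) {
    cat("  top-k:", paste(sprintf("%s=%.3f", names(x$top_k), x$top_k),
                          collapse = "  "), "\n")
  }
  invisible(x)
}

#' Spatial weights from plot centroids
#'
#' k-nearest-neighbour weights (default k = 8), symmetrized by union and
#' row-standardized, or inverse-distance weights with a cutoff. Rows sum
#' to 1 (isolates keep zero rows and are flagged). The construction is
#' recorded so downstream Moran tables are self-describing.
#'
#' @param centroids n x 2 matrix (or tibble with columns x, y) of plot map
#'   coordinates; duplicate centroids are an error.
#' @param scheme `"knn"` or `"idw"`.
#' @param k neighbours for knn.
#' @param cutoff distance cutoff for idw.
#' @param plot_ids optional ids used in error messages and dimnames.
#' @return a `spatial_weights`: list with row-standardized `W`, `scheme`,
#'   parameters, and `isolates`.
#' @export
build_spatial_weights <- function(centroids, scheme = c("knn", "idw"), k = 8,
                                  cutoff = Inf, plot_ids = NULL) {
  scheme <- match.arg(scheme)
  if (is.data.frame(centroids)) centroids <- as.matrix(centroids[, c("x", "y")])
  n <- nrow(centroids)
  if (n < 3) stop("need at least 3 centroids", call. = FALSE)
  if (is.null(plot_ids)) plot_ids <- as.character(seq_len(n))
  dup <- duplicated(centroids) | duplicated(centroids, fromLast = TRUE)
  if (any(dup)) {
    stop("duplicate centroids for plots: ",
         paste(plot_ids[dup], collapse = ", "), call. = FALSE)
  }
  W <- matrix(0, n, n)
  if (scheme == "knn") {
    k <- min(k, n - 1)
    nn <- FNN::get.knn(centroids, k = k)
    for (i in seq_len(n)) W[i, nn$nn.index[i, ]] <- 1
    W <- pmax(W, t(W))  # symmetrize by union
  } else {
    D <- as.matrix(stats::dist(centroids))
    W <- ifelse(D > 0 & D <= cutoff, 1 / D, 0)
  }
  diag(W) <- 0
  rs <- rowSums(W)
  isolates <- which(rs == 0)
  if (length(isolates) > 0) {
    warning("isolate plot(s) with no neighbours: ",
            paste(plot_ids[isolates], collapse = ", "))
  }
  Wstd <- W / ifelse(rs > 0, rs, 1)
  dimnames(Wstd) <- list(plot_ids, plot_ids)
  structure(list(W = Wstd, scheme = scheme,
                 k = if (scheme == "knn") k else NULL,
                 cutoff = if (scheme == "idw") cutoff else NULL,
                 isolates = isolates),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("<spatial_weights> %s%s, n = %d, row-standardized\n", x$scheme,
              if (x$scheme == "knn") paste0(" (k=", x$k, ")") else
                paste0(" (cutoff=", x$cutoff, ")"), nrow(x$W)))
  invisible(x)
}

#' Global Moran's I
#'
#' `I = (n/S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with centred values z
#' and `S0 = sum w_ij`; null expectation `E[I] = -1/(n-1)`; z-score and
#' two-sided p-value under the normality assumption, optionally a
#' permutation (pseudo) p-value from seeded shuffles. Values near 0
#' indicate spatially random residuals.
#'
#' @param values numeric residuals (non-constant, n >= 4).
#' @param weights a [build_spatial_weights()] object or a plain matrix.
#' @param inference `"normal"` or `"permutation"` (which also reports the
#'   normal z-score).
#' @param n_perm permutations.
#' @param seed seed for the shuffles.
#' @return a 1-row tibble (class `moran_result`): `I`, `expected_I`,
#'   `sd_I`, `z`, `p`, `p_perm` (NA unless permutation inference), `n`,
#'   `scheme`.
#' @export
morans_i <- function(values, weights, inference = c("normal", "permutation"),
                     n_perm = 999, seed = 1L) {
  inference <- match.arg(inference)
  scheme <- "matrix"
  if (inherits(weights, "spatial_weights")) {
    scheme <- paste0(weights$scheme,
                     if (!is.null(weights$k)) paste0("-k", weights$k) else "")
    W <- weights$W
  } else {
    W <- as.matrix(weights)
  }
  n <- length(values)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (stats::sd(values) == 0) {
    stop("Moran's I undefined for constant values", call. = FALSE)
  }
  stopifnot(nrow(W) == n, ncol(W) == n)

  moran_stat <- function(z) {
    (n / sum(W)) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
  }
  z <- values - mean(values)
  I <- moran_stat(z)
  EI <- -1 / (n - 1)
  S0 <- sum(W)
  S1 <- sum((W + t(W))^2) / 2
  S2 <- sum((rowSums(W) + colSums(W))^2)
  varI <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - EI^2
  sdI <- sqrt(max(varI, 0))
  zsc <- (I - EI) / sdI
  p <- 2 * stats::pnorm(-abs(zsc))
  p_perm <- NA_real_
  if (inference == "permutation") {
    set.seed(as.integer(seed))
    Iperm <- replicate(n_perm, moran_stat(z[sample.int(n)]))
    p_perm <- (1 + sum(abs(Iperm - EI) >= abs(I - EI))) / (n_perm + 1)
  }
  out <- tibble::tibble(I = I, expected_I = EI, sd_I = sdI, z = zsc, p = p,
                        p_perm = p_perm, n = n, scheme = scheme)
  class(out) <- c("moran_result", class(out))
  out
}

#' Residual spatial-autocorrelation report
#'
#' Computes Global Moran's I on the cross-validated residual of each
#' requested task: signed error (prediction minus measurement) for yield,
#' and the centred misclassification indicator for the classification
#' tasks.
#'
#' @param predictions pooled prediction tibble (see [cross_validate()])
#'   joined with true labels and centroid columns `x`, `y` (as produced by
#'   the pipeline; pass the label table columns if needed).
#' @param tasks subset of `c("yield", "lodging5", "lodging2")` present in
#'   the predictions.
#' @param weights a [build_spatial_weights()] object; built from the
#'   centroids with defaults when omitted.
#' @param ... passed to [morans_i()].
#' @return tibble with one `moran_result` row per task, plus a `task`
#'   column.
#' @export
spatial_report <- function(predictions, tasks = c("yield", "lodging5", "lodging2"),
                           weights = NULL, ...) {
  tasks <- match.arg(tasks, several.ok = TRUE)
  if (is.null(weights)) {
    weights <- build_spatial_weights(predictions[, c("x", "y")],
                                     plot_ids = predictions$plot_id)
  }
  rows <- lapply(tasks, function(tk) {
    res <- switch(tk,
      yield = {
        if (!"yield_pred" %in% names(predictions)) return(NULL)
        predictions$yield_pred - predictions$yield
      },
      lodging5 = {
        if (!"class5_pred" %in% names(predictions)) return(NULL)
        m <- as.numeric(predictions$class5_pred != predictions$class5)
        m - mean(m)
      },
      lodging2 = {
        if (!"class2_pred" %in% names(predictions)) return(NULL)
        m <- as.numeric(predictions$class2_pred != predictions$class2)
        m - mean(m)
      })
    if (is.null(res)) return(NULL)
    out <- morans_i(res, weights, ...)
    out$task <- tk
    out
  })
  dplyr::bind_rows(rows)
}
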