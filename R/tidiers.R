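#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training history of a fit
#' @param x a `soy_fit`.
#' @param ... unused.
#' @return the per-epoch history tibble.
#' @export
tidy.soy_fit <- function(x, ...) x$history

#' One-row summary of a fit
#' @param x a `soy_fit`.
#' @param ... unused.
#' @return tibble: variant, task, pooling, epochs, final training loss,
#'   parameter count.
#' @export
glance.soy_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    variant = x$config$model, task = x$config$task,
    pooling = x$model$arch$pooling, n_points = x$config$n_points,
    epochs = nrow(h), loss = h$loss[nrow(h)],
    n_parameters = n_parameters(x$model)
  )
}

#' Tidy a classification report
#' @param x a `classification_report`.
#' @param ... unused.
#' @return the per-class precision/recall tibble.
#' @export
tidy.classification_report <- function(x, ...) x$per_class

#' One-row summary of a classification report
#' @param x a `classification_report`.
#' @param ... unused.
#' @return the micro-averaged metrics tibble, with top-k columns when
#'   available.
#' @export
glance.classification_report <- function(x, ...) {
  out <- x$metrics
  if (!is.null(x$top_k)) out <- dplyr::bind_cols(out, tibble::as_tibble(as.list(x$top_k)))
  out
}

#' Training-loss curve
#' @param object a `soy_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.soy_fit <- function(object, ...) {
  h <- object$history
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "epoch", y = "training loss",
                  title = sprintf("%s / %s", object$config$model,
                                  object$config$task)) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap
#' @param object a `classification_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.classification_report <- function(object, ...) {
  d <- as.data.frame(as.table(object$confusion))
  names(d) <- c("true", "pred", "count")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pred, y = .data$true,
                                  fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), color = "white") +
    ggplot2::scale_fill_gradient(low = "grey85", high = "steelblue4") +
    ggplot2::labs(x = "predicted class", y = "true class") +
    ggplot2::theme_minimal()
}

#' Top-view rendering of a plot cloud
#'
#' Points in the x-y plane, colored by their RGB values (or by height).
#' @param object a [plot_cloud()].
#' @param color `"rgb"` or `"height"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.plot_cloud <- function(object, color = c("rgb", "height"), ...) {
  color <- match.arg(color)
  d <- as_tibble.plot_cloud(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y))
  if (color == "rgb") {
    p <- p + ggplot2::geom_point(color = grDevices::rgb(d$r, d$g, d$b),
                                 size = 0.3) +
      ggplot2::labs(title = object$plot_id)
  } else {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$z), size = 0.3) +
      ggplot2::scale_color_viridis_c() +
      ggplot2::labs(title = object$plot_id, color = "z (m)")
  }
  p + ggplot2::coord_equal() + ggplot2::theme_minimal()
}

#' Measured-vs-predicted yield plot
#' @param predictions pooled prediction tibble with `yield` and
#'   `yield_pred` columns.
#' @return a ggplot with the 1:1 line.
#' @export
plot_yield_scatter <- function(predictions) {
  ggplot2::ggplot(predictions,
                  ggplot2::aes(x = .data$yield, y = .data$yield_pred)) +
    ggplot2::geom_point(alpha = 0.6, color = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "measured yield (kg/ha)", y = "estimated yield (kg/ha)") +
    ggplot2::theme_minimal()
}
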