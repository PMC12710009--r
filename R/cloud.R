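#' Construct a plot point cloud
#'
#' The raw unit of analysis: one experimental plot's colored canopy point
#' cloud in a local metric frame. Coordinates are metres; colors are
#' reflectance-like values on `[0, 1]` (8-bit inputs are divided by 255 at
#' the file boundary so that vegetation-index algebra is scale-consistent).
#'
#' @param points numeric matrix or data frame with columns x, y, z (metres).
#' @param colors numeric matrix or data frame with columns r, g, b in `[0,1]`.
#' @param plot_id single string identifying the plot.
#' @param centroid_xy length-2 numeric, map coordinate of the plot centre
#'   (metres); used only by the spatial diagnostics.
#' @param height optional numeric vector of per-point heights above the
#'   fitted ground plane (attached by [separate_canopy()]).
#'
#' @return An object of class `plot_cloud`: a list with elements `plot_id`,
#'   `points` (n x 3 matrix), `colors` (n x 3 matrix), `centroid_xy`, and
#'   optionally `height`.
#' @seealso [as_tibble.plot_cloud()], [read_point_cloud()]
#' @export
plot_cloud <- function(points, colors, plot_id = "plot",
                       centroid_xy = c(0, 0), height = NULL) {
  points <- as_xyz_matrix(points, c("x", "y", "z"))
  colors <- as_xyz_matrix(colors, c("r", "g", "b"))
  if (nrow(points) < 1L) stop("a plot_cloud needs at least one point", call. = FALSE)
  if (nrow(colors) != nrow(points)) {
    stop("`points` and `colors` must have the same number of rows", call. = FALSE)
  }
  if (!all(is.finite(points))) stop("point coordinates must be finite", call. = FALSE)
  if (!all(is.finite(colors)) || min(colors) < 0 || max(colors) > 1) {
    stop("colors must be finite and within [0, 1]", call. = FALSE)
  }
  if (!is.character(plot_id) || length(plot_id) != 1L) {
    stop("`plot_id` must be a single string", call. = FALSE)
  }
  centroid_xy <- as.numeric(centroid_xy)
  if (length(centroid_xy) != 2L || !all(is.finite(centroid_xy))) {
    stop("`centroid_xy` must be two finite numbers", call. = FALSE)
  }
  if (!is.null(height)) {
    height <- as.numeric(height)
    if (length(height) != nrow(points)) {
      stop("`height` must have one value per point", call. = FALSE)
    }
  }
  structure(
    list(plot_id = plot_id, points = points, colors = colors,
         centroid_xy = centroid_xy, height = height),
    class = "plot_cloud"
  )
}

as_xyz_matrix <- function(x, nm) {
  if (is.data.frame(x)) {
    miss <- setdiff(nm, names(x))
    if (length(miss) == 0L) x <- x[, nm] else if (ncol(x) == 3L) names(x) <- nm
    x <- as.matrix(x)
  }
  x <- unname(as.matrix(x))
  if (ncol(x) != 3L) stop("expected a 3-column matrix (", paste(nm, collapse = ","), ")", call. = FALSE)
  storage.mode(x) <- "double"
  colnames(x) <- nm
  x
}

#' @export
print.plot_cloud <- function(x, ...) {
  cat("<plot_cloud> ", x$plot_id, ": ", nrow(x$points), " points\n", sep = "")
  rng <- apply(x$points, 2, range)
  cat(sprintf("  extent  x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f] m\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  cat(sprintf("  centroid_xy (%.2f, %.2f)%s\n", x$centroid_xy[1], x$centroid_xy[2],
              if (!is.null(x$height)) "  [heights attached]" else ""))
  invisible(x)
}

#' Number of points in a plot cloud
#' @param cloud a [plot_cloud()].
#' @return integer point count.
#' @export
n_points <- function(cloud) {
  stopifnot(inherits(cloud, "plot_cloud"))
  nrow(cloud$points)
}

#' Tidy view of a plot cloud
#'
#' One row per point with columns `plot_id`, `x`, `y`, `z`, `r`, `g`, `b`
#' (and `height` when attached), so clouds compose with dplyr verbs.
#'
#' @param x a [plot_cloud()].
#' @param ... unused.
#' @return a tibble.
#' @importFrom tibble as_tibble
#' @export
as_tibble.plot_cloud <- function(x, ...) {
  out <- tibble::tibble(
    plot_id = x$plot_id,
    x = x$points[, 1], y = x$points[, 2], z = x$points[, 3],
    r = x$colors[, 1], g = x$colors[, 2], b = x$colors[, 3]
  )
  if (!is.null(x$height)) out$height <- x$height
  out
}

# Rebuild a cloud from a modified copy of its parts, keeping metadata.
cloud_update <- function(cloud, points = NULL, colors = NULL, height = NULL,
                         keep = NULL) {
  pts <- if (is.null(points)) cloud$points else points
  col <- if (is.null(colors)) cloud$colors else colors
  h <- if (is.null(height)) cloud$height else height
  if (!is.null(keep)) {
    pts <- pts[keep, , drop = FALSE]
    col <- col[keep, , drop = FALSE]
    if (!is.null(h)) h <- h[keep]
  }
  plot_cloud(pts, col, plot_id = cloud$plot_id,
             centroid_xy = cloud$centroid_xy, height = h)
}

#' Lodging grade / class-index conversions
#'
#' Field lodging severity is scored on the odd scale {1, 3, 5, 7, 9}
#' (none, mild, moderate, severe, complete). Models index the five classes
#' 0..4; the binary task is 0 for grade 1 (no lodging) and 1 otherwise.
#'
#' @param grade integer vector of grades in {1,3,5,7,9}.
#' @return `grade_to_class5()`: integer class indices 0..4;
#'   `grade_to_class2()`: integers in {0,1}; `class5_to_grade()` inverts.
#' @export
grade_to_class5 <- function(grade) {
  g <- as.integer(grade)
  bad <- !g %in% c(1L, 3L, 5L, 7L, 9L)
  if (any(bad)) {
    stop("invalid lodging grade(s): ", paste(unique(g[bad]), collapse = ", "),
         " (must be one of 1,3,5,7,9)", call. = FALSE)
  }
  (g - 1L) %/% 2L
}

#' @rdname grade_to_class5
#' @export
grade_to_class2 <- function(grade) as.integer(grade_to_class5(grade) > 0L)

#' @rdname grade_to_class5
#' @param class5 integer vector of class indices 0..4.
#' @export
class5_to_grade <- function(class5) {
  k <- as.integer(class5)
  if (any(k < 0L | k > 4L)) stop("class index out of 0..4", call. = FALSE)
  2L * k + 1L
}
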