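#' Statistical outlier removal
#'
#' Drops a point iff its mean distance to its `k_neighbors` nearest
#' neighbours exceeds the global mean of that statistic by more than
#' `std_ratio` standard deviations. Survivor order is preserved and
#' coordinates are untouched (the output is a subset of the input).
#'
#' @param cloud a [plot_cloud()].
#' @param k_neighbors neighbours used for the per-point mean distance.
#' @param std_ratio SD multiplier above the global mean distance.
#' @return the filtered [plot_cloud()].
#' @export
remove_outliers <- function(cloud, k_neighbors = 8, std_ratio = 2.0) {
  stopifnot(inherits(cloud, "plot_cloud"))
  n <- n_points(cloud)
  if (n <= k_neighbors) {
    stop("need more than k_neighbors = ", k_neighbors, " points", call. = FALSE)
  }
  rng <- apply(cloud$points, 2, function(v) diff(range(v)))
  if (all(rng == 0)) {
    warning("degenerate cloud (all points identical); returned unchanged")
    return(cloud)
  }
  nn <- FNN::get.knn(cloud$points, k = k_neighbors)
  md <- rowMeans(nn$nn.dist)
  keep <- md <= mean(md) + std_ratio * stats::sd(md)
  if (!any(keep)) {
    warning("outlier rule removed every point; returned unchanged")
    return(cloud)
  }
  cloud_update(cloud, keep = keep)
}

#' Plane model from RANSAC ground fitting
#'
#' Classic 3-point RANSAC: `max_iters` random triples propose planes, a
#' point is an inlier when its absolute signed distance is at most
#' `dist_thresh`, the candidate with the most inliers wins, and the final
#' plane is a total-least-squares refit on that candidate's inliers. The
#' unit normal is oriented with a positive z component. Deterministic for a
#' given seed.
#'
#' @param cloud a [plot_cloud()] with at least 3 non-collinear points.
#' @param dist_thresh inlier distance threshold (m).
#' @param max_iters number of random candidate planes.
#' @param seed integer seed for the triple draws.
#' @param min_support minimum inlier count for a usable plane.
#' @return an object of class `plane_model`: list with unit `normal`,
#'   offset `d` (plane is `normal . p + d = 0`), logical `inlier_mask` over
#'   the input points (relative to the refit plane), and `inlier_count`.
#' @export
fit_ground_ransac <- function(cloud, dist_thresh = 0.02, max_iters = 500,
                              seed = 1L, min_support = 50) {
  stopifnot(inherits(cloud, "plot_cloud"))
  P <- cloud$points
  n <- nrow(P)
  if (n < 3) stop("need at least 3 points to fit a plane", call. = FALSE)
  set.seed(as.integer(seed))
  idx <- matrix(0L, max_iters, 3)
  for (r in seq_len(max_iters)) idx[r, ] <- sample.int(n, 3L)
  a <- P[idx[, 1], , drop = FALSE]
  u <- P[idx[, 2], , drop = FALSE] - a
  v <- P[idx[, 3], , drop = FALSE] - a
  N <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  nrm <- sqrt(rowSums(N^2))
  ok <- nrm > 1e-12
  if (!any(ok)) stop("no plane found (all samples degenerate)", call. = FALSE)
  N <- N[ok, , drop = FALSE] / nrm[ok]
  d <- -rowSums(N * a[ok, , drop = FALSE])
  # |P n^T + d| <= thresh, counted per candidate
  D <- abs(P %*% t(N) + matrix(d, n, nrow(N), byrow = TRUE))
  counts <- colSums(D <= dist_thresh)
  best <- which.max(counts)
  if (counts[best] < max(3, min_support)) {
    stop("no plane found (best support ", counts[best], " < ",
         max(3, min_support), ")", call. = FALSE)
  }
  inl <- D[, best] <= dist_thresh
  fit <- ls_plane(P[inl, , drop = FALSE])
  mask <- abs(P %*% fit$normal + fit$d) <= dist_thresh
  structure(list(normal = as.vector(fit$normal), d = fit$d,
                 inlier_mask = as.vector(mask),
                 inlier_count = sum(mask)),
            class = "plane_model")
}

# Total-least-squares plane: normal = eigenvector of the covariance with the
# smallest eigenvalue; plane passes through the centroid.
ls_plane <- function(P) {
  ctr <- colMeans(P)
  X <- sweep(P, 2, ctr)
  ev <- eigen(crossprod(X) / nrow(P), symmetric = TRUE)
  nrm <- ev$vectors[, 3]
  if (nrm[3] < 0) nrm <- -nrm
  if (nrm[3] == 0 && (nrm[1] < 0 || (nrm[1] == 0 && nrm[2] < 0))) nrm <- -nrm
  list(normal = nrm, d = -sum(nrm * ctr))
}

#' @export
print.plane_model <- function(x, ...) {
  cat(sprintf("<plane_model> normal (%.4f, %.4f, %.4f), d = %.4f, %d inliers\n",
              x$normal[1], x$normal[2], x$normal[3], x$d, x$inlier_count))
  invisible(x)
}

#' Signed height of points above a plane
#' @param points n x 3 matrix.
#' @param plane a `plane_model`.
#' @return numeric vector of signed distances (positive above the plane).
#' @export
plane_height <- function(points, plane) {
  as.vector(points %*% plane$normal + plane$d)
}

#' Separate the canopy from the ground
#'
#' Keeps points whose signed height above the fitted ground plane exceeds
#' `margin`, and attaches those heights to the cloud for the structure
#' features downstream.
#'
#' @param cloud a [plot_cloud()].
#' @param plane a `plane_model` from [fit_ground_ransac()].
#' @param margin height margin in metres.
#' @return a [plot_cloud()] with `height` attached.
#' @export
separate_canopy <- function(cloud, plane, margin = 0.05) {
  stopifnot(inherits(cloud, "plot_cloud"), inherits(plane, "plane_model"))
  h <- plane_height(cloud$points, plane)
  keep <- h > margin
  if (!any(keep)) {
    stop("no points above the ground plane at margin ", margin,
         " m; try a smaller margin", call. = FALSE)
  }
  out <- cloud_update(cloud, height = h, keep = keep)
  out
}

#' Downsample a cloud to an exact point count
#'
#' Two-stage scheme: a voxel-grid pass keeps one point per occupied voxel
#' (the centroid of its members, with averaged color and height), then the
#' count is adjusted exactly — uniform subsampling without replacement when
#' above `target_n`, resampling with replacement (duplicating existing
#' points) when below. When the initial grid is too coarse to supply at
#' least `target_n / 2` voxels, the voxel size is refined (halved) first.
#' Deterministic given `seed`.
#'
#' @param cloud a [plot_cloud()].
#' @param target_n required output count, one of 256, 512, 1024, 2048,
#'   3072, 4096 in the standard protocol (any positive integer is accepted).
#' @param voxel_size initial voxel edge length (m).
#' @param seed integer seed for the exact-count adjustment.
#' @return a [plot_cloud()] with exactly `target_n` points.
#' @export
sample_to_count <- function(cloud, target_n = 512, voxel_size = 0.01, seed = 1L) {
  stopifnot(inherits(cloud, "plot_cloud"), target_n >= 1)
  vox <- voxel_downsample(cloud, voxel_size)
  for (i in 1:10) {
    if (n_points(vox) >= target_n / 2 || n_points(vox) >= n_points(cloud)) break
    voxel_size <- voxel_size / 2
    vox <- voxel_downsample(cloud, voxel_size)
  }
  m <- n_points(vox)
  set.seed(as.integer(seed))
  if (m > target_n) {
    keep <- sort(sample.int(m, target_n))
    cloud_update(vox, keep = keep)
  } else if (m < target_n) {
    extra <- sample.int(m, target_n - m, replace = TRUE)
    cloud_update(vox, keep = c(seq_len(m), extra))
  } else {
    vox
  }
}

#' Voxel-grid downsampling
#'
#' One output point per occupied voxel: the centroid of the voxel's member
#' points, with averaged colors (and heights, when attached). Voxels are
#' emitted in lexicographic grid order, so the result is deterministic.
#'
#' @inheritParams sample_to_count
#' @param voxel_size voxel edge length (m).
#' @return a [plot_cloud()] with one point per occupied voxel.
#' @export
voxel_downsample <- function(cloud, voxel_size = 0.01) {
  stopifnot(inherits(cloud, "plot_cloud"), voxel_size > 0)
  P <- cloud$points
  lo <- apply(P, 2, min)
  ij <- floor(sweep(P, 2, lo) / voxel_size + 1e-9)
  key <- paste(ij[, 1], ij[, 2], ij[, 3], sep = "_")
  f <- factor(key, levels = sort(unique(key)))
  cnt <- as.vector(table(f))
  M <- cbind(P, cloud$colors, if (!is.null(cloud$height)) cloud$height)
  S <- rowsum(M, f)
  A <- S / cnt
  h <- if (!is.null(cloud$height)) A[, 7] else NULL
  plot_cloud(A[, 1:3, drop = FALSE],
             pmin(pmax(A[, 4:6, drop = FALSE], 0), 1),
             plot_id = cloud$plot_id, centroid_xy = cloud$centroid_xy,
             height = h)
}

#' Normalize a cloud for network input
#'
#' `"unit_ball"` (the default): coordinates are translated to the centroid
#' and scaled by the maximum centroid distance so all points lie in the
#' unit ball — the classic PointNet conditioning. `"ground"`: x and y are
#' centred on the horizontal centroid but z is replaced by the height
#' above the fitted ground plane (falling back to `z - min(z)` when no
#' heights are attached), and everything is scaled by the maximum
#' horizontal radius; this keeps the absolute canopy height — the dominant
#' yield signal — in the z channel instead of re-centring it away, while
#' the fixed plot footprint still bounds the coordinates near the unit
#' ball. Colors and attached heights are untouched; the translation and
#' scale are stored in the `transform` attribute so metric heights remain
#' recoverable.
#'
#' @param cloud a [plot_cloud()].
#' @param mode `"unit_ball"` or `"ground"`.
#' @return a [plot_cloud()] with normalized coordinates and attribute
#'   `transform = list(center, scale, mode)`.
#' @export
normalize_cloud <- function(cloud, mode = c("unit_ball", "ground")) {
  stopifnot(inherits(cloud, "plot_cloud"))
  mode <- match.arg(mode)
  if (mode == "unit_ball") {
    ctr <- colMeans(cloud$points)
    X <- sweep(cloud$points, 2, ctr)
    s <- sqrt(max(rowSums(X^2)))
    if (s == 0) s <- 1
  } else {
    z <- if (!is.null(cloud$height)) cloud$height else
      cloud$points[, 3] - min(cloud$points[, 3])
    ctr <- c(mean(cloud$points[, 1]), mean(cloud$points[, 2]), 0)
    X <- cbind(cloud$points[, 1] - ctr[1], cloud$points[, 2] - ctr[2], z)
    s <- sqrt(max(X[, 1]^2 + X[, 2]^2))
    if (s == 0) s <- 1
  }
  out <- cloud_update(cloud, points = X / s)
  attr(out, "transform") <- list(center = ctr, scale = s, mode = mode)
  out
}

#' Full preprocessing pipeline for one plot
#'
#' Composes outlier removal, RANSAC ground fitting, canopy separation,
#' exact-count downsampling and unit-ball normalization. All randomness
#' derives from `seed`.
#'
#' @param cloud a raw [plot_cloud()].
#' @param target_n output point count.
#' @param k_neighbors,std_ratio see [remove_outliers()].
#' @param dist_thresh,max_iters,min_support see [fit_ground_ransac()].
#' @param margin see [separate_canopy()].
#' @param voxel_size see [sample_to_count()].
#' @param seed master seed for this plot.
#' @return list with `cloud` (processed, normalized, `target_n` points),
#'   `plane` (the fitted `plane_model`), and `qc` (1-row tibble:
#'   points in/out, plane normal z component, inlier fraction).
#' @export
preprocess_cloud <- function(cloud, target_n = 512, k_neighbors = 8,
                             std_ratio = 2.0, dist_thresh = 0.02,
                             max_iters = 500, min_support = 50,
                             margin = 0.05, voxel_size = 0.01, seed = 1L) {
  n_in <- n_points(cloud)
  cl <- remove_outliers(cloud, k_neighbors, std_ratio)
  plane <- fit_ground_ransac(cl, dist_thresh, max_iters,
                             seed = derive_seed(seed, "ransac"),
                             min_support = min_support)
  canopy <- separate_canopy(cl, plane, margin)
  sampled <- sample_to_count(canopy, target_n, voxel_size,
                             seed = derive_seed(seed, "sample"))
  norm <- normalize_cloud(sampled)
  qc <- tibble::tibble(
    plot_id = cloud$plot_id, points_in = n_in,
    points_after_outliers = n_points(cl),
    points_canopy = n_points(canopy), points_out = n_points(norm),
    plane_nz = plane$normal[3],
    ground_inlier_frac = plane$inlier_count / n_points(cl)
  )
  list(cloud = norm, plane = plane, qc = qc)
}
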