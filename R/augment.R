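#' Augmentation specification
#'
#' Magnitudes for the training-time color and geometry augmentations.
#' Geometry is augmented first (Gaussian jitter, rotation about the
#' gravity-aligned z axis), then colors (hue/saturation/value/contrast);
#' vegetation-index channels are recomputed after color jitter so the
#' spectral channels always stay consistent with the stored RGB.
#'
#' @param hue_deg maximum hue shift, degrees (draw is uniform in +/- this).
#' @param sat,val,contrast maximum relative factors; each multiplier is
#'   drawn uniformly from `[1 - m, 1 + m]`.
#' @param sigma Gaussian coordinate jitter SD (m).
#' @param clip absolute clip on each jitter offset (m); must be >= `sigma`.
#' @param axis rotation axis, `"z"` by default (arbitrary axes would
#'   destroy the lodging geometry).
#' @param angle_range rotation angle range in radians, default `[0, 2*pi)`.
#' @return an `augment_spec` list.
#' @export
augment_spec <- function(hue_deg = 18, sat = 0.2, val = 0.2, contrast = 0.2,
                         sigma = 0.01, clip = 0.05, axis = "z",
                         angle_range = c(0, 2 * pi)) {
  stopifnot(hue_deg >= 0, sat >= 0, val >= 0, contrast >= 0,
            sigma >= 0, clip >= sigma, length(angle_range) == 2)
  axis <- match.arg(axis, c("z", "x", "y"))
  structure(list(hue_deg = hue_deg, sat = sat, val = val, contrast = contrast,
                 sigma = sigma, clip = clip, axis = axis,
                 angle_range = angle_range),
            class = "augment_spec")
}

hsv_to_rgb <- function(h, s, v) {
  # h in [0,1); piecewise hexcone conversion, vectorized, full precision
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

#' Color jitter
#'
#' RGB -> HSV, hue rotated by a uniform draw in `+/- hue_deg` degrees,
#' saturation and value scaled by uniform relative factors, then contrast
#' applied on RGB as `c * (x - 0.5) + 0.5`; results clipped to `[0, 1]`.
#' Geometry is untouched. One draw per cloud; pass explicit values to fix
#' the transformation.
#'
#' @param cloud a [plot_cloud()].
#' @param spec an [augment_spec()].
#' @param hue_deg,sat_f,val_f,contrast_f optional fixed draw values
#'   (degrees; multiplicative factors).
#' @return the color-jittered [plot_cloud()].
#' @export
jitter_colors <- function(cloud, spec = augment_spec(), hue_deg = NULL,
                          sat_f = NULL, val_f = NULL, contrast_f = NULL) {
  stopifnot(inherits(cloud, "plot_cloud"), inherits(spec, "augment_spec"))
  if (is.null(hue_deg)) hue_deg <- stats::runif(1, -spec$hue_deg, spec$hue_deg)
  if (is.null(sat_f)) sat_f <- stats::runif(1, 1 - spec$sat, 1 + spec$sat)
  if (is.null(val_f)) val_f <- stats::runif(1, 1 - spec$val, 1 + spec$val)
  if (is.null(contrast_f)) {
    contrast_f <- stats::runif(1, 1 - spec$contrast, 1 + spec$contrast)
  }
  hsv <- grDevices::rgb2hsv(t(cloud$colors), maxColorValue = 1)
  h <- (hsv[1, ] + hue_deg / 360) %% 1
  s <- pmin(pmax(hsv[2, ] * sat_f, 0), 1)
  v <- pmin(pmax(hsv[3, ] * val_f, 0), 1)
  rgb <- hsv_to_rgb(h, s, v)
  rgb <- contrast_f * (rgb - 0.5) + 0.5
  cloud_update(cloud, colors = pmin(pmax(rgb, 0), 1))
}

#' Gaussian coordinate perturbation
#'
#' Adds i.i.d. `N(0, sigma^2)` offsets per coordinate, clipped to
#' `+/- clip`. Colors are untouched.
#'
#' @inheritParams jitter_colors
#' @return the perturbed [plot_cloud()].
#' @export
perturb_points <- function(cloud, spec = augment_spec()) {
  stopifnot(inherits(cloud, "plot_cloud"), inherits(spec, "augment_spec"))
  if (spec$sigma == 0) return(cloud)
  n <- n_points(cloud)
  off <- matrix(stats::rnorm(3 * n, 0, spec$sigma), n, 3)
  off <- pmin(pmax(off, -spec$clip), spec$clip)
  h <- if (!is.null(cloud$height)) cloud$height + off[, 3] else NULL
  cloud_update(cloud, points = cloud$points + off, height = h)
}

#' Random rotation about the configured axis
#'
#' Rotates about the cloud centroid by an angle drawn uniformly from
#' `angle_range` (or a fixed `angle`); pairwise distances are preserved and
#' labels are unchanged by contract.
#'
#' @inheritParams jitter_colors
#' @param angle optional fixed rotation angle in radians.
#' @return the rotated [plot_cloud()].
#' @export
rotate_cloud <- function(cloud, spec = augment_spec(), angle = NULL) {
  stopifnot(inherits(cloud, "plot_cloud"), inherits(spec, "augment_spec"))
  if (is.null(angle)) {
    angle <- stats::runif(1, spec$angle_range[1], spec$angle_range[2])
  }
  ca <- cos(angle); sa <- sin(angle)
  R <- switch(spec$axis,
    z = matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE),
    x = matrix(c(1, 0, 0, 0, ca, -sa, 0, sa, ca), 3, 3, byrow = TRUE),
    y = matrix(c(ca, 0, sa, 0, 1, 0, -sa, 0, ca), 3, 3, byrow = TRUE))
  ctr <- colMeans(cloud$points)
  X <- sweep(cloud$points, 2, ctr)
  cloud_update(cloud, points = X %*% t(R) + matrix(ctr, n_points(cloud), 3,
                                                  byrow = TRUE))
}

#' Apply the full augmentation chain to one cloud
#'
#' Geometry first (perturbation, rotation), then color jitter.
#' @inheritParams jitter_colors
#' @return the augmented [plot_cloud()].
#' @export
augment_cloud <- function(cloud, spec = augment_spec()) {
  cloud |>
    perturb_points(spec) |>
    rotate_cloud(spec) |>
    jitter_colors(spec)
}

#' Oversample minority lodging grades with fresh augmentation
#'
#' Replicates minority-class training samples, applying a fresh
#' augmentation draw to each replicate, until every five-class grade
#' reaches `target_per_class`. Only training folds may be oversampled;
#' calling this on a validation fold is an error by contract.
#'
#' @param entries list of records, each `list(cloud = <plot_cloud>,
#'   label = <1-row label tibble>)` (as produced by the training pipeline).
#' @param target_per_class required per-class count; default the size of
#'   the largest class.
#' @param spec an [augment_spec()] for the replicate draws.
#' @param seed integer seed.
#' @param role must be `"training"`.
#' @return the augmented list of records, original entries first.
#' @export
oversample_minority <- function(entries, target_per_class = NULL,
                                spec = augment_spec(), seed = 1L,
                                role = c("training", "validation")) {
  role <- match.arg(role)
  if (role != "training") {
    stop("oversampling must never touch a validation fold", call. = FALSE)
  }
  cls <- vapply(entries, function(e) e$label$class5, integer(1))
  tab <- table(cls)
  if (is.null(target_per_class)) target_per_class <- max(tab)
  set.seed(as.integer(seed))
  out <- entries
  for (k in names(tab)) {
    need <- target_per_class - tab[[k]]
    if (need <= 0) next
    members <- which(cls == as.integer(k))
    picks <- members[sample.int(length(members), need, replace = TRUE)]
    for (i in picks) {
      e <- entries[[i]]
      out[[length(out) + 1]] <- list(cloud = augment_cloud(e$cloud, spec),
                                     label = e$label)
    }
  }
  out
}
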