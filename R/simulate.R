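#' Parameters for one synthetic soybean plot
#'
#' Describes the generative model for a single three-ridge soybean plot:
#' a noisy ground plane plus per-plant stems whose tilt encodes the lodging
#' grade (tilting reduces apparent canopy height by the cosine of the tilt),
#' ellipsoidal leaf crowns, green-dominant canopy and brown-dominant soil
#' colors, and a linear yield model
#' `yield = beta0 + beta_height * mean_canopy_height + beta_cover * cover -
#' beta_tilt * tilt + N(0, noise_sd)` truncated at zero.
#'
#' @param n_plants plants per plot (split over three ridges).
#' @param plot_extent plot footprint in metres, `c(len_x, len_y)`.
#' @param base_height,height_sd upright stem height distribution (m).
#' @param lodging_grade one of 1, 3, 5, 7, 9.
#' @param tilt_map named map grade -> mean stem tilt from vertical (degrees).
#' @param tilt_jitter_sd per-plant tilt jitter (degrees).
#' @param crown_radius,crown_height crown ellipsoid semi-axes (m).
#' @param points_per_plant canopy points sampled per plant.
#' @param ground_density ground points per square metre.
#' @param ground_noise_sd vertical ground roughness (m).
#' @param canopy_rgb,canopy_rgb_sd,soil_rgb,soil_rgb_sd color model means
#'   and per-channel SDs on `[0,1]`. Defaults give green-dominant canopy
#'   (G > R > B) and brown-dominant soil (R > G > B) with overlapping
#'   channel distributions.
#' @param beta0,beta_height,beta_cover,beta_tilt,noise_sd yield model
#'   coefficients (kg/ha intercept; kg/ha per m; kg/ha per cover fraction;
#'   kg/ha per degree; noise SD in kg/ha).
#' @param seed integer seed (used by [simulate_plot()] when not overridden).
#' @return a `canopy_sim_params` list.
#' @export
canopy_sim_params <- function(n_plants = 60,
                              plot_extent = c(3.1, 1.9),
                              base_height = 0.94, height_sd = 0.12,
                              lodging_grade = 1,
                              tilt_map = c("1" = 5, "3" = 25, "5" = 45,
                                           "7" = 65, "9" = 82),
                              tilt_jitter_sd = 4,
                              crown_radius = 0.15, crown_height = 0.13,
                              points_per_plant = 60,
                              ground_density = 450,
                              ground_noise_sd = 0.012,
                              canopy_rgb = c(0.26, 0.46, 0.16),
                              canopy_rgb_sd = c(0.07, 0.07, 0.05),
                              soil_rgb = c(0.46, 0.36, 0.26),
                              soil_rgb_sd = c(0.06, 0.05, 0.05),
                              beta0 = 1200, beta_height = 1800,
                              beta_cover = 400, beta_tilt = 4,
                              noise_sd = 50, seed = 1L) {
  stopifnot(n_plants >= 1, length(plot_extent) == 2, all(plot_extent > 0),
            height_sd >= 0, tilt_jitter_sd >= 0, ground_noise_sd >= 0,
            all(canopy_rgb_sd >= 0), all(soil_rgb_sd >= 0), noise_sd >= 0,
            points_per_plant >= 1, ground_density > 0)
  if (!lodging_grade %in% c(1, 3, 5, 7, 9)) {
    stop("lodging_grade must be one of 1,3,5,7,9", call. = FALSE)
  }
  if (any(tilt_map < 0) || any(tilt_map >= 90)) {
    stop("tilt_map angles must lie in [0, 90) degrees", call. = FALSE)
  }
  structure(as.list(environment()), class = "canopy_sim_params")
}

#' Simulate one plot's colored point cloud and label
#'
#' Ground points are sampled uniformly over the footprint at `z = 0` plus
#' Gaussian roughness; each plant is a stem tilted by the grade's mean tilt
#' plus per-plant jitter (shared lodging azimuth per plot) topped by an
#' ellipsoidal crown of canopy points. Yield follows the linear model in
#' [canopy_sim_params()], evaluated on the realized mean canopy height,
#' cover fraction and mean tilt, so at `noise_sd = 0` the label equals the
#' deterministic form exactly.
#'
#' @param params a [canopy_sim_params()].
#' @param plot_id plot identifier.
#' @param centroid_xy map coordinate of the plot centre.
#' @param seed overrides `params$seed` when given.
#' @return a list with elements `cloud` (a [plot_cloud()]), `label` (1-row
#'   tibble: `plot_id, yield, lodging_grade, class5, class2, density, x, y`),
#'   and `truth` (list: `is_canopy` mask over cloud rows,
#'   `mean_canopy_height`, `cover`, `tilt`, `yield_det` the noise-free
#'   yield, `plane` the true ground plane `z = 0`).
#' @export
simulate_plot <- function(params = canopy_sim_params(), plot_id = "P001",
                          centroid_xy = c(0, 0), seed = NULL) {
  stopifnot(inherits(params, "canopy_sim_params"))
  set.seed(if (is.null(seed)) params$seed else as.integer(seed))
  p <- params
  ex <- p$plot_extent

  # ground
  n_ground <- max(1L, round(p$ground_density * prod(ex)))
  gx <- stats::runif(n_ground, -ex[1] / 2, ex[1] / 2)
  gy <- stats::runif(n_ground, -ex[2] / 2, ex[2] / 2)
  gz <- stats::rnorm(n_ground, 0, p$ground_noise_sd)
  ground_col <- sample_colors(n_ground, p$soil_rgb, p$soil_rgb_sd)

  # plants on three ridges
  ridge_y <- c(-0.63, 0, 0.63) * ex[2] / 1.9
  per <- ceiling(p$n_plants / 3)
  base_y <- rep(ridge_y, length.out = p$n_plants) +
    stats::rnorm(p$n_plants, 0, 0.03)
  base_x <- stats::runif(p$n_plants, -ex[1] / 2 + 0.1, ex[1] / 2 - 0.1)
  tilt_mean <- unname(p$tilt_map[as.character(p$lodging_grade)])
  tilt <- pmin(89, pmax(0, stats::rnorm(p$n_plants, tilt_mean, p$tilt_jitter_sd)))
  azim0 <- stats::runif(1, 0, 2 * pi)             # lodging direction, shared
  azim <- azim0 + stats::rnorm(p$n_plants, 0, 0.3)
  stem_len <- pmax(0.15, stats::rnorm(p$n_plants, p$base_height, p$height_sd))
  tr <- tilt * pi / 180
  top <- cbind(base_x + stem_len * sin(tr) * cos(azim),
               base_y + stem_len * sin(tr) * sin(azim),
               stem_len * cos(tr))

  m <- p$points_per_plant
  n_canopy <- p$n_plants * m
  idx <- rep(seq_len(p$n_plants), each = m)
  cx <- top[idx, 1] + stats::rnorm(n_canopy, 0, p$crown_radius / 2)
  cy <- top[idx, 2] + stats::rnorm(n_canopy, 0, p$crown_radius / 2)
  cz <- pmax(0.03, top[idx, 3] + stats::rnorm(n_canopy, 0, p$crown_height / 2))
  cx <- pmin(ex[1] / 2, pmax(-ex[1] / 2, cx))
  cy <- pmin(ex[2] / 2, pmax(-ex[2] / 2, cy))
  canopy_col <- sample_colors(n_canopy, p$canopy_rgb, p$canopy_rgb_sd)

  pts <- rbind(cbind(gx, gy, gz), cbind(cx, cy, cz))
  cols <- rbind(ground_col, canopy_col)
  is_canopy <- c(rep(FALSE, n_ground), rep(TRUE, n_canopy))
  cloud <- plot_cloud(pts, cols, plot_id = plot_id, centroid_xy = centroid_xy)

  # realized structure -> yield
  mean_h <- mean(cz)
  cover <- min(1, p$n_plants * pi * p$crown_radius^2 / prod(ex))
  mean_tilt <- mean(tilt)
  yield_det <- p$beta0 + p$beta_height * mean_h + p$beta_cover * cover -
    p$beta_tilt * mean_tilt
  yield <- max(0, yield_det + stats::rnorm(1, 0, p$noise_sd))

  label <- tibble::tibble(
    plot_id = plot_id, yield = yield,
    lodging_grade = as.integer(p$lodging_grade),
    class5 = grade_to_class5(p$lodging_grade),
    class2 = grade_to_class2(p$lodging_grade),
    density = NA_character_,
    x = centroid_xy[1], y = centroid_xy[2]
  )
  truth <- list(is_canopy = is_canopy, mean_canopy_height = mean_h,
                cover = cover, tilt = mean_tilt, yield_det = yield_det,
                plane = c(0, 0, 1, 0))
  list(cloud = cloud, label = label, truth = truth)
}

sample_colors <- function(n, mean_rgb, sd_rgb) {
  m <- cbind(stats::rnorm(n, mean_rgb[1], sd_rgb[1]),
             stats::rnorm(n, mean_rgb[2], sd_rgb[2]),
             stats::rnorm(n, mean_rgb[3], sd_rgb[3]))
  pmin(pmax(m, 0), 1)
}

#' Parameters for a synthetic field of plots
#'
#' Lays plots on a `rows x cols` grid and draws per-plot canopy parameters:
#' lodging grade from `grade_probs`, planting-density code (D1/D2/D3, which
#' scales plant count), and per-plot stem height. Optionally adds a smooth
#' Gaussian-random-field yield effect across the grid (squared-exponential
#' covariance) to emulate spatially structured soil/management variation.
#'
#' @param rows,cols grid shape; `rows * cols` plots.
#' @param spacing centre-to-centre plot spacing in metres `c(dx, dy)`.
#' @param base a [canopy_sim_params()] used as the template for every plot.
#' @param grade_probs probabilities for grades 1,3,5,7,9 (default uniform so
#'   every class is exercised; pass an imbalanced vector to emulate a real
#'   field).
#' @param density_probs probabilities for density codes D1, D2, D3.
#' @param spatial_effect `"none"` or `"gaussian_random_field"`.
#' @param spatial_range correlation length of the field (m).
#' @param spatial_sd SD of the additive yield effect (kg/ha).
#' @param seed master seed.
#' @return a `field_sim_params` list.
#' @export
field_sim_params <- function(rows = 6, cols = 10, spacing = c(3.6, 2.4),
                             base = canopy_sim_params(),
                             grade_probs = rep(0.2, 5),
                             density_probs = c(1, 1, 1) / 3,
                             spatial_effect = c("none", "gaussian_random_field"),
                             spatial_range = 8, spatial_sd = 150,
                             seed = 1L) {
  spatial_effect <- match.arg(spatial_effect)
  stopifnot(rows >= 1, cols >= 1, length(spacing) == 2, all(spacing > 0),
            length(grade_probs) == 5, all(grade_probs >= 0), sum(grade_probs) > 0,
            spatial_range > 0, spatial_sd >= 0)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 spacing = spacing, base = base,
                 grade_probs = grade_probs / sum(grade_probs),
                 density_probs = density_probs / sum(density_probs),
                 spatial_effect = spatial_effect,
                 spatial_range = spatial_range, spatial_sd = spatial_sd,
                 seed = as.integer(seed)),
            class = "field_sim_params")
}

#' Simulate a field of plots
#'
#' @param params a [field_sim_params()].
#' @return list with `clouds` (list of [plot_cloud()]), `labels` (tibble,
#'   one row per plot, in grid order), and `truth` (tibble with the per-plot
#'   generative quantities: deterministic yield, realized structure, and the
#'   injected `spatial` effect, zero when `spatial_effect = "none"`).
#' @export
simulate_field <- function(params = field_sim_params()) {
  stopifnot(inherits(params, "field_sim_params"))
  set.seed(params$seed)
  n <- params$rows * params$cols
  gi <- rep(seq_len(params$rows), each = params$cols)
  gj <- rep(seq_len(params$cols), times = params$rows)
  cx <- (gj - 1) * params$spacing[1]
  cy <- (gi - 1) * params$spacing[2]

  grades <- sample(c(1L, 3L, 5L, 7L, 9L), n, replace = TRUE,
                   prob = params$grade_probs)
  dens <- sample(c("D1", "D2", "D3"), n, replace = TRUE,
                 prob = params$density_probs)
  dens_mult <- c(D1 = 0.8, D2 = 1.0, D3 = 1.25)[dens]
  heights <- stats::rnorm(n, params$base$base_height, 0.05)
  plot_seeds <- sample.int(2147483646L, n)

  spatial <- rep(0, n)
  if (params$spatial_effect == "gaussian_random_field") {
    spatial <- gaussian_random_field(cbind(cx, cy), params$spatial_range,
                                     params$spatial_sd)
  }

  clouds <- vector("list", n)
  labels <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    p <- params$base
    p$lodging_grade <- grades[i]
    p$n_plants <- max(3L, round(p$n_plants * dens_mult[i]))
    p$base_height <- heights[i]
    sim <- simulate_plot(p, plot_id = sprintf("P%03d", i),
                         centroid_xy = c(cx[i], cy[i]), seed = plot_seeds[i])
    lab <- sim$label
    lab$density <- dens[i]
    lab$yield <- max(0, lab$yield + spatial[i])
    clouds[[i]] <- sim$cloud
    labels[[i]] <- lab
    truths[[i]] <- tibble::tibble(
      plot_id = lab$plot_id, yield_det = sim$truth$yield_det,
      mean_canopy_height = sim$truth$mean_canopy_height,
      cover = sim$truth$cover, tilt = sim$truth$tilt,
      spatial = spatial[i], n_canopy_points = sum(sim$truth$is_canopy)
    )
  }
  list(clouds = clouds,
       labels = dplyr::bind_rows(labels),
       truth = dplyr::bind_rows(truths))
}

# Smooth zero-mean field with squared-exponential covariance, drawn by
# Cholesky factorization (fields here are at most a few hundred plots).
gaussian_random_field <- function(xy, range, sd) {
  n <- nrow(xy)
  if (sd == 0) return(rep(0, n))
  d2 <- as.matrix(stats::dist(xy))^2
  K <- sd^2 * exp(-d2 / (2 * range^2)) + diag(1e-8 * sd^2, n)
  L <- chol(K)
  as.vector(crossprod(L, stats::rnorm(n)))
}
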