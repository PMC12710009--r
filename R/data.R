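#' Reference descriptive statistics of the motivating field campaign
#'
#' Per-trait mean, maximum, minimum and standard deviation measured across
#' the 558-plot soybean breeding trial that motivates the pipeline's
#' defaults (plot footprint, canopy height range, yield scale). The
#' coefficient of variation is not stored; compute it with
#' [cv_percent()] from the mean and SD columns.
#'
#' @return tibble with columns `parameter`, `unit`, `mean`, `max`, `min`,
#'   `sd`.
#' @export
field_reference_stats <- function() {
  tibble::tribble(
    ~parameter, ~unit, ~mean, ~max, ~min, ~sd,
    "canopy_height", "m", 0.94, 1.54, 0.53, 0.14,
    "bottom_pod_height", "m", 0.31, 1.06, 0.09, 0.09,
    "main_stem_nodes", "count", 12.24, 16.80, 7.60, 1.42,
    "branches", "count", 0.14, 2.20, 0.00, 0.31,
    "pods_per_plant", "count", 20.64, 43.40, 9.80, 5.37,
    "grains_per_plant", "count", 46.41, 102.00, 15.80, 12.05,
    "seed_weight_100", "g", 16.69, 21.87, 7.50, 2.32,
    "grain_yield", "kg/ha", 2529.75, 3860.00, 760.00, 467.89
  )
}

#' Coefficient of variation
#'
#' `100 * sd / mean`, the percent CV as reported in field descriptive
#' tables.
#' @param mean,sd trait mean and standard deviation.
#' @return CV in percent.
#' @export
cv_percent <- function(mean, sd) 100 * sd / mean
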