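#' Read a plot label table
#'
#' Reads the per-plot ground-truth CSV: plot id, grain yield (kg/ha),
#' lodging grade on the odd scale {1,3,5,7,9}, optional planting-density
#' code (D1/D2/D3), and plot-centroid map coordinates. Rows are returned in
#' file order with derived class columns attached.
#'
#' @param path CSV path with header columns `plot_id, yield, lodging_grade,
#'   x, y` (optionally `density`).
#' @return a tibble with columns `plot_id`, `yield`, `lodging_grade`,
#'   `class5` (0..4), `class2` (0/1), `density` (or `NA`), `x`, `y`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "yield", "lodging_grade", "x", "y")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    stop("label CSV is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(!d$lodging_grade %in% c(1, 3, 5, 7, 9))
  if (length(bad) > 0L) {
    stop("invalid lodging_grade at row(s) ", paste(bad, collapse = ", "),
         " (must be one of 1,3,5,7,9)", call. = FALSE)
  }
  if (anyDuplicated(d$plot_id)) {
    stop("duplicate plot_id: ",
         paste(unique(d$plot_id[duplicated(d$plot_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(d$yield)) || any(d$yield < 0)) {
    stop("yield must be finite and non-negative", call. = FALSE)
  }
  tibble::tibble(
    plot_id = as.character(d$plot_id),
    yield = as.numeric(d$yield),
    lodging_grade = as.integer(d$lodging_grade),
    class5 = grade_to_class5(d$lodging_grade),
    class2 = grade_to_class2(d$lodging_grade),
    density = if ("density" %in% names(d)) as.character(d$density) else NA_character_,
    x = as.numeric(d$x),
    y = as.numeric(d$y)
  )
}

#' Write a plot label table
#'
#' Inverse of [read_labels()]; writes `plot_id, yield, lodging_grade,
#' density, x, y`.
#' @param labels a tibble as returned by [read_labels()] or
#'   [simulate_field()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  keep <- intersect(c("plot_id", "yield", "lodging_grade", "density", "x", "y"),
                    names(labels))
  utils::write.csv(labels[, keep], path, row.names = FALSE)
  invisible(path)
}
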