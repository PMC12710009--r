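vi_names <- c("EXR", "EXG", "EXGR", "MGRVI", "RGRI", "PPRb", "VARI",
              "WI", "VEG", "CIVE")

# channels 7..13 of the fused model input
vi_model_channels <- c("EXR", "EXG", "EXGR", "MGRVI", "RGRI", "PPRb", "VARI")

feature_channel_names <- c("x", "y", "z", "R", "G", "B", vi_model_channels)

# Sign-preserving denominator guard: |d| + eps with d's sign (zero treated
# as positive), so ratio indices stay finite on degenerate pixels.
guard_denom <- function(d, eps = 1e-8) {
  s <- ifelse(d < 0, -1, 1)
  s * (abs(d) + eps)
}

#' Visible-band vegetation indices
#'
#' Element-wise evaluation of the ten standard RGB vegetation indices on
#' `[0,1]` colors: EXR = 1.4R - G, EXG = 2G - R - B, EXGR = EXG - EXR,
#' MGRVI = (G^2 - R^2)/(G^2 + R^2), RGRI = R/G (the red-green ratio index),
#' PPRb = (G - B)/(G + B), VARI = (G - R)/(G + R - B), WI = (G - B)/(R - G),
#' VEG = G / (R^0.667 B^0.333), CIVE = 0.441R - 0.811G + 0.385B + 18.79.
#' Every ratio denominator is guarded by adding 1e-8 to its absolute value
#' (sign preserved), so outputs are always finite.
#'
#' @param colors n x 3 matrix or data frame of R, G, B in `[0,1]`.
#' @param which character subset of
#'   `c("EXR","EXG","EXGR","MGRVI","RGRI","PPRb","VARI","WI","VEG","CIVE")`.
#' @return a tibble with one column per requested index, n rows.
#' @export
compute_vis <- function(colors, which = vi_names) {
  which <- match.arg(which, vi_names, several.ok = TRUE)
  colors <- as_xyz_matrix(colors, c("r", "g", "b"))
  if (min(colors) < 0 || max(colors) > 1) {
    stop("colors must lie in [0, 1]", call. = FALSE)
  }
  R <- unname(colors[, 1]); G <- unname(colors[, 2]); B <- unname(colors[, 3])
  out <- list()
  exr <- 1.4 * R - G
  exg <- 2 * G - R - B
  for (w in which) {
    out[[w]] <- switch(w,
      EXR = exr,
      EXG = exg,
      EXGR = exg - exr,
      MGRVI = (G^2 - R^2) / guard_denom(G^2 + R^2),
      RGRI = R / guard_denom(G),
      PPRb = (G - B) / guard_denom(G + B),
      VARI = (G - R) / guard_denom(G + R - B),
      WI = (G - B) / guard_denom(R - G),
      VEG = G / guard_denom(R^0.667 * B^0.333),
      CIVE = 0.441 * R - 0.811 * G + 0.385 * B + 18.79)
  }
  tibble::as_tibble(out)
}

#' Assemble the 13-channel fused model input
#'
#' Concatenates, per point, the normalized coordinates, the RGB colors and
#' the seven vegetation-index channels, in the fixed order
#' (x, y, z, R, G, B, EXR, EXG, EXGR, MGRVI, RGRI, PPRb, VARI). This is the
#' data-level fusion of spatial and spectral information the networks
#' consume.
#'
#' @param cloud a normalized [plot_cloud()], already sampled to the
#'   configured point count.
#' @param target_n when given, the cloud's point count is checked against it.
#' @return an object of class `feature_cloud`: list with `plot_id` and `x`,
#'   an n x 13 numeric matrix with the channel names above.
#' @export
assemble_feature_cloud <- function(cloud, target_n = NULL) {
  stopifnot(inherits(cloud, "plot_cloud"))
  if (!is.null(target_n) && n_points(cloud) != target_n) {
    stop("cloud has ", n_points(cloud), " points but target_n = ", target_n,
         call. = FALSE)
  }
  vis <- as.matrix(compute_vis(cloud$colors, vi_model_channels))
  x <- cbind(cloud$points, cloud$colors, vis)
  colnames(x) <- feature_channel_names
  structure(list(plot_id = cloud$plot_id, x = x), class = "feature_cloud")
}

#' @export
print.feature_cloud <- function(x, ...) {
  cat("<feature_cloud> ", x$plot_id, ": ", nrow(x$x), " x ", ncol(x$x),
      " (", paste(colnames(x$x), collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' Otsu threshold
#'
#' Classic histogram-based two-class threshold (maximizes between-class
#' variance) on values scaled to `[0,1]`.
#' @param v numeric vector.
#' @param levels histogram resolution.
#' @return threshold on the original scale, or `NA` if `v` is constant.
#' @export
otsu_threshold <- function(v, levels = 256) {
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(NA_real_)
  u <- (v - lo) / (hi - lo)
  h <- tabulate(pmin(levels, floor(u * levels) + 1L), nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(levels))
  mu_t <- mu[levels]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  lo + (k / levels) * (hi - lo)
}

#' Canopy cover from the CIVE index
#'
#' Computes CIVE per pixel of an RGB image, splits plant from soil with an
#' Otsu threshold on the CIVE histogram (vegetation has low CIVE), and
#' returns the plant-pixel fraction.
#'
#' @param image H x W x 3 numeric array in `[0,1]`, or an n x 3 color
#'   matrix.
#' @return cover fraction in `[0,1]`; 0 with a warning for a constant image.
#' @export
canopy_cover_cive <- function(image) {
  if (length(dim(image)) == 3L) {
    stopifnot(dim(image)[3] == 3L)
    cols <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
                  as.vector(image[, , 3]))
  } else {
    cols <- as.matrix(image)
  }
  if (nrow(cols) == 0L) stop("empty image", call. = FALSE)
  cive <- compute_vis(pmin(pmax(cols, 0), 1), "CIVE")$CIVE
  thr <- otsu_threshold(cive)
  if (is.na(thr)) {
    warning("constant image: no separable classes; cover reported as 0")
    return(0)
  }
  mean(cive < thr)
}

#' Gray-level co-occurrence texture features
#'
#' Symmetric, normalized co-occurrence matrices at distance 1 for the
#' requested angles (averaged), then the six classical statistics:
#' homogeneity, contrast, dissimilarity, entropy (natural log, 0 ln 0 := 0),
#' angular second moment, and correlation.
#'
#' @param gray H x W matrix: either integers in `0..levels-1` or numeric
#'   values (quantized to `levels` over their range).
#' @param levels number of gray levels used for the co-occurrence matrix.
#' @param angles subset of `c(0, 45, 90, 135)` degrees.
#' @return 1-row tibble with columns `HO, CO, DI, EN, SE, COR`.
#' @export
glcm_features <- function(gray, levels = 32, angles = c(0, 45, 90, 135)) {
  gray <- as.matrix(gray)
  stopifnot(all(angles %in% c(0, 45, 90, 135)))
  lo <- min(gray); hi <- max(gray)
  if (hi > lo) {
    q <- pmin(floor((gray - lo) / (hi - lo) * levels), levels - 1L)
  } else {
    q <- matrix(0L, nrow(gray), ncol(gray))
  }
  offsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
                  `135` = c(-1L, -1L))
  H <- nrow(q); W <- ncol(q)
  Pacc <- matrix(0, levels, levels)
  n_used <- 0L
  for (a in as.character(angles)) {
    o <- offsets[[a]]
    r1 <- max(1L, 1L - o[1]):min(H, H - o[1])
    c1 <- max(1L, 1L - o[2]):min(W, W - o[2])
    A <- q[r1, c1, drop = FALSE]
    B <- q[r1 + o[1], c1 + o[2], drop = FALSE]
    tab <- matrix(tabulate(as.vector(A) + levels * as.vector(B) + 1L,
                           nbins = levels * levels), levels, levels)
    tab <- tab + t(tab)                 # symmetric
    Pacc <- Pacc + tab / sum(tab)       # normalize per angle, then average
    n_used <- n_used + 1L
  }
  P <- Pacc / n_used
  i <- row(P); j <- col(P)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  s_i <- sqrt(sum((i - mu_i)^2 * P)); s_j <- sqrt(sum((j - mu_j)^2 * P))
  cor <- if (s_i == 0 || s_j == 0) {
    warning("constant image: GLCM correlation undefined; reported as 1")
    1
  } else {
    sum(P * (i - mu_i) * (j - mu_j)) / (s_i * s_j)
  }
  pn0 <- P[P > 0]
  tibble::tibble(
    HO = sum(P / (1 + abs(i - j))),
    CO = sum(P * (i - j)^2),
    DI = sum(P * abs(i - j)),
    EN = -sum(pn0 * log(pn0)),
    SE = sum(P^2),
    COR = cor
  )
}

#' Canopy structure features from a canopy cloud
#'
#' Height statistics (mean, max, 95% quantile by the linear-interpolation
#' convention), 2-D convex hull area of the horizontal footprint, 3-D
#' convex hull volume, and the density-percentage profile: the fraction of
#' canopy points whose height exceeds `t * max(height)` for each relative
#' threshold `t`.
#'
#' @param cloud a [plot_cloud()] with heights above the fitted ground plane
#'   attached (see [separate_canopy()]); falls back to z coordinates when
#'   heights are absent.
#' @param thresholds relative-height thresholds for the density profile.
#' @return 1-row tibble: `height_mean, height_max, height_q95, hull_area,
#'   hull_volume, density_50, density_40, density_30, density_20,
#'   density_10, density_05`.
#' @export
structure_features <- function(cloud,
                               thresholds = c(0.5, 0.4, 0.3, 0.2, 0.1, 0.05)) {
  stopifnot(inherits(cloud, "plot_cloud"))
  h <- if (!is.null(cloud$height)) cloud$height else cloud$points[, 3]
  hmax <- max(h)
  dens <- vapply(thresholds, function(t) mean(h > t * hmax), numeric(1))
  names(dens) <- paste0("density_", sub("^0\\.", "", sprintf("%.2f", thresholds)))
  out <- tibble::tibble(
    height_mean = mean(h), height_max = hmax,
    height_q95 = unname(stats::quantile(h, 0.95, type = 7)),
    hull_area = convex_hull_area(cloud$points),
    hull_volume = convex_hull_volume(cloud$points)
  )
  dplyr::bind_cols(out, tibble::as_tibble(as.list(dens)))
}

#' Read a single-band raster or RGB image from file
#'
#' Thin reader for the raster inputs of the feature table: TIFF (surface
#' and elevation models; requires the `tiff` package) and PNG (orthophoto
#' crops; requires `png`). Returns a numeric matrix for single-band input
#' or an H x W x 3 array with any alpha channel dropped.
#'
#' @param path `.tif`/`.tiff` or `.png` file.
#' @return matrix or 3-band array.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF rasters requires the 'tiff' package", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    png = {
      if (!requireNamespace("png", quietly = TRUE)) {
        stop("reading PNG images requires the 'png' package", call. = FALSE)
      }
      png::readPNG(path)
    },
    stop("unsupported raster format '.", ext, "'", call. = FALSE))
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L) {
    img <- img[, , 1:3, drop = FALSE]  # drop alpha
  }
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) img <- img[, , 1]
  img
}

#' Mean canopy height from surface-model differencing
#'
#' Mean over the plot mask of `DSM - DEM`, with negative differences
#' clamped to zero before averaging.
#'
#' @param dsm,dem numeric matrices on the same grid (surface and bare-earth
#'   elevation, metres).
#' @param mask optional logical matrix selecting plot pixels (default all).
#' @return mean canopy height in metres.
#' @export
canopy_height_from_dsm <- function(dsm, dem, mask = NULL) {
  dsm <- as.matrix(dsm); dem <- as.matrix(dem)
  if (!identical(dim(dsm), dim(dem))) {
    stop("DSM and DEM grids do not match: ", paste(dim(dsm), collapse = "x"),
         " vs ", paste(dim(dem), collapse = "x"), call. = FALSE)
  }
  diffm <- pmax(dsm - dem, 0)
  if (is.null(mask)) mask <- !is.na(diffm)
  vals <- diffm[mask]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("mask selects no valid pixels", call. = FALSE)
  mean(vals)
}

#' Plot-level statistical feature table
#'
#' The classical per-plot feature row: means of the ten vegetation indices,
#' the six GLCM texture statistics (from the orthophoto crop, when given),
#' DSM - DEM canopy height (when rasters are given), point-height
#' statistics, convex hull area and volume, the density-percentage profile,
#' and CIVE canopy cover.
#'
#' @param cloud a canopy [plot_cloud()] with heights attached.
#' @param image optional H x W x 3 orthophoto crop in `[0,1]` used for the
#'   GLCM texture and CIVE cover; when absent, cover is computed from the
#'   point colors and texture columns are `NA`.
#' @param dsm,dem,mask optional rasters for [canopy_height_from_dsm()].
#' @param glcm_levels gray levels for [glcm_features()].
#' @return 1-row tibble keyed by `plot_id`.
#' @export
plot_features <- function(cloud, image = NULL, dsm = NULL, dem = NULL,
                          mask = NULL, glcm_levels = 32) {
  stopifnot(inherits(cloud, "plot_cloud"))
  vim <- dplyr::summarise_all(compute_vis(cloud$colors), mean)
  names(vim) <- paste0("vi_", tolower(names(vim)))
  tex <- if (!is.null(image)) {
    gray <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
    glcm_features(gray, levels = glcm_levels)
  } else {
    tibble::tibble(HO = NA_real_, CO = NA_real_, DI = NA_real_,
                   EN = NA_real_, SE = NA_real_, COR = NA_real_)
  }
  names(tex) <- paste0("glcm_", tolower(names(tex)))
  ch_dsm <- if (!is.null(dsm) && !is.null(dem)) {
    canopy_height_from_dsm(dsm, dem, mask)
  } else NA_real_
  cover <- canopy_cover_cive(if (!is.null(image)) image else cloud$colors)
  dplyr::bind_cols(
    tibble::tibble(plot_id = cloud$plot_id),
    vim, tex,
    tibble::tibble(canopy_height_dsm = ch_dsm),
    structure_features(cloud),
    tibble::tibble(canopy_cover = cover)
  )
}
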