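test_that("vegetation indices match closed-form values", {
  gray <- compute_vis(matrix(0.5, 1, 3))
  expect_equal(gray$EXG, 0)
  expect_equal(gray$MGRVI, 0)
  expect_equal(gray$VARI, 0)
  expect_equal(gray$EXR, 1.4 * 0.5 - 0.5)

  green <- compute_vis(matrix(c(0, 1, 0), 1),
                       which = c("EXR", "EXG", "EXGR", "MGRVI", "PPRb", "CIVE"))
  expect_equal(green$EXR, -1)
  expect_equal(green$EXG, 2)
  expect_equal(green$EXGR, 3)
  expect_equal(green$MGRVI, 1, tolerance = 1e-6)
  expect_equal(green$PPRb, 1, tolerance = 1e-6)
  expect_equal(green$CIVE, 0.441 * 0 - 0.811 * 1 + 0.385 * 0 + 18.79)
})

test_that("bounded indices stay in [-1,1] and all stay finite", {
  set.seed(2)
  cols <- matrix(runif(3e5), 1e5, 3)
  v <- compute_vis(cols)
  expect_true(all(is.finite(as.matrix(v))))
  expect_true(all(abs(v$MGRVI) <= 1 + 1e-9))
  expect_true(all(abs(v$PPRb) <= 1 + 1e-9))
  # VARI is bounded on vegetation-like pixels (B below both R and G, which
  # keeps the denominator at least |G - R|)
  veg <- cols[, 3] <= pmin(cols[, 1], cols[, 2])
  expect_true(all(abs(v$VARI[veg]) <= 1 + 1e-9))
  # degenerate pixels are absorbed by the guard, not NaN
  v0 <- compute_vis(matrix(0, 2, 3))
  expect_true(all(is.finite(as.matrix(v0))))
})

test_that("feature clouds have the documented 13-channel layout", {
  sim <- simulate_plot(canopy_sim_params(seed = 4))
  pp <- preprocess_cloud(sim$cloud, target_n = 1024, seed = 2)
  fc <- assemble_feature_cloud(pp$cloud, target_n = 1024)
  expect_equal(dim(fc$x), c(1024L, 13L))
  expect_equal(colnames(fc$x),
               c("x", "y", "z", "R", "G", "B", "EXR", "EXG", "EXGR",
                 "MGRVI", "RGRI", "PPRb", "VARI"))
  # EXG channel equals 2G - R - B recomputed independently
  idx <- sample(1024, 100)
  expect_equal(fc$x[idx, "EXG"],
               2 * fc$x[idx, "G"] - fc$x[idx, "R"] - fc$x[idx, "B"],
               tolerance = 1e-12)
  expect_error(assemble_feature_cloud(pp$cloud, target_n = 512), "512")
  # all-gray colors zero the symmetric channels
  grayc <- plot_cloud(pp$cloud$points, matrix(0.5, 1024, 3))
  fg <- assemble_feature_cloud(grayc)
  expect_true(all(fg$x[, c("EXG", "MGRVI", "VARI")] == 0))
})

test_that("plot-level features are invariant to point order", {
  sim <- simulate_plot(canopy_sim_params(seed = 6))
  pp <- preprocess_cloud(sim$cloud, target_n = 256, seed = 3)
  perm <- sample(256)
  shuffled <- plot_cloud(pp$cloud$points[perm, ], pp$cloud$colors[perm, ],
                         plot_id = pp$cloud$plot_id,
                         height = pp$cloud$height[perm])
  f1 <- plot_features(pp$cloud)
  f2 <- plot_features(shuffled)
  expect_equal(f1[, -1], f2[, -1], tolerance = 1e-12)
})

test_that("CIVE canopy cover recovers known masks", {
  set.seed(7)
  H <- 40; W <- 40
  img <- array(0, c(H, W, 3))
  # left half vegetation (green), right half soil (brown), with noise
  for (ch in 1:3) {
    img[, 1:(W / 2), ch] <- pmin(pmax(rnorm(H * W / 2, c(0.22, 0.5, 0.14)[ch], 0.04), 0), 1)
    img[, (W / 2 + 1):W, ch] <- pmin(pmax(rnorm(H * W / 2, c(0.5, 0.37, 0.24)[ch], 0.04), 0), 1)
  }
  expect_equal(canopy_cover_cive(img), 0.5, tolerance = 0.02)
  expect_warning(c0 <- canopy_cover_cive(array(0.4, c(5, 5, 3))), "constant")
  expect_equal(c0, 0)
  cv <- canopy_cover_cive(matrix(runif(300), 100, 3))
  expect_gte(cv, 0); expect_lte(cv, 1)
})

test_that("otsu threshold agrees with the EBImage reference", {
  skip_if_not_installed("EBImage")
  set.seed(3)
  v <- c(rnorm(500, 0.3, 0.05), rnorm(500, 0.7, 0.05))
  v <- pmin(pmax(v, 0), 1)
  ours <- otsu_threshold(v, levels = 256)
  ref <- EBImage::otsu(matrix(v, 50, 20), range = c(0, 1), levels = 256)
  # bin-edge conventions differ slightly; the induced masks must agree
  expect_gte(mean((v < ours) == (v < ref)), 0.99)
})

test_that("GLCM features match hand-enumerated co-occurrences", {
  const <- matrix(3, 6, 6)
  expect_warning(g <- glcm_features(const, levels = 4), "constant")
  expect_equal(g$CO, 0); expect_equal(g$DI, 0)
  expect_equal(g$HO, 1); expect_equal(g$SE, 1)
  expect_equal(g$EN, 0); expect_equal(g$COR, 1)

  # 2-level checkerboard at 0 degrees: every horizontal pair differs by 1 level
  cb <- outer(1:6, 1:6, function(i, j) (i + j) %% 2)
  g2 <- glcm_features(cb, levels = 2, angles = 0)
  expect_equal(g2$CO, 1)
  expect_equal(g2$DI, 1)
  expect_equal(g2$HO, 0.5)

  set.seed(1)
  rnd <- matrix(runif(100), 10, 10)
  g3 <- glcm_features(rnd, levels = 8)
  expect_gte(g3$EN, 0)
  expect_gt(g3$SE, 0); expect_lte(g3$SE, 1)
})

test_that("hull area and volume are exact on known solids", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0), c(0.5, 0.5, 0))
  expect_equal(convex_hull_area(sq), 1)
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(convex_hull_volume(cube), 1)
  tetra <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(convex_hull_volume(tetra), 1 / 6)
  # interior points change nothing
  set.seed(5)
  inside <- matrix(runif(90, 0.1, 0.9), 30, 3)
  expect_equal(convex_hull_volume(rbind(cube, inside)), 1)
  # random clouds: hull of a unit-cube sample approaches 1 from below
  big <- matrix(runif(3000), 1000, 3)
  v <- convex_hull_volume(big)
  expect_gt(v, 0.85); expect_lt(v, 1)
  expect_warning(convex_hull_volume(sq), "coplanar|distinct")
  expect_warning(convex_hull_area(rbind(c(0, 0), c(1, 1), c(2, 2))), "collinear")
})

test_that("structure features follow their closed forms", {
  set.seed(9)
  n <- 10000
  h <- runif(n)
  cl <- plot_cloud(cbind(runif(n), runif(n), h), matrix(0.5, n, 3), height = h)
  sf <- structure_features(cl)
  hmax <- max(h)
  expect_equal(sf$density_50, mean(h > 0.5 * hmax), tolerance = 1e-12)
  expect_equal(sf$density_50, 0.5, tolerance = 0.02)  # closed form 1 - t
  dens <- as.numeric(sf[, paste0("density_", c("50", "40", "30", "20", "10", "05"))])
  expect_true(all(diff(dens) >= 0))  # non-increasing as t increases
  expect_equal(sf$height_q95, unname(quantile(h, 0.95)), tolerance = 1e-12)
})

test_that("DSM - DEM canopy height averages with negatives clamped", {
  dem <- matrix(100, 4, 4)
  expect_equal(canopy_height_from_dsm(dem + 0.5, dem), 0.5)
  expect_equal(canopy_height_from_dsm(dem, dem), 0)
  dsm <- dem; dsm[1:2, ] <- dem[1:2, ] + 1
  expect_equal(canopy_height_from_dsm(dsm, dem), 0.5)
  dsm2 <- dem - 1  # below ground clamps to zero, not -1
  expect_equal(canopy_height_from_dsm(dsm2, dem), 0)
  expect_error(canopy_height_from_dsm(matrix(0, 2, 2), dem), "match")
  mask <- matrix(FALSE, 4, 4)
  expect_error(canopy_height_from_dsm(dem, dem, mask), "no valid")
})

test_that("raster files round-trip into the DSM - DEM workflow", {
  dem <- matrix(runif(64, 99, 101), 8, 8)
  dsm <- dem + 0.8
  fd <- withr::local_tempfile(fileext = ".tif")
  fs <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF((dem - 90) / 20, fd, bits.per.sample = 32)
  tiff::writeTIFF((dsm - 90) / 20, fs, bits.per.sample = 32)
  dem2 <- read_raster(fd) * 20 + 90
  dsm2 <- read_raster(fs) * 20 + 90
  expect_equal(canopy_height_from_dsm(dsm2, dem2), 0.8, tolerance = 1e-4)

  img <- array(runif(48), c(4, 4, 3))
  fp <- withr::local_tempfile(fileext = ".png")
  png::writePNG(img, fp)
  back <- read_raster(fp)
  expect_equal(dim(back), c(4L, 4L, 3L))
  expect_equal(back, img, tolerance = 1 / 255)
  expect_error(read_raster("missing.tif"), "not found")
  f_bad <- withr::local_tempfile(fileext = ".bmp")
  writeLines("x", f_bad)
  expect_error(read_raster(f_bad), "unsupported")
})
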