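test_that("statistical outlier removal matches the brute-force rule", {
  set.seed(8)
  grid <- as.matrix(expand.grid(x = seq(0, 1, 0.1), y = seq(0, 1, 0.1), z = 0))
  pts <- rbind(grid, c(100, 100, 100))
  cl <- plot_cloud(pts, matrix(0.5, nrow(pts), 3))
  out <- remove_outliers(cl, k_neighbors = 8, std_ratio = 2)
  expect_equal(n_points(out), nrow(grid))
  expect_equal(out$points, cl$points[seq_len(nrow(grid)), ])

  # brute-force oracle: mean distance to 8 nearest neighbours
  D <- as.matrix(dist(pts))
  md <- apply(D, 1, function(r) mean(sort(r)[2:9]))  # drop self-distance 0
  keep_oracle <- md <= mean(md) + 2 * sd(md)
  expect_equal(n_points(out), sum(keep_oracle))

  # no-outlier cloud is returned unchanged (identity case, subset contract)
  cl2 <- make_cloud(100, seed = 4)
  out2 <- remove_outliers(cl2, 8, 3)
  expect_true(nrow(out2$points) <= 100)
  expect_true(all(out2$points %in% cl2$points))
})

test_that("RANSAC recovers an exact plane and is seed-deterministic", {
  set.seed(1)
  xy <- matrix(runif(200, -1, 1), 100, 2)
  pts <- cbind(xy, 0.5 + 0.25 * xy[, 1] * 0)  # z = 0.5 plane
  cl <- plot_cloud(rbind(pts, c(0, 0, 2)), matrix(0.5, 101, 3))
  pm <- fit_ground_ransac(cl, dist_thresh = 0.01, max_iters = 100, seed = 2,
                          min_support = 3)
  expect_equal(pm$normal, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(pm$d, -0.5, tolerance = 1e-9)
  expect_true(all(pm$inlier_mask[1:100]))
  expect_false(pm$inlier_mask[101])

  pm2 <- fit_ground_ransac(cl, dist_thresh = 0.01, max_iters = 100, seed = 2,
                           min_support = 3)
  expect_identical(pm, pm2)
})

test_that("RANSAC separates noisy ground from canopy like the LS oracle", {
  set.seed(42)
  ground <- cbind(matrix(runif(1400, -1.5, 1.5), 700, 2),
                  rnorm(700, 0, 0.005))
  canopy <- cbind(matrix(runif(600, -1.5, 1.5), 300, 2),
                  runif(300, 0.3, 1.0))
  cl <- plot_cloud(rbind(ground, canopy), matrix(0.5, 1000, 3))
  pm <- fit_ground_ransac(cl, dist_thresh = 0.02, max_iters = 500, seed = 7)
  # oracle: least-squares plane on the true ground points
  oracle <- soycloud:::ls_plane(ground)
  angle <- acos(min(1, abs(sum(pm$normal * oracle$normal)))) * 180 / pi
  expect_lt(angle, 1)
  expect_gte(mean(pm$inlier_mask[1:700]), 0.95)

  canopy_cl <- separate_canopy(cl, pm, margin = 0.05)
  expect_gte(n_points(canopy_cl), 0.95 * 300)   # recall of true canopy
  expect_lte(n_points(canopy_cl), 300)          # no ground leaks above margin
  expect_true(all(canopy_cl$height > 0.05))
})

test_that("plane recovery error decreases with ground noise", {
  angle_for <- function(noise_sd, seed) {
    set.seed(seed)
    ground <- cbind(matrix(runif(800, -1.5, 1.5), 400, 2),
                    rnorm(400, 0, noise_sd))
    canopy <- cbind(matrix(runif(200, -1.5, 1.5), 100, 2),
                    runif(100, 0.3, 1))
    cl <- plot_cloud(rbind(ground, canopy), matrix(0.5, 500, 3))
    pm <- fit_ground_ransac(cl, dist_thresh = 0.03, max_iters = 200,
                            seed = seed)
    acos(min(1, abs(pm$normal[3]))) * 180 / pi
  }
  mean_angle <- vapply(c(0.002, 0.01, 0.05), function(ns) {
    mean(vapply(1:20, function(s) angle_for(ns, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_angle) > 0))
})

test_that("voxel hashing matches the brute-force grid count", {
  grid <- as.matrix(expand.grid(x = 0:9, y = 0:9, z = 0))
  cl <- plot_cloud(grid, matrix(0.5, 100, 3))
  vox <- voxel_downsample(cl, voxel_size = 2.0)
  # brute force: integer cell ids at size 2
  cells <- unique(floor(sweep(grid, 2, apply(grid, 2, min)) / 2))
  expect_equal(nrow(cells), 25L)
  expect_equal(n_points(vox), 25L)
  # each voxel point is the centroid of its 4 members
  expect_true(all(vox$points[, 1] %in% c(0.5, 2.5, 4.5, 6.5, 8.5)))
})

test_that("sample_to_count hits every standard level exactly", {
  cl <- simulate_plot(canopy_sim_params(seed = 3))$cloud
  for (lvl in c(256, 512, 1024, 2048, 3072, 4096)) {
    out <- sample_to_count(cl, target_n = lvl, seed = 5)
    expect_equal(n_points(out), lvl)
  }
  # padding: every point of an upsampled cloud is a copy of a voxel point
  small <- make_cloud(50, seed = 6)
  up <- sample_to_count(small, target_n = 128, voxel_size = 1e-4, seed = 1)
  expect_equal(n_points(up), 128L)
  expect_true(all(apply(up$points, 1, function(r) {
    any(abs(small$points[, 1] - r[1]) < 1e-12)
  })))
})

test_that("unit-ball normalization is idempotent and similarity-preserving", {
  cl <- make_cloud(80, seed = 9)
  nn <- normalize_cloud(cl)
  expect_equal(max(sqrt(rowSums(nn$points^2))), 1, tolerance = 1e-9)
  n2 <- normalize_cloud(nn)
  expect_equal(n2$points, nn$points, tolerance = 1e-9)
  d0 <- dist(cl$points); d1 <- dist(nn$points)
  expect_equal(as.vector(d1 / d0), rep(1 / attr(nn, "transform")$scale,
                                       length(d0)), tolerance = 1e-9)
  one <- normalize_cloud(plot_cloud(matrix(c(1, 2, 3), 1), matrix(0.5, 1, 3)))
  expect_equal(attr(one, "transform")$scale, 1)
})

test_that("ground-referenced normalization keeps canopy height in z", {
  sim <- simulate_plot(canopy_sim_params(seed = 12))
  pp <- preprocess_cloud(sim$cloud, target_n = 256, seed = 1)
  gn <- normalize_cloud(pp$cloud, mode = "ground")
  s <- attr(gn, "transform")$scale
  expect_equal(gn$points[, 3] * s, pp$cloud$height, tolerance = 1e-9)
  expect_equal(mean(gn$points[, 1]), 0, tolerance = 1e-9)
})

test_that("the preprocessing pipeline is deterministic and well-formed", {
  sim <- simulate_plot(canopy_sim_params(seed = 10))
  a <- preprocess_cloud(sim$cloud, target_n = 512, seed = 33)
  b <- preprocess_cloud(sim$cloud, target_n = 512, seed = 33)
  expect_identical(a$cloud$points, b$cloud$points)
  expect_identical(a$qc, b$qc)
  expect_equal(n_points(a$cloud), 512L)
  expect_true(all(a$cloud$colors >= 0 & a$cloud$colors <= 1))
  expect_gt(a$qc$plane_nz, 0.999)
  # canopy recall against generator truth: ground points sit near z=0
  expect_gt(min(a$cloud$height), 0.05)
})
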