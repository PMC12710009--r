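test_that("regression metrics match hand computations", {
  ident <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$rmse, 0)
  expect_equal(ident$r_eq, 1)
  expect_equal(ident$mape, 0)

  m <- regression_metrics(c(1, 2, 3), c(2, 3, 4))
  expect_equal(m$rmse, 1)
  expect_equal(m$r_eq, 1 - sqrt(3 / 2))   # about -0.2247
  expect_equal(m$pearson_r, 1)            # reported alongside, not conflated
  expect_equal(m$rrmse, 100 * 1 / 2)

  m2 <- regression_metrics(c(100, 200), c(110, 180))
  expect_equal(m2$mape, 10)
  # zero measured values drop out of MAPE with a count
  m3 <- regression_metrics(c(0, 100, 200), c(5, 110, 180))
  expect_equal(m3$mape_excluded, 1L)
  expect_equal(m3$mape, 10)
  expect_error(regression_metrics(c(2, 2), c(1, 3)), "all equal")
})

test_that("micro-averaged identity holds on random confusion data", {
  set.seed(41)
  for (i in 1:1000) {
    n <- sample(10:40, 1)
    C <- sample(2:6, 1)
    labels <- sample(0:(C - 1), n, replace = TRUE)
    preds <- sample(0:(C - 1), n, replace = TRUE)
    r <- classification_metrics(labels, preds, n_classes = C)$metrics
    expect_identical(r$accuracy, r$precision)
    expect_identical(r$accuracy, r$recall)
    expect_equal(r$accuracy, r$f1)
  }
})

test_that("perfect predictions score 1 everywhere", {
  labels <- rep(0:4, 4)
  probs <- diag(5)[labels + 1, ]
  r <- classification_metrics(labels, probs = probs)
  expect_equal(r$metrics$accuracy, 1)
  expect_equal(r$metrics$f1, 1)
  expect_equal(unname(r$top_k["top1"]), 1)
})

test_that("top-k accuracies follow the enumerated ranks", {
  probs <- rbind(c(.5, .3, .2, 0, 0),
                 c(.6, .2, .1, .1, 0),
                 c(.1, .2, .3, .2, .2))
  labels <- c(1, 0, 4)
  tk <- top_k_accuracy(labels, probs)
  expect_equal(unname(tk["top1"]), 1 / 3)
  expect_equal(unname(tk["top2"]), 2 / 3)
  expect_equal(unname(tk["top5"]), 1)
  expect_true(all(diff(tk) >= 0))
  # ties break toward the lower class index
  tie <- top_k_accuracy(0, matrix(c(.25, .25, .25, .25), 1))
  expect_equal(unname(tie["top1"]), 1)
  tie2 <- top_k_accuracy(3, matrix(c(.25, .25, .25, .25), 1))
  expect_equal(unname(tie2["top3"]), 0)
  expect_equal(unname(tie2["top4"]), 1)
})

test_that("spatial weights are row-standardized with symmetric knn unions", {
  pts <- cbind(c(0, 1, 2), c(0, 0, 0))
  w <- build_spatial_weights(pts, k = 1)
  # middle point gains both ends after union symmetrization
  expect_equal(sum(w$W[2, ] > 0), 2L)
  expect_equal(unname(rowSums(w$W)), c(1, 1, 1))
  expect_true(all(diag(w$W) == 0))
  expect_error(build_spatial_weights(rbind(pts, c(0, 0)),
                                     plot_ids = c("a", "b", "c", "a2")),
               "duplicate")
  set.seed(2)
  pts2 <- matrix(runif(40), 20, 2)
  w2 <- build_spatial_weights(pts2, k = 8)
  expect_equal(unname(rowSums(w2$W)), rep(1, 20))
})

test_that("Moran's I matches brute-force sums and closed forms", {
  # 2x2 rook grid, checkerboard values
  W <- matrix(0, 4, 4)
  rook <- list(c(2, 3), c(1, 4), c(1, 4), c(2, 3))
  for (i in 1:4) W[i, rook[[i]]] <- 1
  Wstd <- W / rowSums(W)
  vals <- c(1, -1, -1, 1)
  # brute-force double sum oracle
  z <- vals - mean(vals)
  num <- 0
  for (i in 1:4) for (j in 1:4) num <- num + Wstd[i, j] * z[i] * z[j]
  I_oracle <- (4 / sum(Wstd)) * num / sum(z^2)
  expect_equal(I_oracle, -1)
  r <- morans_i(vals, Wstd)
  expect_equal(r$I, -1)
  expect_equal(r$expected_I, -1 / 3)
  expect_equal(morans_i(rnorm(5) + 1:5, matrix(1, 5, 5) - diag(5))$expected_I,
               -0.25)

  # two separated constant blocks on a 4x4 rook grid: positive I
  idx <- function(r, c) (r - 1) * 4 + c
  W2 <- matrix(0, 16, 16)
  for (r2 in 1:4) for (c2 in 1:4) {
    for (d in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
      rr <- r2 + d[1]; cc <- c2 + d[2]
      if (rr >= 1 && rr <= 4 && cc >= 1 && cc <= 4) {
        W2[idx(r2, c2), idx(rr, cc)] <- 1
      }
    }
  }
  blocks <- rep(c(1, 1, -1, -1), each = 4)
  rb <- morans_i(blocks, W2 / rowSums(W2))
  expect_gt(rb$I, 0)
  expect_error(morans_i(rep(1, 16), W2), "constant")
})

test_that("Moran's I agrees with the ape reference implementation", {
  set.seed(5)
  xy <- matrix(runif(60), 30, 2)
  vals <- rnorm(30)
  w <- build_spatial_weights(xy, k = 4)
  ours <- morans_i(vals, w)
  ref <- ape::Moran.I(vals, w$W)
  expect_equal(ours$I, ref$observed, tolerance = 1e-12)
  expect_equal(ours$expected_I, ref$expected, tolerance = 1e-12)
  # ape uses the randomization variance; ours is the normality variance,
  # so the spread and p agree approximately, the moments exactly
  expect_equal(ours$sd_I, ref$sd, tolerance = 0.05)
  expect_equal(ours$p, ref$p.value, tolerance = 0.05)
})

test_that("permutation and normal p-values agree on Gaussian residuals", {
  set.seed(6)
  xy <- matrix(runif(120), 60, 2)
  w <- build_spatial_weights(xy, k = 8)
  diffs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    vals <- rnorm(60)
    r <- morans_i(vals, w, inference = "permutation", n_perm = 399, seed = s)
    abs(r$p - r$p_perm)
  }, numeric(1))
  expect_lt(stats::median(diffs), 0.05)
  expect_gte(mean(diffs < 0.05), 0.75)
})

test_that("spatial reports produce one row per requested task", {
  set.seed(7)
  n <- 40
  preds <- tibble::tibble(
    plot_id = sprintf("P%02d", 1:n),
    x = runif(n, 0, 20), y = runif(n, 0, 10),
    yield = rnorm(n, 2500, 400))
  preds$yield_pred <- preds$yield + rnorm(n, 0, 100)
  preds$class5 <- sample(0:4, n, TRUE)
  preds$class5_pred <- ifelse(runif(n) < 0.8, preds$class5, sample(0:4, n, TRUE))
  preds$class2 <- as.integer(preds$class5 > 0)
  preds$class2_pred <- as.integer(preds$class5_pred > 0)
  tab <- spatial_report(preds)
  expect_equal(nrow(tab), 3L)
  expect_setequal(tab$task, c("yield", "lodging5", "lodging2"))
  expect_true(all(is.finite(tab$z)))
  expect_true(all(grepl("knn", tab$scheme)))
})
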