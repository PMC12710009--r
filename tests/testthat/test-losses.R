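test_that("target scaling uses training-fold population statistics", {
  sc <- target_scaler(c(2000, 3000))
  expect_equal(scaler_transform(sc, c(2000, 3000)), c(-1, 1))
  y <- c(1834.2, 2529.75, 3860)
  sc2 <- target_scaler(y)
  expect_equal(scaler_inverse(sc2, scaler_transform(sc2, y)), y,
               tolerance = 1e-9)
  # validation values are scaled with the training statistics, not their own
  val <- c(2500, 2600)
  expect_equal(scaler_transform(sc, val), (val - 2500) / 500)
  expect_error(target_scaler(c(5, 5, 5)), "zero SD")
})

test_that("huber loss matches its closed forms and is continuous at delta", {
  expect_equal(huber_loss(0, 0), 0)
  expect_equal(huber_loss(0.05, 0), 0.5 * 0.05^2)        # 0.00125
  expect_equal(huber_loss(0.5, 0), 0.1 * 0.5 - 0.005)    # 0.045
  expect_equal(huber_loss(0.10, 0), 0.005)               # both branches agree
  e <- 0.1
  quad <- 0.5 * e^2
  lin <- 0.1 * e - 0.5 * 0.1^2
  expect_equal(quad, lin)
  # batch mean
  expect_equal(huber_loss(c(0.05, 0.5), c(0, 0)), (0.00125 + 0.045) / 2)
})

test_that("classification losses match ln 2 / ln 5 reference points", {
  expect_lt(classification_loss(100, 1, "binary"), 1e-6)
  expect_lt(classification_loss(matrix(c(100, 0, 0, 0, 0), 1), 0,
                                "multiclass"), 1e-6)
  expect_equal(classification_loss(0, 1, "binary"), log(2))
  expect_equal(classification_loss(0, 0, "binary"), log(2))
  expect_equal(classification_loss(matrix(0, 1, 5), 3, "multiclass"), log(5))
  expect_error(classification_loss(matrix(0, 1, 5), 5, "multiclass"), "range")
  expect_error(classification_loss(0, 2, "binary"), "0/1")
})

test_that("multitask fusion obeys both the fixed and dynamic forms", {
  L <- c(yield = 2, lodging5 = 4, lodging2 = 6)
  expect_equal(multitask_loss(L, c(yield = 1, lodging5 = 1, lodging2 = 1))$total, 12)
  expect_equal(multitask_loss(L, c(yield = 1, lodging5 = 0.5, lodging2 = 0))$total, 4)
  expect_error(multitask_loss(c(bogus = 1), c(yield = 1)), "unknown task")
  expect_error(multitask_loss(L, c(oops = 1)), "unknown|named")

  d0 <- multitask_loss(c(yield = 1), "dynamic", log_sigma = c(yield = 0))
  expect_equal(d0$total, 0.5)
  d1 <- multitask_loss(c(yield = 1), "dynamic", log_sigma = c(yield = 1))
  expect_equal(d1$total, 0.5 * exp(-2) + 1)
  # effective weight decreases monotonically in log sigma
  w <- vapply(seq(-1, 2, 0.5), function(s) {
    multitask_loss(c(yield = 1), "dynamic", log_sigma = c(yield = s))$weights
  }, numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("analytic gradients agree with numerical differentiation", {
  num_grad <- function(f, x, h = 1e-6) {
    vapply(seq_along(x), function(i) {
      xp <- x; xm <- x
      xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
      (f(xp) - f(xm)) / (2 * h)
    }, numeric(1))
  }
  set.seed(31)
  pred <- rnorm(7, 0, 0.5); targ <- rnorm(7, 0, 0.5)
  g <- huber_grad(pred, targ)
  gn <- num_grad(function(p) huber_loss(p, targ), pred)
  expect_lt(max(abs(g - gn)), 1e-4)

  logits <- rnorm(5)
  lab <- c(1, 0, 1, 1, 0)
  g2 <- classification_grad(logits, lab, "binary")
  gn2 <- num_grad(function(l) classification_loss(l, lab, "binary"), logits)
  expect_lt(max(abs(g2 - gn2)), 1e-4)

  L5 <- matrix(rnorm(15), 3, 5)
  lab5 <- c(0, 3, 4)
  g3 <- classification_grad(L5, lab5, "multiclass")
  gn3 <- matrix(num_grad(function(v) {
    classification_loss(matrix(v, 3, 5), lab5, "multiclass")
  }, as.vector(L5)), 3, 5)
  expect_lt(max(abs(g3 - gn3)), 1e-4)

  L <- c(yield = 0.3, lodging5 = 1.2, lodging2 = 0.8)
  s <- c(yield = 0.2, lodging5 = 1.0, lodging2 = -0.3)
  mg <- multitask_grad(L, "dynamic", log_sigma = s)
  gn4 <- num_grad(function(Lv) {
    multitask_loss(setNames(Lv, names(L)), "dynamic", log_sigma = s)$total
  }, L)
  expect_lt(max(abs(unname(mg$d_loss) - gn4)), 1e-4)
  gn5 <- num_grad(function(sv) {
    multitask_loss(L, "dynamic", log_sigma = setNames(sv, names(s)))$total
  }, s)
  expect_lt(max(abs(unname(mg$d_log_sigma) - gn5)), 1e-4)
})

test_that("learning-rate schedules start at lr0 and never increase", {
  lrs <- vapply(1:200, lr_schedule, numeric(1), epochs = 200)
  expect_equal(lrs[1], 0.02)
  expect_true(all(diff(lrs) <= 0))
  expect_equal(lrs[200], 1e-4)
  st <- vapply(1:100, lr_schedule, numeric(1), epochs = 100, schedule = "step")
  expect_equal(st[1], 0.02)
  expect_equal(st[51], 0.002)
  expect_equal(st[76], 2e-4)
  expect_true(all(diff(st) <= 0))
})

test_that("dynamic weighting recovers the injected noise ordering", {
  # two linear regression tasks sharing a scalar parameter, noise SDs 4x
  # apart; gradient descent on (w, log_sigma) via the dynamic-loss
  # gradients should order the learned sigmas like the injected noise
  recovered <- vapply(1:10, function(seed) {
    set.seed(seed)
    n <- 200
    x <- rnorm(n)
    yA <- 1.5 * x + rnorm(n, 0, 0.1)   # low-noise task
    yB <- 1.5 * x + rnorm(n, 0, 0.4)   # high-noise task
    w <- 0; s <- c(taskA = 1, taskB = 1)
    names(s) <- c("yield", "lodging5")  # any two distinct task slots
    for (it in 1:1500) {
      eA <- w * x - yA; eB <- w * x - yB
      L <- c(yield = mean(eA^2) / 2, lodging5 = mean(eB^2) / 2)
      g <- multitask_grad(L, "dynamic", log_sigma = s)
      dw <- g$d_loss[["yield"]] * mean(eA * x) +
        g$d_loss[["lodging5"]] * mean(eB * x)
      w <- w - 0.01 * dw
      s <- s - 0.05 * g$d_log_sigma
    }
    s[["yield"]] < s[["lodging5"]]
  }, logical(1))
  expect_gte(sum(recovered), 9)
})

test_that("a small model overfits a 25-plot training set", {
  # capacity check: regularization (dropout) off, since the question is
  # whether the optimizer can drive the training loss toward zero
  d <- small_entries()
  cfg <- run_config(n_points = 256, task = "yield", model = "soynet_res",
                    pooling = "mean", epochs = 30, batch_size = 5, seed = 9)
  arch <- arch_spec("soynet_res", "mean", dropout = 0)
  set.seed(9)
  fit <- soy_fit(d$entries, cfg, arch = arch, augment = FALSE,
                 oversample = FALSE)
  labs <- entry_labels(d$entries)
  pr <- predict(fit$model, entry_features(d$entries))
  final_training_loss <- huber_loss(
    scaler_transform(fit$model$scaler, pr$yield_pred),
    scaler_transform(fit$model$scaler, labs$yield))
  expect_lt(final_training_loss, 0.1 * fit$history$loss[1])
})

test_that("training runs are deterministic given the seed", {
  d <- small_entries()
  cfg <- run_config(n_points = 256, task = "lodging5", model = "soynet_res",
                    pooling = "max", epochs = 3, seed = 21)
  f1 <- soy_fit(d$entries, cfg)
  f2 <- soy_fit(d$entries, cfg)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$history$loss_lodging5, f2$history$loss_lodging5)
})

test_that("the training-fold scaler never sees validation yields", {
  d <- small_entries()
  tr <- d$entries[1:18]; va <- d$entries[19:25]
  cfg <- run_config(n_points = 256, task = "yield", model = "soynet_res",
                    pooling = "mean", epochs = 2, seed = 3)
  fit <- soy_fit(tr, cfg, validation = va, eval_every = 1)
  ytr <- entry_labels(tr)$yield
  expect_equal(fit$model$scaler$center, mean(ytr))
  expect_equal(fit$model$scaler$scale, sqrt(mean((ytr - mean(ytr))^2)))
})

test_that("stratified folds partition plots and balance grades", {
  class5 <- rep(0:4, times = c(30, 25, 20, 15, 10))
  fold <- make_folds(class5, k = 5, seed = 4)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(length(fold), 100L)
  # per-fold grade counts within 1 of the stratified share
  for (cl in 0:4) {
    per <- table(factor(fold[class5 == cl], levels = 1:5))
    expect_lte(max(per) - min(per), 1)
  }
  expect_warning(make_folds(c(0, 0, 0, 1), k = 5), "fewer than k")
})

test_that("cross-validation pools one prediction per plot", {
  d <- small_entries()
  cfg <- run_config(n_points = 256, task = "lodging2", model = "soynet_res",
                    pooling = "max", epochs = 2, seed = 13)
  suppressWarnings(cv <- cross_validate(d$entries, cfg, k = 3,
                                        oversample = FALSE, augment = FALSE))
  expect_equal(nrow(cv$predictions), length(d$entries))
  expect_setequal(cv$predictions$plot_id, d$labels$plot_id)
  expect_equal(sort(unique(cv$predictions$fold)), 1:3)
  expect_equal(sum(table(cv$folds)), 25L)
  expect_true(all(table(cv$folds) >= 6))
})
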