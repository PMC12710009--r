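test_that("global feature widths and head shapes match the designs", {
  n <- 64
  set.seed(1)
  m_res <- soy_model("multitask", arch_spec("soynet_res", "per_task"),
                     n_points = n)
  m_soy <- soy_model("lodging5", arch_spec("soynet", "max"), n_points = n)
  X <- rand_features(2, n)
  out_res <- model_forward(m_res, fclouds_from_matrix(X, n))
  out_soy <- model_forward(m_soy, fclouds_from_matrix(X, n))
  expect_equal(ncol(out_res$global_feature), 256L)
  expect_equal(ncol(out_soy$global_feature), 1024L)
  expect_equal(dim(out_res$logits5), c(2L, 5L))
  expect_length(out_res$yield, 2L)
  expect_length(out_res$logit2, 2L)
  expect_lt(soycloud:::eng_global_dim(m_res$ptr),
            soycloud:::eng_global_dim(m_soy$ptr))
  # parameter counts are deterministic
  set.seed(99)
  m2 <- soy_model("lodging5", arch_spec("soynet", "max"), n_points = n)
  expect_equal(n_parameters(m_soy), n_parameters(m2))
  # 13-channel input contract
  expect_error(soycloud:::eng_forward(m_soy$ptr, X[, 1:12], 2L, FALSE), "13")
})

test_that("eval-mode forward matches an independent R implementation", {
  n <- 32
  X <- rand_features(3, n, seed = 5)
  for (setup in list(list("yield", "soynet_res", "mean"),
                     list("lodging5", "soynet_res", "max"),
                     list("lodging2", "soynet", "max"),
                     list("multitask", "soynet_res", "per_task"))) {
    set.seed(7)
    m <- soy_model(setup[[1]], arch_spec(setup[[2]], setup[[3]]),
                   n_points = n, precision = "double")
    eng <- model_forward(m, fclouds_from_matrix(X, n))
    ref <- ref_forward(m, X, 3)
    for (nm in intersect(names(ref), names(eng))) {
      expect_equal(unname(as.matrix(eng[[nm]])), unname(as.matrix(ref[[nm]])),
                   tolerance = 1e-10,
                   info = paste(setup[[2]], setup[[1]], nm))
    }
  }
})

test_that("outputs are invariant to point permutation under both poolings", {
  n <- 64
  X <- rand_features(2, n, seed = 3)
  for (pool in c("max", "mean")) {
    set.seed(11)
    m <- soy_model("yield", arch_spec("soynet_res", pool), n_points = n)
    base <- model_forward(m, fclouds_from_matrix(X, n))
    Xp <- X
    for (b in 1:2) {
      rows <- ((b - 1) * n + 1):(b * n)
      Xp[rows, ] <- X[rows[sample(n)], ]
    }
    perm <- model_forward(m, fclouds_from_matrix(Xp, n))
    expect_equal(base$yield, perm$yield, tolerance = 1e-5)
    expect_equal(base$global_feature, perm$global_feature, tolerance = 1e-5)
  }
})

test_that("duplicating every point leaves the pooled feature unchanged", {
  n <- 48
  set.seed(13)
  mA <- soy_model("lodging5", arch_spec("soynet_res", "max"), n_points = n)
  mB <- soy_model("lodging5", arch_spec("soynet_res", "max"), n_points = 2 * n)
  soycloud:::eng_set_params(mB$ptr, soycloud:::eng_get_params(mA$ptr))
  X <- rand_features(1, n, seed = 4)
  Xdup <- rbind(X, X)
  a <- model_forward(mA, fclouds_from_matrix(X, n))
  b <- model_forward(mB, fclouds_from_matrix(Xdup, 2 * n))
  expect_equal(a$global_feature, b$global_feature, tolerance = 1e-6)
  expect_equal(a$logits5, b$logits5, tolerance = 1e-5)
})

test_that("zeroed residual branches reduce blocks to their shortcut", {
  n <- 16
  set.seed(17)
  m <- soy_model("yield", arch_spec("soynet_res", "mean"), n_points = n,
                 precision = "double")
  p <- soycloud:::eng_get_params(m$ptr)
  for (i in 0:2) {
    nm <- paste0("res", i)
    p[[paste0(nm, ".down.W")]][] <- 0
    p[[paste0(nm, ".down.b")]][] <- 0
    p[[paste0(nm, ".bn2.gamma")]][] <- 0
    p[[paste0(nm, ".bn2.beta")]][] <- 0
  }
  soycloud:::eng_set_params(m$ptr, p)
  X <- rand_features(1, n, seed = 9)
  eng <- model_forward(m, fclouds_from_matrix(X, n))
  # analytic trace: backbone collapses to lrelu chains over the shortcuts
  s <- m$arch$leaky_slope
  H <- ref_cbr(X, p, "stem", s)
  H <- ref_lrelu(H, s)                       # res0: identity shortcut
  H <- ref_lrelu(ref_dense(H, p, "res1.proj"), s)
  H <- ref_lrelu(ref_dense(H, p, "res2.proj"), s)
  G <- matrix(colMeans(H), 1)
  Tr <- ref_trunk(G, p, 1, s)
  expect_equal(as.vector(eng$yield), as.vector(ref_dense(Tr, p, "head_yield")),
               tolerance = 1e-10)
})

test_that("multitask degenerate input gives equal pooled paths", {
  n <- 24
  set.seed(19)
  m <- soy_model("multitask", arch_spec("soynet_res", "per_task"),
                 n_points = n, precision = "double")
  X <- matrix(0, n, 13)  # all features identical -> mean pool == max pool
  out <- model_forward(m, fclouds_from_matrix(X, n))
  p <- soycloud:::eng_get_params(m$ptr)
  ref <- ref_forward(m, X, 1)
  expect_equal(as.vector(out$yield), ref$yield, tolerance = 1e-10)
  # with constant per-point features, the mean- and max-pooled vectors agree
  Hstem <- ref_cbr(X, p, "stem", m$arch$leaky_slope)
  expect_equal(max(apply(Hstem, 2, function(v) diff(range(v)))), 0)
})

test_that("forwards are finite on random inputs and eval is bit-stable", {
  n <- 32
  set.seed(23)
  m <- soy_model("multitask", arch_spec("soynet_res", "per_task"), n_points = n)
  for (i in 1:10) {
    X <- rand_features(100, n, seed = 100 + i)
    out <- model_forward(m, fclouds_from_matrix(X, n))
    expect_true(all(is.finite(out$yield)))
    expect_true(all(is.finite(out$logits5)))
    expect_true(all(is.finite(out$logit2)))
  }
  X <- rand_features(5, n, seed = 200)
  a <- model_forward(m, fclouds_from_matrix(X, n))
  b <- model_forward(m, fclouds_from_matrix(X, n))
  expect_identical(a$yield, b$yield)
  expect_identical(a$logits5, b$logits5)
})

test_that("checkpoints restore the exact model state", {
  n <- 32
  set.seed(29)
  m <- soy_model("yield", arch_spec("soynet_res", "mean"), n_points = n)
  m$scaler <- target_scaler(c(2000, 2500, 3000))
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  X <- rand_features(2, n, seed = 6)
  expect_identical(model_forward(m, fclouds_from_matrix(X, n))$yield,
                   model_forward(m2, fclouds_from_matrix(X, n))$yield)
  expect_equal(m2$scaler$center, m$scaler$center)
})
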