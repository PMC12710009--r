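# Shared fixtures and an independent R re-implementation of the network
# forward pass (eval mode), used as the oracle for the C++ engine.

make_cloud <- function(n = 50, seed = 1, plot_id = "T001") {
  set.seed(seed)
  plot_cloud(matrix(rnorm(n * 3), n, 3),
             matrix(runif(n * 3), n, 3),
             plot_id = plot_id)
}

# small synthetic field -> training records, shared across training tests
small_entries <- local({
  cache <- NULL
  function(n_points = 256, rows = 5, cols = 5, seed = 3) {
    if (!is.null(cache)) return(cache)
    fld <- simulate_field(field_sim_params(rows = rows, cols = cols, seed = seed))
    pp <- lapply(seq_along(fld$clouds), function(i) {
      preprocess_cloud(fld$clouds[[i]], target_n = n_points, seed = i)
    })
    cache <<- list(entries = entries_from(lapply(pp, `[[`, "cloud"), fld$labels),
                   labels = fld$labels, truth = fld$truth)
    cache
  }
})

ref_lrelu <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)

ref_dense <- function(X, p, nm) {
  sweep(X %*% p[[paste0(nm, ".W")]], 2, p[[paste0(nm, ".b")]], "+")
}

ref_bn <- function(X, p, nm, slot = 0) {
  mu <- p[[paste0(nm, ".rmean", slot)]]
  va <- p[[paste0(nm, ".rvar", slot)]]
  g <- p[[paste0(nm, ".gamma")]]
  b <- p[[paste0(nm, ".beta")]]
  xh <- sweep(sweep(X, 2, mu), 2, sqrt(va + 1e-5), "/")
  sweep(sweep(xh, 2, g, "*"), 2, b, "+")
}

ref_cbr <- function(X, p, nm, slope) {
  ref_lrelu(ref_bn(ref_dense(X, p, paste0(nm, ".fc")), p, paste0(nm, ".bn")),
            slope)
}

ref_res <- function(X, p, nm, slope) {
  h <- ref_lrelu(ref_bn(ref_dense(X, p, paste0(nm, ".up")), p,
                        paste0(nm, ".bn1")), slope)
  y <- ref_bn(ref_dense(h, p, paste0(nm, ".down")), p, paste0(nm, ".bn2"))
  r <- if (!is.null(p[[paste0(nm, ".proj.W")]])) {
    ref_dense(X, p, paste0(nm, ".proj"))
  } else X
  ref_lrelu(y + r, slope)
}

ref_pool <- function(H, B, n, type) {
  t(sapply(seq_len(B), function(b) {
    S <- H[((b - 1) * n + 1):(b * n), , drop = FALSE]
    if (type == "max") apply(S, 2, max) else colMeans(S)
  }))
}

ref_trunk <- function(G, p, n_layers, slope, slot = 0) {
  H <- G
  for (i in seq_len(n_layers) - 1) {
    H <- ref_lrelu(ref_bn(ref_dense(H, p, paste0("trunk", i)), p,
                          paste0("trunkbn", i), slot), slope)
  }
  H
}

# full eval-mode forward in plain R, for any model configuration
ref_forward <- function(model, X, B) {
  p <- eng_params_of(model)
  n <- model$n_points
  slope <- model$arch$leaky_slope
  variant <- model$arch$variant
  H <- X
  if (variant == "soynet") {
    for (i in 0:4) H <- ref_cbr(H, p, paste0("cbr", i), slope)
    n_trunk <- 2
  } else {
    H <- ref_cbr(H, p, "stem", slope)
    for (i in 0:2) H <- ref_res(H, p, paste0("res", i), slope)
    n_trunk <- 1
  }
  out <- list()
  if (model$task == "multitask" && model$arch$pooling == "per_task") {
    gmean <- ref_pool(H, B, n, "mean")
    gmax <- ref_pool(H, B, n, "max")
    tmean <- ref_trunk(gmean, p, n_trunk, slope, slot = 0)
    tmax <- ref_trunk(gmax, p, n_trunk, slope, slot = 1)
    out$yield <- as.vector(ref_dense(tmean, p, "head_yield"))
    out$logits5 <- ref_dense(tmax, p, "head5")
    out$logit2 <- as.vector(ref_dense(tmax, p, "head2"))
    out$global_feature <- gmax
  } else {
    G <- ref_pool(H, B, n, model$arch$pooling)
    Tr <- ref_trunk(G, p, n_trunk, slope)
    if (model$task %in% c("yield", "multitask")) {
      out$yield <- as.vector(ref_dense(Tr, p, "head_yield"))
    }
    if (model$task %in% c("lodging5", "multitask")) {
      out$logits5 <- ref_dense(Tr, p, "head5")
    }
    if (model$task %in% c("lodging2", "multitask")) {
      out$logit2 <- as.vector(ref_dense(Tr, p, "head2"))
    }
    out$global_feature <- G
  }
  out
}

eng_params_of <- function(model) soycloud:::eng_get_params(model$ptr)

rand_features <- function(B, n, seed = 1) {
  set.seed(seed)
  matrix(runif(B * n * 13, -1, 1), B * n, 13)
}

fclouds_from_matrix <- function(X, n) {
  B <- nrow(X) / n
  lapply(seq_len(B), function(b) {
    structure(list(plot_id = paste0("F", b),
                   x = {
                     m <- X[((b - 1) * n + 1):(b * n), , drop = FALSE]
                     colnames(m) <- c("x", "y", "z", "R", "G", "B", "EXR",
                                      "EXG", "EXGR", "MGRVI", "RGRI", "PPRb",
                                      "VARI")
                     m
                   }),
              class = "feature_cloud")
  })
}
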