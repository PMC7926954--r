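# Finite-difference utilities for the gradient check -------------------------

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(vec, skel) {
  pos <- 0L
  rec <- function(s) {
    if (is.list(s)) return(lapply(s, rec))
    n <- length(s)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(s))) dim(out) <- dim(s)
    out
  }
  rec(skel)
}

check_gradients <- function(arch, lcfg, seed, n_checks = 25) {
  set.seed(seed)
  n <- 6
  x <- matrix(runif(n * arch$input_dim), n)
  y <- sample(arch$n_classes, n, replace = TRUE)
  eps_mat <- if (arch$variational)
    matrix(rnorm(n * arch$encoder_dims[length(arch$encoder_dims)]), n) else NULL
  model <- build_model(arch, lcfg, seed = seed)
  params <- model$params

  loss_of <- function(vec) {
    p <- unflatten_params(vec, params)
    fwd <- hemafex:::joint_forward(p, arch, x, eps = eps_mat,
                                  with_head = lcfg$classification_loss != "none",
                                  with_decoder = lcfg$use_reconstruction)
    hemafex:::batch_losses(fwd, x, y, arch, lcfg)$total
  }

  fwd <- hemafex:::joint_forward(params, arch, x, eps = eps_mat,
                                with_head = lcfg$classification_loss != "none",
                                with_decoder = lcfg$use_reconstruction)
  grads <- hemafex:::joint_backward(params, arch, fwd, x, y, lcfg)
  gvec <- flatten_params(grads[names(params)])
  pvec <- flatten_params(params)

  idx <- sample(length(pvec), n_checks)
  h <- 1e-6
  for (k in idx) {
    up <- pvec; up[k] <- up[k] + h
    dn <- pvec; dn[k] <- dn[k] - h
    num <- (loss_of(up) - loss_of(dn)) / (2 * h)
    expect_equal(gvec[k], num, tolerance = 1e-4,
                 label = sprintf("analytic grad at %d", k))
  }
}

test_that("backpropagation matches numerical gradients for every loss mix", {
  arch <- tiny_arch(10, n_classes = 3)
  check_gradients(arch, loss_config("CE", use_reconstruction = TRUE), seed = 1)
  check_gradients(arch, loss_config("FL", use_reconstruction = TRUE,
                                    focal_gamma = 2), seed = 2)
  check_gradients(arch, loss_config("FL", use_reconstruction = FALSE,
                                    focal_gamma = 0.5), seed = 3)
  check_gradients(arch, loss_config("none", use_reconstruction = TRUE), seed = 4)
  varch <- tiny_arch(10, n_classes = 3, variational = TRUE)
  check_gradients(varch, loss_config("CE", use_reconstruction = TRUE), seed = 5)
})

test_that("model shapes follow the architecture and builds are seed-deterministic", {
  arch <- architecture_config(input_dim = 40, n_classes = 5,
                              encoder_dims = c(30, 12, 7),
                              decoder_dims = c(12, 30))
  m1 <- build_model(arch, seed = 11)
  m2 <- build_model(arch, seed = 11)
  m3 <- build_model(arch, seed = 12)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))

  x <- matrix(runif(7 * 40), 7)
  feats <- extract_features(m1, x)
  expect_equal(dim(feats), c(7L, 7L))
  fwd <- hemafex:::joint_forward(m1$params, arch, x)
  expect_equal(dim(fwd$dec$recon), dim(x))
  expect_equal(dim(fwd$head$probs), c(7L, 5L))
  expect_equal(rowSums(fwd$head$probs), rep(1, 7), tolerance = 1e-12)

  expect_error(architecture_config(10, 3, encoder_dims = c(8, 4),
                                   decoder_dims = c(4, 8, 10)),
               "exactly two")
})

test_that("training reduces reconstruction loss and keeps the loss ledger consistent", {
  spec <- small_signal_spec(seed = 3)
  ds <- generate_synthetic(spec)
  prep <- preprocess_for_ae(ds)
  arch <- architecture_config(n_genes(ds), 5, encoder_dims = c(32, 8),
                              decoder_dims = c(8, 32), head_hidden_dim = 8)

  m <- build_model(arch, loss_config("none", use_reconstruction = TRUE), seed = 1)
  fit <- train_joint(m, prep$dataset,
                     train_config(max_epochs = 40, learning_rate = 1e-3,
                                  early_stopping_patience = 39, seed = 2))
  h <- as.data.frame(fit$history)
  expect_lt(h$mse[nrow(h)], h$mse[1])
  expect_true(fit$model$trained)

  m2 <- build_model(arch, loss_config("CE", use_reconstruction = TRUE), seed = 1)
  fit2 <- train_joint(m2, prep$dataset,
                      train_config(max_epochs = 15, learning_rate = 1e-3,
                                   early_stopping_patience = 14, seed = 2))
  h2 <- as.data.frame(fit2$history)
  expect_equal(h2$total, h2$mse + h2$classification_loss, tolerance = 1e-9)
})

test_that("reconstruction-only training never reads the labels", {
  spec <- small_signal_spec(seed = 6, sizes = c(30, 30, 30))
  ds <- generate_synthetic(spec)
  prep <- preprocess_for_ae(ds)
  arch <- architecture_config(n_genes(ds), 3, encoder_dims = c(16, 6),
                              decoder_dims = c(6, 16), head_hidden_dim = 6)
  cfg <- train_config(max_epochs = 10, learning_rate = 1e-3,
                      early_stopping_patience = 9, seed = 5)
  lcfg <- loss_config("none", use_reconstruction = TRUE)

  fit_a <- train_joint(build_model(arch, lcfg, seed = 4), prep$dataset, cfg)
  scrambled <- prep$dataset
  scrambled$labels <- rev(scrambled$labels)
  fit_b <- train_joint(build_model(arch, lcfg, seed = 4), scrambled, cfg)
  expect_identical(fit_a$model$params, fit_b$model$params)
})

test_that("feature extraction is deterministic, also for the variational model", {
  arch <- tiny_arch(12, variational = TRUE)
  m <- build_model(arch, loss_config("CE", TRUE), seed = 2)
  x <- matrix(runif(5 * 12), 5)
  f1 <- extract_features(m, x)
  f2 <- extract_features(m, x)
  expect_identical(f1, f2)
  expect_equal(dim(f1), c(5L, 5L))
  expect_error(extract_features(m, x[, 1:4]), "expects")
})

test_that("jointly trained features separate planted classes", {
  spec <- small_signal_spec(seed = 13)
  ds <- generate_synthetic(spec)
  sp <- stratified_split(ds, 0.8, seed = 1)
  prep <- preprocess_for_ae(sp$train)
  tprep <- preprocess_for_ae(sp$test, scaler = prep$scaler)
  arch <- architecture_config(n_genes(ds), 5, encoder_dims = c(64, 16, 8),
                              decoder_dims = c(16, 64), head_hidden_dim = 16)
  m <- build_model(arch, loss_config("FL", use_reconstruction = TRUE), seed = 7)
  fit <- train_joint(m, prep$dataset,
                     train_config(max_epochs = 150, learning_rate = 1e-3,
                                  early_stopping_patience = 30, seed = 7))
  ftr <- extract_features(fit$model, prep$dataset)
  fte <- extract_features(fit$model, tprep$dataset)

  # silhouette-style separation of test features by class
  dmat <- as.matrix(dist(fte))
  y <- sp$test$labels
  sil <- vapply(seq_along(y), function(i) {
    a <- mean(dmat[i, y == y[i] & seq_along(y) != i])
    b <- min(vapply(setdiff(unique(y), y[i]),
                    function(c) mean(dmat[i, y == c]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)

  # joint-loss features match a raw-feature oracle for a linear classifier
  lr <- classifier_spec("LR", seed = 1)
  f1_feat <- compute_metrics(confusion(
    label_factor(sp$test),
    fit_predict(lr, ftr, label_factor(sp$train), fte)$labels))$macro[["f1"]]
  f1_raw <- compute_metrics(confusion(
    label_factor(sp$test),
    fit_predict(lr, prep$dataset$matrix, label_factor(sp$train),
                tprep$dataset$matrix)$labels))$macro[["f1"]]
  expect_gte(f1_raw, 0.95)
  expect_gte(f1_feat, 0.95)
})

test_that("checkpoints reload to bit-identical features", {
  arch <- tiny_arch(9)
  m <- build_model(arch, loss_config("CE", TRUE), seed = 3)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  x <- matrix(runif(4 * 9), 4)
  expect_identical(extract_features(m, x), extract_features(m2, x))
})

test_that("PCA and NMF baselines behave like their definitions", {
  set.seed(5)
  # exact low-rank case: rank-2 matrix reconstructed by 2 components
  basis <- matrix(rnorm(20), 10, 2)
  load <- matrix(rnorm(16), 2, 8)
  x <- basis %*% load
  bf <- baseline_features(x, "PCA", 2)
  recon <- bf$train %*% t(bf$fit$rotation[, 1:2]) +
    matrix(bf$fit$center, 10, 8, byrow = TRUE)
  expect_equal(recon, x, tolerance = 1e-8, ignore_attr = TRUE)
  # orthogonal loadings
  expect_equal(crossprod(bf$fit$rotation), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)

  xp <- matrix(rexp(30 * 12), 30, 12)
  nf <- baseline_features(xp, "NMF", 3, newdata = xp[1:5, ], seed = 2)
  expect_true(all(nf$train >= 0))
  expect_true(all(nf$fit$H >= 0))
  expect_true(all(nf$test >= 0))
  expect_equal(dim(nf$train), c(30L, 3L))
  expect_error(baseline_features(xp, "PCA", 50), "n_components")
})
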