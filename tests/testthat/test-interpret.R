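test_that("sampled Shapley values recover the closed form for a linear model", {
  set.seed(3)
  d <- 6
  w <- rnorm(d)
  f <- function(x) as.matrix(x) %*% w
  background <- matrix(rnorm(200 * d), 200, d)
  x <- matrix(rnorm(d), 1, d)
  # for a linear model, phi_i = w_i * (x_i - mean(background_i))
  closed <- w * (x[1, ] - colMeans(background))

  ests <- t(vapply(1:12, function(s)
    shapley_attribution(f, background, x, n_permutations = 150,
                        seed = s)$values[1, ], numeric(d)))
  m <- colMeans(ests)
  se <- apply(ests, 2, sd) / sqrt(nrow(ests))
  expect_true(all(abs(m - closed) <= 3 * pmax(se, 1e-8)))
})

test_that("a constant model gets zero attribution everywhere", {
  f <- function(x) rep(1, nrow(as.matrix(x)))
  attr <- shapley_attribution(f, matrix(rnorm(20), 10, 2),
                              matrix(rnorm(6), 3, 2), n_permutations = 10,
                              seed = 1)
  expect_true(all(attr$values == 0))
})

test_that("per-sample estimates satisfy the efficiency axiom exactly", {
  set.seed(9)
  d <- 5
  f <- function(x) {
    x <- as.matrix(x)
    cbind(stats::plogis(x %*% rnorm5), 1 - stats::plogis(x %*% rnorm5))
  }
  rnorm5 <- rnorm(d)
  background <- matrix(rnorm(50 * d), 50, d)
  explained <- matrix(rnorm(3 * d), 3, d)
  attr <- shapley_attribution(f, background, explained, n_permutations = 25,
                              seed = 4)
  expect_equal(rowSums(attr$values), attr$prediction - attr$base_values,
               tolerance = 1e-10)
})

test_that("duplicated features share attribution and ignored features get none", {
  set.seed(15)
  n_bg <- 400
  z <- rnorm(n_bg)
  background <- cbind(z, z, rnorm(n_bg))   # columns 1 and 2 identical
  f <- function(x) as.matrix(x)[, 1] + as.matrix(x)[, 2]  # column 3 is a dummy
  x <- matrix(c(1.3, 1.3, 0.5), 1, 3)
  ests <- t(vapply(1:10, function(s)
    shapley_attribution(f, background, x, n_permutations = 200,
                        seed = s)$values[1, ], numeric(3)))
  m <- colMeans(ests)
  se <- apply(ests, 2, sd) / sqrt(nrow(ests))
  expect_lt(abs(m[1] - m[2]), 3 * sqrt(se[1]^2 + se[2]^2) + 1e-8)
  expect_identical(unname(m[3]), 0)  # dummy never changes f
})

test_that("more permutations shrink the estimator's variance", {
  set.seed(21)
  d <- 4
  w <- rnorm(d)
  f <- function(x) as.matrix(x) %*% w
  background <- matrix(rnorm(100 * d), 100, d)
  x <- matrix(rnorm(d), 1, d)
  est_at <- function(n_perm) vapply(1:15, function(s)
    shapley_attribution(f, background, x, n_permutations = n_perm,
                        seed = 100 + s)$values[1, 1], numeric(1))
  v_small <- var(est_at(5))
  v_large <- var(est_at(80))
  expect_lt(v_large, v_small)
})

test_that("biomarker ranking sorts by mean |attribution| with lexicographic ties", {
  vals <- rbind(c(0.2, -0.9, 0.1), c(0.4, 0.7, -0.1))
  attr <- structure(list(values = vals, gene_ids = c("gB", "gA", "gC"),
                         base_values = c(0, 0), base_value = 0,
                         prediction = c(0, 0), target_class = c(1L, 1L)),
                    class = "attribution_matrix")
  top <- top_k_biomarkers(attr, 3)
  expect_equal(top$gene_id, c("gA", "gB", "gC"))
  expect_equal(top$mean_abs_attribution, c(0.8, 0.3, 0.1))
  expect_error(top_k_biomarkers(attr, 4), "exceeds")

  zero <- attr
  zero$values <- matrix(0, 2, 3)
  expect_equal(top_k_biomarkers(zero, 2)$gene_id, c("gA", "gB"))

  long <- attribution_long(attr)
  expect_equal(nrow(long), 6)
  expect_equal(long$value[long$gene == "gA"], c(-0.9, 0.7))
})
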