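test_that("every classifier separates well-separated blobs perfectly", {
  blobs <- make_blobs(c(30, 30), d = 4, sep = 8, seed = 2)
  for (name in c("LR", "RF", "KNN", "ANN", "SVM")) {
    spec <- classifier_spec(name, seed = 3)
    pred <- fit_predict(spec, blobs$x, blobs$y, blobs$x)
    expect_equal(as.character(pred$labels), as.character(blobs$y),
                 label = name)
    expect_equal(unname(rowSums(pred$scores)), rep(1, 60), tolerance = 1e-6)
  }
  expect_error(classifier_spec("GBM"), "LR, RF, KNN, ANN, SVM")
})

test_that("1-NN returns the label of an exactly matching training point", {
  blobs <- make_blobs(c(10, 10, 10), d = 3, seed = 5)
  spec <- classifier_spec("KNN", hyperparameters = list(k = 1), seed = 1)
  pred <- fit_predict(spec, blobs$x, blobs$y, blobs$x[c(3, 25), , drop = FALSE])
  expect_equal(as.character(pred$labels), as.character(blobs$y[c(3, 25)]))
})

test_that("predictions are deterministic given the spec seed", {
  blobs <- make_blobs(c(25, 15, 20), d = 5, sep = 2, sd = 1.5, seed = 8)
  test <- make_blobs(c(10, 6, 8), d = 5, sep = 2, sd = 1.5, seed = 8)
  for (name in c("RF", "ANN", "SVM")) {
    p1 <- fit_predict(classifier_spec(name, seed = 42), blobs$x, blobs$y, test$x)
    p2 <- fit_predict(classifier_spec(name, seed = 42), blobs$x, blobs$y, test$x)
    expect_identical(p1$labels, p2$labels, label = name)
    expect_identical(p1$scores, p2$scores, label = name)
  }
})

test_that("confusion counts true-by-predicted cells", {
  cm <- confusion(c(1, 1, 2), c(1, 2, 2), n_classes = 2)
  expect_equal(unname(unclass(cm)), matrix(c(1L, 0L, 1L, 1L), 2))
  perfect <- confusion(rep(1:5, 3), rep(1:5, 3), n_classes = 5)
  expect_equal(unname(unclass(perfect)), diag(3L, 5))
  expect_equal(sum(cm), 3)
  # invariant to permuting the sample order
  set.seed(1)
  t <- sample(3, 50, replace = TRUE); p <- sample(3, 50, replace = TRUE)
  o <- sample(50)
  expect_identical(confusion(t, p, 3), confusion(t[o], p[o], 3))
  expect_error(confusion(1:3, 1:2), "equal length")
})

test_that("metric suite matches hand-evaluated binary values", {
  # TP=50, FN=5, FP=5, TN=40 for class 1
  cm <- matrix(c(50, 5, 5, 40), 2, byrow = TRUE)
  rep <- compute_metrics(cm)
  c1 <- rep$per_class[1, ]
  expect_equal(rep$accuracy, 0.9)
  expect_equal(c1$precision, 50 / 55, tolerance = 1e-5)
  expect_equal(c1$recall, 50 / 55, tolerance = 1e-5)
  expect_equal(c1$specificity, 40 / 45, tolerance = 1e-5)
  expect_equal(c1$f1, 0.90909, tolerance = 1e-4)
  expect_equal(c1$gmean, 0.89893, tolerance = 1e-4)
  expect_equal(c1$iba, 0.90075, tolerance = 1e-4)

  # Rec = 0.8, Spe = 0.9 closed form: GM = 0.84853, IBA = 0.99 * GM
  gm <- sqrt(0.8 * 0.9)
  expect_equal(gm, 0.84853, tolerance = 1e-5)
  expect_equal((1 + 0.1 * (0.8 - 0.9)) * gm, 0.84004, tolerance = 1e-4)

  perfect <- diag(10L, 5)
  prep <- compute_metrics(perfect)
  expect_equal(prep$accuracy, 1)
  expect_true(all(abs(prep$macro - 1) < 1e-12))
})

test_that("metric suite agrees with a brute-force per-sample counter", {
  brute_force <- function(cm, alpha = 0.1) {
    # expand the matrix into per-sample labels and count binary outcomes
    t <- rep(rep(seq_len(nrow(cm)), ncol(cm)), as.vector(cm))
    p <- rep(rep(seq_len(ncol(cm)), each = nrow(cm)), as.vector(cm))
    per <- t(vapply(seq_len(nrow(cm)), function(c) {
      tp <- sum(t == c & p == c); fn <- sum(t == c & p != c)
      fp <- sum(t != c & p == c); tn <- sum(t != c & p != c)
      pre <- if (tp + fp) tp / (tp + fp) else 0
      rec <- if (tp + fn) tp / (tp + fn) else 0
      spe <- if (tn + fp) tn / (tn + fp) else 0
      f1 <- if (2 * tp + fp + fn) 2 * tp / (2 * tp + fp + fn) else 0
      gm <- sqrt(rec * spe)
      c(pre, rec, spe, f1, gm, (1 + alpha * (rec - spe)) * gm)
    }, numeric(6)))
    list(acc = mean(t == p), macro = colMeans(per))
  }
  set.seed(17)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    cm <- matrix(rpois(k * k, 3), k)
    if (sum(cm) == 0) cm[1, 1] <- 1
    got <- compute_metrics(cm)
    want <- brute_force(cm)
    expect_equal(got$accuracy, want$acc, tolerance = 1e-12)
    expect_equal(unname(got$macro), unname(want$macro), tolerance = 1e-12)
  }
})

test_that("IBA reduces to the G-mean at alpha = 0 and F1 sits between Pre and Rec", {
  set.seed(23)
  for (i in 1:20) {
    cm <- matrix(rpois(16, 4), 4)
    if (sum(cm) == 0) cm[2, 2] <- 1
    r0 <- compute_metrics(cm, alpha = 0)
    expect_identical(r0$per_class$iba, r0$per_class$gmean)
    r <- compute_metrics(cm)
    ok <- r$per_class$f1 >= pmin(r$per_class$precision, r$per_class$recall) - 1e-12 &
      r$per_class$f1 <= pmax(r$per_class$precision, r$per_class$recall) + 1e-12
    expect_true(all(ok))
  }
  # squared-GM variant of the IBA
  cm <- matrix(c(50, 5, 5, 40), 2, byrow = TRUE)
  ri <- compute_metrics(cm, iba_squared = TRUE)
  rg <- compute_metrics(cm)
  expect_equal(ri$per_class$iba, rg$per_class$iba * rg$per_class$gmean,
               tolerance = 1e-12)
})

test_that("zero-denominator metrics are flagged zeros, not NaN", {
  cm <- matrix(c(5, 0, 3, 0), 2, byrow = TRUE)  # class 2 never predicted...
  rep <- compute_metrics(cm)
  expect_true(all(is.finite(rep$per_class$precision)))
  expect_true(all(is.finite(unname(rep$macro))))
  expect_true(any(rep$flagged))
})

test_that("PR curve and average precision follow the step-wise integral", {
  pc <- pr_curve(c(1, 2, 1, 2), cbind(c(0.9, 0.8, 0.4, 0.1),
                                      c(0.1, 0.2, 0.6, 0.9)), 1)
  expect_equal(pc$average_precision, 0.5 * 1 + 0.5 * (2 / 3),
               tolerance = 1e-12)
  # perfectly ranked scores
  perfect <- pr_curve(c(1, 1, 2, 2), cbind(c(0.9, 0.8, 0.2, 0.1),
                                           c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(perfect$average_precision, 1)
  # constant scores: precision equals prevalence everywhere
  const <- pr_curve(c(1, 1, 2, 2, 2, 2, 2, 2), matrix(0.5, 8, 2), 1)
  expect_true(all(abs(const$points$precision - 0.25) < 1e-12))
  expect_error(pr_curve(c(2, 2), matrix(0.5, 2, 2), 1), "absent")
})

test_that("random guessing on balanced classes yields chance-level macro recall", {
  set.seed(29)
  t <- rep(1:4, each = 250)
  p <- sample(4, 1000, replace = TRUE)
  rep <- compute_metrics(confusion(t, p, 4))
  expect_lt(abs(rep$macro[["recall"]] - 0.25), 0.05)
})
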