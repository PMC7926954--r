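#' Sampling-based Shapley-value feature attribution
#'
#' Model-agnostic Monte-Carlo permutation estimator of Shapley values for
#' any predictor. For each explained sample and each sampled feature
#' ordering, features are switched one at a time from a randomly drawn
#' background row to the explained sample's values, and the marginal change
#' in the model output is credited to the switched feature. The estimator is
#' unbiased for the exact Shapley value, and each per-sample estimate
#' satisfies the efficiency axiom exactly:
#' `sum_i phi_i = f(x) - mean_b f(b)` over the sampled background rows.
#'
#' The explained output is the probability of `target_class`; by default the
#' model's predicted class for each explained sample, which is the natural
#' target for biomarker ranking.
#'
#' @param predict_fn Function mapping a feature matrix (rows = samples) to a
#'   matrix of class probabilities, or to a numeric vector (single output).
#' @param background Matrix of background samples used to impute "absent"
#'   features (e.g. a stratified subsample of training data).
#' @param explained Matrix of samples to explain (same column count).
#' @param n_permutations Number of sampled feature orderings per sample.
#' @param seed Integer seed; the estimate is reproducible from it.
#' @param target_class Optional fixed class (integer column index) to
#'   explain for every sample.
#' @param feature_names Optional feature (gene) names; defaults to the
#'   column names of `explained`.
#' @return A list of class `attribution_matrix`: `values` (explained samples
#'   x features), `base_values` (per-sample expected output on the sampled
#'   background), `base_value` (their mean), `prediction` (f(x) per sample),
#'   `target_class`, `gene_ids`.
#' @export
shapley_attribution <- function(predict_fn, background, explained,
                                n_permutations = 100L, seed = 1L,
                                target_class = NULL, feature_names = NULL) {
  background <- as.matrix(background)
  explained <- as.matrix(explained)
  assert_that(nrow(background) >= 1, "background must be non-empty")
  assert_that(ncol(background) == ncol(explained),
              "background and explained must have the same features")
  if (n_permutations < 1)
    stop("n_permutations must be >= 1", call. = FALSE)
  d <- ncol(explained)
  n <- nrow(explained)
  feature_names <- feature_names %||% colnames(explained) %||%
    paste0("f", seq_len(d))

  as_output <- function(out) {
    if (is.null(dim(out))) matrix(out, ncol = 1) else as.matrix(out)
  }
  pred_x <- as_output(predict_fn(explained))
  targets <- if (is.null(target_class))
    max.col(pred_x, ties.method = "first") else rep(as.integer(target_class), n)

  values <- matrix(0, n, d)
  base_values <- numeric(n)
  # cumulative inclusion mask: row r has the first r-1 ordered features "on"
  mask0 <- outer(0:d, seq_len(d), ">=")

  with_seed(seed, {
    for (i in seq_len(n)) {
      x <- explained[i, ]
      tc <- targets[i]
      phi <- numeric(d)
      base_acc <- 0
      for (p in seq_len(n_permutations)) {
        ord <- sample.int(d)
        b <- background[sample.int(nrow(background), 1L), ]
        mask <- mask0
        mask[, ord] <- mask0
        z <- matrix(b, d + 1L, d, byrow = TRUE)
        xrep <- matrix(x, d + 1L, d, byrow = TRUE)
        z[mask] <- xrep[mask]
        f <- as_output(predict_fn(z))[, tc]
        phi[ord] <- phi[ord] + diff(f)
        base_acc <- base_acc + f[1L]
      }
      values[i, ] <- phi / n_permutations
      base_values[i] <- base_acc / n_permutations
    }
  })

  colnames(values) <- feature_names
  structure(list(values = values, base_values = base_values,
                 base_value = mean(base_values),
                 prediction = pred_x[cbind(seq_len(n), targets)],
                 target_class = targets, gene_ids = feature_names),
            class = "attribution_matrix")
}

#' Rank genes by mean absolute attribution
#'
#' Orders genes by decreasing mean absolute Shapley value across the
#' explained samples (ties broken lexicographically by gene ID) — the
#' "top-k biomarkers" summary.
#'
#' @param attr An [shapley_attribution()] result.
#' @param k Number of top genes to return (<= number of genes).
#' @return Data.frame with `gene_id`, `mean_abs_attribution`, `rank`.
#' @export
top_k_biomarkers <- function(attr, k) {
  assert_that(inherits(attr, "attribution_matrix"),
              "attr must be an attribution_matrix")
  n_genes <- ncol(attr$values)
  if (k > n_genes)
    stop(sprintf("k = %d exceeds the %d available genes", k, n_genes),
         call. = FALSE)
  score <- colMeans(abs(attr$values))
  ord <- order(-score, attr$gene_ids)
  top <- ord[seq_len(k)]
  data.frame(gene_id = attr$gene_ids[top],
             mean_abs_attribution = unname(score[top]),
             rank = seq_len(k), stringsAsFactors = FALSE)
}

#' Export attribution values in long format
#'
#' One row per (sample, gene): the layout used for summary/beeswarm-style
#' plots of per-class attributions.
#'
#' @param attr An [shapley_attribution()] result.
#' @return Data.frame with `sample`, `gene`, `class`, `value`.
#' @export
attribution_long <- function(attr) {
  assert_that(inherits(attr, "attribution_matrix"),
              "attr must be an attribution_matrix")
  n <- nrow(attr$values); d <- ncol(attr$values)
  data.frame(sample = rep(seq_len(n), times = d),
             gene = rep(attr$gene_ids, each = n),
             class = rep(attr$target_class, times = d),
             value = as.vector(attr$values),
             stringsAsFactors = FALSE)
}
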