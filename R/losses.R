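# Loss functions of the joint objective. All take an n x K matrix of class
# probabilities (rows summing to 1) and integer labels in 1..K, and return a
# batch mean. Probabilities are clipped at 1e-12 before logs.

PROB_EPS <- 1e-12

check_probs <- function(probabilities, labels) {
  probabilities <- as.matrix(probabilities)
  labels <- as.integer(labels)
  assert_that(nrow(probabilities) == length(labels),
              "probabilities and labels must agree in sample count")
  assert_that(all(labels >= 1 & labels <= ncol(probabilities)),
              "labels out of range for probability matrix")
  sums <- rowSums(probabilities)
  assert_that(all(abs(sums - 1) < 1e-6),
              "probability rows must sum to 1")
  list(p = probabilities, y = labels)
}

p_true <- function(probabilities, labels) {
  probabilities[cbind(seq_along(labels), labels)]
}

#' Cross-entropy classification loss
#'
#' Mean over samples of `-log p_true`.
#'
#' @param probabilities n x K matrix of class probabilities (rows sum to 1).
#' @param labels Integer class codes in 1..K.
#' @return Non-negative scalar.
#' @export
cross_entropy <- function(probabilities, labels) {
  ck <- check_probs(probabilities, labels)
  pt <- pmax(p_true(ck$p, ck$y), PROB_EPS)
  mean(-log(pt))
}

#' Focal classification loss
#'
#' Cross-entropy with the modulating factor `(1 - p_true)^gamma` that
#' down-weights well-classified samples, countering class imbalance:
#' mean of `-(1 - p_true)^gamma * log(p_true)`. At `gamma = 0` it equals
#' [cross_entropy()].
#'
#' @inheritParams cross_entropy
#' @param gamma Focusing parameter, >= 0 (default 2).
#' @return Non-negative scalar.
#' @export
focal_loss <- function(probabilities, labels, gamma = 2) {
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  ck <- check_probs(probabilities, labels)
  pt <- pmax(p_true(ck$p, ck$y), PROB_EPS)
  mean(-(1 - pt)^gamma * log(pt))
}

#' Reconstruction loss (mean squared error)
#'
#' Mean over all matrix entries of the squared difference between a batch
#' and its reconstruction.
#'
#' @param input_batch,reconstructed_batch Numeric matrices of equal shape.
#' @return Non-negative scalar.
#' @export
reconstruction_mse <- function(input_batch, reconstructed_batch) {
  input_batch <- as.matrix(input_batch)
  reconstructed_batch <- as.matrix(reconstructed_batch)
  assert_that(all(dim(input_batch) == dim(reconstructed_batch)),
              "input and reconstruction must have equal shape")
  mean((input_batch - reconstructed_batch)^2)
}

#' KL divergence of a diagonal Gaussian from the standard normal
#'
#' The variational regularizer `0.5 * sum_d(mu^2 + exp(log_var) - 1 -
#' log_var)`, averaged over samples. Vectors are treated as a single sample.
#'
#' @param mu Matrix (samples x dims) or vector of posterior means.
#' @param log_var Matching matrix/vector of posterior log-variances.
#' @return Non-negative scalar.
#' @export
kl_divergence_gaussian <- function(mu, log_var) {
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1)
  if (is.null(dim(log_var))) log_var <- matrix(log_var, nrow = 1)
  assert_that(all(dim(mu) == dim(log_var)),
              "mu and log_var must have equal shape")
  mean(0.5 * rowSums(mu^2 + exp(log_var) - 1 - log_var))
}
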