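#' SMOTE oversampling to a uniform class histogram
#'
#' Synthetic minority oversampling: every non-majority class is topped up to
#' the majority count with synthetic points `x + u * (x_nn - x)`, where
#' `u ~ Uniform(0, 1)` and `x_nn` is one of the `k_neighbors` nearest
#' same-class neighbors (Euclidean). Original rows pass through unchanged
#' (first in the output); synthetic rows are appended. `k_neighbors` is
#' capped at class size minus one. Intended for the extracted training
#' features only — never resample test data.
#'
#' @param features Numeric matrix (samples x features).
#' @param labels Class codes (integer or factor), one per row.
#' @param k_neighbors Number of same-class nearest neighbors to interpolate
#'   toward (default 5, the classical SMOTE setting).
#' @param seed Integer seed; output is reproducible from it.
#' @return List with `features` (matrix) and `labels` (same type as input),
#'   originals first, synthetic rows appended.
#' @export
smote_oversample <- function(features, labels, k_neighbors = 5L, seed = 1L) {
  features <- as.matrix(features)
  assert_that(k_neighbors >= 1, "k_neighbors must be >= 1")
  assert_that(nrow(features) == length(labels),
              "features and labels must agree in sample count")
  fac <- if (is.factor(labels)) labels else factor(labels)
  counts <- table(fac)
  majority <- max(counts)
  present <- names(counts)[counts > 0]

  singletons <- names(counts)[counts == 1 & counts < majority]
  if (length(singletons))
    stop(sprintf(paste0("class(es) %s have a single sample; SMOTE needs >= 2 ",
                        "per class - lower k_neighbors or merge classes"),
                 paste(singletons, collapse = ", ")), call. = FALSE)

  syn_x <- list(); syn_y <- list()
  with_seed(seed, {
    for (cl in present) {
      idx <- which(fac == cl)
      n_new <- majority - length(idx)
      if (n_new == 0) next
      xc <- features[idx, , drop = FALSE]
      k <- min(k_neighbors, length(idx) - 1L)
      dmat <- as.matrix(stats::dist(xc))
      diag(dmat) <- Inf
      # k nearest same-class neighbors of each original point (k x n_c)
      nn <- matrix(apply(dmat, 1, function(r) order(r)[seq_len(k)]),
                   nrow = k)
      base <- sample.int(length(idx), n_new, replace = TRUE)
      pick <- vapply(base, function(b) nn[sample.int(k, 1), b], integer(1))
      u <- stats::runif(n_new)
      syn_x[[cl]] <- xc[base, , drop = FALSE] +
        u * (xc[pick, , drop = FALSE] - xc[base, , drop = FALSE])
      syn_y[[cl]] <- rep(cl, n_new)
    }
  })

  new_x <- rbind(features, do.call(rbind, syn_x))
  new_fac <- factor(c(as.character(fac), unlist(syn_y)), levels = levels(fac))
  out_labels <- if (is.factor(labels)) new_fac
                else if (is.character(labels)) as.character(new_fac)
                else as.integer(as.character(new_fac))
  rownames(new_x) <- NULL
  list(features = new_x, labels = out_labels)
}
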