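#' Downstream classifier specification
#'
#' The five classifiers of the comparison grid, served by established
#' backends: multinomial logistic regression (`nnet::multinom`), random
#' forest (`randomForest`, 100 trees), k-nearest neighbor (`caret::knn3`,
#' k = 5), a single-hidden-layer neural network (`nnet`, 100 nodes) and an
#' RBF-kernel support vector machine (`e1071::svm`). Stated defaults can be
#' overridden through `hyperparameters`.
#'
#' @param name One of `"LR"`, `"RF"`, `"KNN"`, `"ANN"`, `"SVM"`.
#' @param hyperparameters Named list of backend hyperparameter overrides.
#' @param seed Integer seed controlling any backend randomness.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(name, hyperparameters = list(), seed = 1L) {
  valid <- c("LR", "RF", "KNN", "ANN", "SVM")
  if (!name %in% valid)
    stop(sprintf("unknown classifier '%s'; valid names: %s", name,
                 paste(valid, collapse = ", ")), call. = FALSE)
  defaults <- switch(name,
                     LR  = list(maxit = 200),
                     RF  = list(ntree = 100),
                     KNN = list(k = 5),
                     ANN = list(size = 100, maxit = 200, decay = 1e-4),
                     SVM = list(kernel = "radial", cost = 1))
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(name = name, hyperparameters = hp, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Fit a classifier and predict test labels
#'
#' Fits the specified backend on training features and labels and predicts
#' the test features. Deterministic given `spec$seed`. All backends provide
#' class scores (probability matrices with rows summing to 1).
#'
#' @param spec A [classifier_spec()].
#' @param train_features,test_features Numeric matrices with identical
#'   column counts.
#' @param train_labels Factor (or coercible) of training labels.
#' @return A list of class `subtype_prediction` with `labels` (factor over
#'   the training levels) and `scores` (matrix, columns in level order).
#' @export
fit_predict <- function(spec, train_features, train_labels, test_features) {
  assert_that(inherits(spec, "classifier_spec"), "spec must be a classifier_spec")
  train_features <- as.matrix(train_features)
  test_features <- as.matrix(test_features)
  assert_that(ncol(train_features) == ncol(test_features),
              "train and test feature dimensionality must agree")
  y <- if (is.factor(train_labels)) droplevels(train_labels)
       else factor(train_labels)
  lev <- levels(y)
  hp <- spec$hyperparameters
  colnames(train_features) <- paste0("F", seq_len(ncol(train_features)))
  colnames(test_features) <- colnames(train_features)

  out <- with_seed(spec$seed, switch(spec$name,
    LR = {
      df <- data.frame(.y = y, train_features, check.names = FALSE)
      fit <- nnet::multinom(.y ~ ., data = df, maxit = hp$maxit,
                            MaxNWts = 100000, trace = FALSE)
      ndf <- data.frame(test_features, check.names = FALSE)
      pr <- stats::predict(fit, ndf, type = "probs")
      if (is.null(dim(pr))) pr <- cbind(1 - pr, pr, deparse.level = 0)
      colnames(pr) <- lev
      list(scores = pr)
    },
    RF = {
      fit <- randomForest::randomForest(train_features, y, ntree = hp$ntree)
      list(scores = stats::predict(fit, test_features, type = "prob")[, lev,
                                                                      drop = FALSE])
    },
    KNN = {
      fit <- caret::knn3(train_features, y, k = hp$k)
      list(scores = stats::predict(fit, test_features, type = "prob")[, lev,
                                                                      drop = FALSE])
    },
    ANN = {
      targets <- nnet::class.ind(y)
      fit <- nnet::nnet(train_features, targets, size = hp$size,
                        softmax = TRUE, maxit = hp$maxit, decay = hp$decay,
                        MaxNWts = 1000000, trace = FALSE)
      pr <- stats::predict(fit, test_features, type = "raw")
      colnames(pr) <- colnames(targets)
      list(scores = pr[, lev, drop = FALSE])
    },
    SVM = {
      fit <- e1071::svm(train_features, y, kernel = hp$kernel, cost = hp$cost,
                        probability = TRUE, scale = FALSE)
      pred <- stats::predict(fit, test_features, probability = TRUE)
      pr <- attr(pred, "probabilities")[, lev, drop = FALSE]
      list(scores = pr)
    }))

  scores <- out$scores
  labels <- factor(lev[max.col(scores, ties.method = "first")], levels = lev)
  structure(list(labels = labels, scores = scores, classifier = spec$name),
            class = "subtype_prediction")
}

#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes:
#' `counts[i, j]` = number of samples with true class `i` predicted as `j`.
#'
#' @param true_labels,predicted_labels Equal-length vectors of class codes
#'   (integer or factor).
#' @param n_classes Number of classes; inferred when labels are factors.
#' @return Integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(true_labels, predicted_labels, n_classes = NULL) {
  assert_that(length(true_labels) == length(predicted_labels),
              "true and predicted labels must have equal length")
  if (is.factor(true_labels) || is.factor(predicted_labels)) {
    # a numeric side is interpreted as codes into the factor side's levels
    lev <- if (is.factor(true_labels)) levels(true_labels)
           else levels(predicted_labels)
    to_codes <- function(v) {
      if (is.numeric(v)) as.integer(v) else match(as.character(v), lev)
    }
    t_codes <- to_codes(true_labels)
    p_codes <- to_codes(predicted_labels)
    if (is.null(n_classes)) n_classes <- length(lev)
  } else {
    t_codes <- as.integer(true_labels)
    p_codes <- as.integer(predicted_labels)
    if (is.null(n_classes)) n_classes <- max(t_codes, p_codes)
    lev <- as.character(seq_len(n_classes))
  }
  assert_that(all(t_codes >= 1 & t_codes <= n_classes) &&
                all(p_codes >= 1 & p_codes <= n_classes),
              "labels out of range for n_classes")
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = lev[seq_len(n_classes)],
                               predicted = lev[seq_len(n_classes)]))
  for (i in seq_along(t_codes))
    cm[t_codes[i], p_codes[i]] <- cm[t_codes[i], p_codes[i]] + 1L
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' Imbalance-aware metric suite from a confusion matrix
#'
#' Global accuracy plus one-vs-rest per-class precision, recall
#' (sensitivity), specificity, F1, geometric mean `GM = sqrt(Rec * Spe)` and
#' index of balanced accuracy `IBA = (1 + alpha * (Rec - Spe)) * GM`
#' (default `alpha = 0.1`), together with their unweighted macro averages.
#' Ratios with a zero denominator are reported as 0 and flagged so macro
#' averages stay defined. `iba_squared = TRUE` switches the IBA base from GM
#' to GM^2, the form of the original IBA literature.
#'
#' @param cm A [confusion()] matrix (or any square count matrix).
#' @param alpha IBA weighting of the recall-specificity dominance.
#' @param iba_squared Use GM^2 instead of GM in the IBA.
#' @return A list of class `metric_report`: `accuracy`, `per_class`
#'   (data.frame), `macro` (named vector), `alpha`, `flagged`.
#' @export
compute_metrics <- function(cm, alpha = 0.1, iba_squared = FALSE) {
  cm <- unclass(cm)
  assert_that(is.matrix(cm) && nrow(cm) == ncol(cm) && nrow(cm) >= 1,
              "cm must be a square confusion matrix")
  total <- sum(cm)
  assert_that(total > 0, "confusion matrix is empty")
  k <- nrow(cm)
  classes <- rownames(cm) %||% as.character(seq_len(k))

  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp

  pre <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  spe <- safe_div(tn, tn + fp)
  f1 <- safe_div(2 * tp, 2 * tp + fp + fn)
  gm <- sqrt(rec * spe)
  base <- if (iba_squared) gm^2 else gm
  iba <- (1 + alpha * (rec - spe)) * base
  flagged <- (tp + fp == 0) | (tp + fn == 0) | (tn + fp == 0)

  per_class <- data.frame(class = classes, precision = pre, recall = rec,
                          specificity = spe, f1 = f1, gmean = gm, iba = iba,
                          flagged = flagged, row.names = NULL)
  macro <- c(precision = mean(pre), recall = mean(rec),
             specificity = mean(spe), f1 = mean(f1), gmean = mean(gm),
             iba = mean(iba))
  structure(list(accuracy = sum(tp) / total, per_class = per_class,
                 macro = macro, alpha = alpha, flagged = flagged),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("accuracy: %.4f\n", x$accuracy))
  cat("macro:  ", paste(sprintf("%s=%.4f", names(x$macro), x$macro),
                        collapse = "  "), "\n")
  print(x$per_class, digits = 4)
  invisible(x)
}

#' One-vs-rest precision-recall curve and average precision
#'
#' Treats `class_index` as positive, ranks samples by descending score, and
#' returns the precision/recall points at each distinct threshold plus the
#' step-wise average precision `AP = sum_i (R_i - R_{i-1}) * P_i`.
#'
#' @param true_labels Class codes (integer or factor).
#' @param class_scores Matrix of class scores, columns in class-code order.
#' @param class_index Positive class (integer code or level name).
#' @return List of class `pr_curve`: `points` (data.frame with `threshold`,
#'   `recall`, `precision`) and `average_precision`.
#' @export
pr_curve <- function(true_labels, class_scores, class_index) {
  class_scores <- as.matrix(class_scores)
  if (is.factor(true_labels)) {
    lev <- levels(true_labels)
    if (is.numeric(class_index)) {
      pos <- as.integer(true_labels) == as.integer(class_index)
      col <- as.integer(class_index)
    } else {
      pos <- as.character(true_labels) == as.character(class_index)
      col <- if (class_index %in% colnames(class_scores)) class_index
             else match(as.character(class_index), lev)
    }
  } else {
    pos <- as.integer(true_labels) == as.integer(class_index)
    col <- as.integer(class_index)
  }
  if (!any(pos))
    stop("positive class absent from true labels", call. = FALSE)
  s <- class_scores[, col]
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; pos <- pos[ord]
  # collapse ties: evaluate at each distinct threshold
  last_of_thr <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(pos)[last_of_thr]
  fp <- cumsum(!pos)[last_of_thr]
  thr <- s[last_of_thr]
  n_pos <- sum(pos)
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  ap <- sum(diff(c(0, recall)) * precision)
  structure(list(points = data.frame(threshold = thr, recall = recall,
                                     precision = precision),
                 average_precision = ap),
            class = "pr_curve")
}

#' Flatten a metric report to a one-row results table
#'
#' Produces the row layout of the experiment results tables:
#' feature extraction, loss, sampling, then Acc / Pre / Rec / Spe / F1 /
#' GM / IBA (global accuracy, macro averages for the rest).
#'
#' @param report A [compute_metrics()] report.
#' @param classifier,feature_extraction,loss,sampling Cell identifiers.
#' @return One-row data.frame.
#' @export
metric_row <- function(report, classifier = NA, feature_extraction = NA,
                       loss = NA, sampling = NA) {
  data.frame(classifier = classifier, feature_extraction = feature_extraction,
             loss = loss, sampling = sampling,
             Acc = report$accuracy,
             Pre = report$macro[["precision"]],
             Rec = report$macro[["recall"]],
             Spe = report$macro[["specificity"]],
             F1 = report$macro[["f1"]],
             GM = report$macro[["gmean"]],
             IBA = report$macro[["iba"]],
             stringsAsFactors = FALSE)
}
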