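#' Configuration of the experimental grid
#'
#' Describes the full comparison: feature extractors (PCA, NMF, AE, VAE) x
#' loss functions (CE, FL, RE, TOC = CE+RE, TOF = FL+RE; the loss axis
#' applies only to the autoencoders) x sampling (none, SMOTE) x classifiers
#' (LR, KNN, RF, SVM, ANN). One global seed makes the whole grid
#' reproducible.
#'
#' @param feature_extractors Subset of `c("PCA", "NMF", "AE", "VAE")`.
#' @param losses Subset of `c("CE", "FL", "RE", "TOC", "TOF")`.
#' @param sampling Subset of `c("none", "SMOTE")`.
#' @param classifiers Subset of `c("LR", "KNN", "RF", "SVM", "ANN")`.
#' @param train_fraction Train share of the stratified split.
#' @param n_components PCA/NMF component count (defaults to the code
#'   dimension so all extractors emit features of equal width).
#' @param encoder_dims,decoder_dims,head_hidden_dim Autoencoder architecture
#'   (see [architecture_config()]).
#' @param train A [train_config()] template (its seed is re-derived per
#'   cell from the global seed).
#' @param focal_gamma Focal-loss focusing parameter.
#' @param smote_k SMOTE neighbor count.
#' @param seed Global seed.
#' @param out_dir Optional directory for per-cell artifacts (models,
#'   histories, confusion matrices, metrics, pinned config).
#' @return A list of class `grid_config`.
#' @export
grid_config <- function(feature_extractors = c("PCA", "NMF", "AE", "VAE"),
                        losses = c("CE", "FL", "RE", "TOC", "TOF"),
                        sampling = c("none", "SMOTE"),
                        classifiers = c("LR", "KNN", "RF", "SVM", "ANN"),
                        train_fraction = 0.8,
                        n_components = NULL,
                        encoder_dims = c(2000L, 500L, 100L),
                        decoder_dims = rev(encoder_dims)[-1],
                        head_hidden_dim = 100L,
                        train = train_config(),
                        focal_gamma = 2,
                        smote_k = 5L,
                        seed = 1L,
                        out_dir = NULL) {
  feature_extractors <- match.arg(feature_extractors,
                                  c("PCA", "NMF", "AE", "VAE"), several.ok = TRUE)
  losses <- match.arg(losses, c("CE", "FL", "RE", "TOC", "TOF"),
                      several.ok = TRUE)
  sampling <- match.arg(sampling, c("none", "SMOTE"), several.ok = TRUE)
  classifiers <- match.arg(classifiers,
                           c("LR", "KNN", "RF", "SVM", "ANN"), several.ok = TRUE)
  assert_that(length(feature_extractors) >= 1 && length(sampling) >= 1 &&
                length(classifiers) >= 1, "grid axes must be non-empty")
  assert_that(!any(c("AE", "VAE") %in% feature_extractors) ||
                length(losses) >= 1,
              "losses must be non-empty when AE/VAE are in the grid")
  structure(list(feature_extractors = feature_extractors, losses = losses,
                 sampling = sampling, classifiers = classifiers,
                 train_fraction = train_fraction,
                 n_components = n_components %||%
                   encoder_dims[length(encoder_dims)],
                 encoder_dims = as.integer(encoder_dims),
                 decoder_dims = as.integer(decoder_dims),
                 head_hidden_dim = as.integer(head_hidden_dim),
                 train = train, focal_gamma = focal_gamma,
                 smote_k = as.integer(smote_k),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "grid_config")
}

#' Run the full experimental grid
#'
#' For every grid cell: stratified split, log/min-max preprocessing fit on
#' train, feature-extractor fit on train and applied to test, optional
#' SMOTE on the training features, classifier fit, test prediction and the
#' full metric suite. Feature extraction is computed once per
#' (extractor, loss) cell and shared across sampling and classifier axes.
#' A failing cell is recorded with `NA` metrics and its error message;
#' remaining cells continue. Fully reproducible from `cfg$seed`.
#'
#' @param data An `expression_dataset` or a [synthetic_spec()] (which is
#'   generated first).
#' @param cfg A [grid_config()].
#' @return A data.frame of class `grid_result`: one row per cell with
#'   columns `classifier`, `feature_extraction`, `loss`, `sampling`,
#'   `Acc`, `Pre`, `Rec`, `Spe`, `F1`, `GM`, `IBA`, `error`.
#' @export
run_grid <- function(data, cfg) {
  assert_that(inherits(cfg, "grid_config"), "cfg must be a grid_config")
  ds <- if (inherits(data, "synthetic_spec")) generate_synthetic(data) else data
  assert_that(inherits(ds, "expression_dataset"),
              "data must be an expression_dataset or synthetic_spec")
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(grid_config_as_list(cfg), file.path(out_dir, "config.yaml"))
  }

  split <- stratified_split(ds, cfg$train_fraction, seed = derive_seed(cfg$seed, 1L))
  prep <- preprocess_for_ae(split$train)
  test_prep <- preprocess_for_ae(split$test, scaler = prep$scaler)
  y_train <- label_factor(split$train)
  y_test <- label_factor(split$test)

  # feature cells: list of (extractor, loss, train features, test features)
  cells <- list()
  cell_id <- 0L
  for (fx in cfg$feature_extractors) {
    if (fx %in% c("PCA", "NMF")) {
      cell_id <- cell_id + 1L
      feats <- tryCatch({
        if (fx == "PCA") {
          bf <- baseline_features(prep$dataset$matrix, "PCA",
                                  cfg$n_components,
                                  newdata = test_prep$dataset$matrix)
        } else {
          bf <- baseline_features(split$train$matrix, "NMF",
                                  cfg$n_components,
                                  newdata = split$test$matrix,
                                  seed = derive_seed(cfg$seed, 100L + cell_id))
        }
        list(train = bf$train, test = bf$test, error = NA_character_)
      }, error = function(e) list(train = NULL, test = NULL,
                                  error = conditionMessage(e)))
      cells[[length(cells) + 1L]] <- c(list(extractor = fx, loss = "No"), feats)
    } else {
      for (lk in cfg$losses) {
        cell_id <- cell_id + 1L
        cseed <- derive_seed(cfg$seed, 100L + cell_id)
        feats <- tryCatch({
          arch <- architecture_config(
            input_dim = n_genes(ds), n_classes = length(ds$class_names),
            encoder_dims = cfg$encoder_dims, decoder_dims = cfg$decoder_dims,
            head_hidden_dim = cfg$head_hidden_dim,
            variational = fx == "VAE")
          lcfg <- loss_config_from_keyword(lk, focal_gamma = cfg$focal_gamma)
          tcfg <- cfg$train
          tcfg$seed <- cseed
          model <- build_model(arch, lcfg, seed = cseed)
          fit <- train_joint(model, prep$dataset, tcfg)
          if (!is.null(out_dir)) {
            stem <- file.path(out_dir, sprintf("%s_%s", fx, lk))
            save_model(fit$model, paste0(stem, "_model.rds"))
            utils::write.csv(as.data.frame(fit$history),
                             paste0(stem, "_history.csv"), row.names = FALSE)
          }
          list(train = extract_features(fit$model, prep$dataset),
               test = extract_features(fit$model, test_prep$dataset),
               error = NA_character_)
        }, error = function(e) list(train = NULL, test = NULL,
                                    error = conditionMessage(e)))
        cells[[length(cells) + 1L]] <- c(list(extractor = fx, loss = lk), feats)
      }
    }
  }

  rows <- list()
  ri <- 0L
  for (cell in cells) {
    for (sm in cfg$sampling) {
      resampled <- NULL
      for (clf in cfg$classifiers) {
        ri <- ri + 1L
        row <- tryCatch({
          if (!is.na(cell$error)) stop(cell$error, call. = FALSE)
          if (is.null(resampled)) {
            resampled <- if (sm == "SMOTE")
              smote_oversample(cell$train, y_train, cfg$smote_k,
                               seed = derive_seed(cfg$seed, 500L + ri))
            else list(features = cell$train, labels = y_train)
          }
          spec <- classifier_spec(clf, seed = derive_seed(cfg$seed, 1000L + ri))
          pred <- fit_predict(spec, resampled$features, resampled$labels,
                              cell$test)
          cm <- confusion(y_test, pred$labels,
                          n_classes = length(ds$class_names))
          rep <- compute_metrics(cm)
          if (!is.null(out_dir)) {
            stem <- file.path(out_dir, sprintf("%s_%s_%s_%s",
                                               clf, cell$extractor, cell$loss, sm))
            utils::write.csv(as.data.frame(unclass(cm)),
                             paste0(stem, "_confusion.csv"))
            utils::write.csv(rep$per_class, paste0(stem, "_per_class.csv"),
                             row.names = FALSE)
          }
          cbind(metric_row(rep, clf, cell$extractor, cell$loss, sm),
                error = NA_character_)
        }, error = function(e) {
          data.frame(classifier = clf, feature_extraction = cell$extractor,
                     loss = cell$loss, sampling = sm, Acc = NA_real_,
                     Pre = NA_real_, Rec = NA_real_, Spe = NA_real_,
                     F1 = NA_real_, GM = NA_real_, IBA = NA_real_,
                     error = conditionMessage(e), stringsAsFactors = FALSE)
        })
        rows[[ri]] <- row
      }
    }
  }

  result <- do.call(rbind, rows)
  rownames(result) <- NULL
  class(result) <- c("grid_result", "data.frame")
  if (!is.null(out_dir))
    utils::write.csv(result, file.path(out_dir, "grid_results.csv"),
                     row.names = FALSE)
  result
}

grid_config_as_list <- function(cfg) {
  out <- unclass(cfg)
  out$train <- unclass(out$train)
  out
}

#' Top-k grid cells by macro F1
#'
#' Sorts a grid result by descending macro F1 (ties broken by accuracy,
#' then by cell name) and returns the top `k` rows — the "top performances"
#' summary table.
#'
#' @param gr A [run_grid()] result.
#' @param k Number of rows to return.
#' @return A `grid_result` data.frame with `k` rows.
#' @export
rank_results <- function(gr, k = 10L) {
  assert_that(inherits(gr, "data.frame") && nrow(gr) >= 1,
              "grid result is empty")
  assert_that(k >= 1 && k <= nrow(gr), "k must be in [1, nrow(gr)]")
  cell <- paste(gr$classifier, gr$feature_extraction, gr$loss, gr$sampling)
  ord <- order(-gr$F1, -gr$Acc, cell)
  out <- gr[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}
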