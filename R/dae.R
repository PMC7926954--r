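#' Architecture of the joint autoencoder
#'
#' The encoder is a stack of fully connected ReLU layers whose widths are
#' `encoder_dims` (default 2000/500/100; the last entry is the code
#' dimension). The decoder has exactly two ReLU hidden layers
#' (`decoder_dims`, default mirroring the encoder: 500/2000) followed by a
#' sigmoid output back to `input_dim`. A classifier head maps the code
#' through one ReLU hidden layer of `head_hidden_dim` nodes (default 100) to
#' a softmax over `n_classes`. With `variational = TRUE` the code layer
#' parameterizes a diagonal Gaussian (mu, log-variance) sampled via the
#' reparameterization trick during training; the mean is used as the
#' deterministic feature at extraction time.
#'
#' @param input_dim Number of input genes.
#' @param n_classes Number of subtype classes.
#' @param encoder_dims Integer vector of encoder layer widths.
#' @param decoder_dims Integer vector of exactly two decoder hidden widths.
#' @param head_hidden_dim Width of the classifier head's hidden layer.
#' @param variational Build the variational variant?
#' @return A list of class `architecture_config`.
#' @export
architecture_config <- function(input_dim, n_classes,
                                encoder_dims = c(2000L, 500L, 100L),
                                decoder_dims = rev(encoder_dims)[-1],
                                head_hidden_dim = 100L,
                                variational = FALSE) {
  assert_that(input_dim >= 1, "input_dim must be positive")
  assert_that(n_classes >= 2, "n_classes must be >= 2")
  assert_that(length(encoder_dims) >= 1 && all(encoder_dims >= 1),
              "encoder_dims must be positive integers")
  assert_that(length(decoder_dims) == 2 && all(decoder_dims >= 1),
              "decoder_dims must contain exactly two positive widths")
  structure(list(input_dim = as.integer(input_dim),
                 n_classes = as.integer(n_classes),
                 encoder_dims = as.integer(encoder_dims),
                 decoder_dims = as.integer(decoder_dims),
                 head_hidden_dim = as.integer(head_hidden_dim),
                 variational = isTRUE(variational)),
            class = "architecture_config")
}

#' Loss configuration of the joint objective
#'
#' The trained objective is the sum of the enabled components:
#' reconstruction MSE (plus the Gaussian KL term for the variational model)
#' and a classification loss on the code (cross-entropy `"CE"` or focal loss
#' `"FL"`). Keyword shorthands of the experiment grid: RE (reconstruction
#' only), CE, FL (classification only), TOC = CE + RE, TOF = FL + RE.
#'
#' @param classification_loss One of `"CE"`, `"FL"`, `"none"`.
#' @param use_reconstruction Include the reconstruction MSE term?
#' @param focal_gamma Focusing parameter for the focal loss (>= 0).
#' @return A list of class `loss_config`.
#' @export
loss_config <- function(classification_loss = c("CE", "FL", "none"),
                        use_reconstruction = TRUE, focal_gamma = 2) {
  classification_loss <- match.arg(classification_loss)
  assert_that(focal_gamma >= 0, "focal_gamma must be >= 0")
  assert_that(use_reconstruction || classification_loss != "none",
              "at least one loss component must be enabled")
  structure(list(classification_loss = classification_loss,
                 use_reconstruction = isTRUE(use_reconstruction),
                 focal_gamma = focal_gamma),
            class = "loss_config")
}

# Map a grid keyword (CE/FL/RE/TOC/TOF) to a loss_config.
loss_config_from_keyword <- function(keyword, focal_gamma = 2) {
  switch(keyword,
         CE  = loss_config("CE", use_reconstruction = FALSE),
         FL  = loss_config("FL", use_reconstruction = FALSE,
                           focal_gamma = focal_gamma),
         RE  = loss_config("none", use_reconstruction = TRUE),
         TOC = loss_config("CE", use_reconstruction = TRUE),
         TOF = loss_config("FL", use_reconstruction = TRUE,
                           focal_gamma = focal_gamma),
         stop(sprintf("unknown loss keyword '%s' (use CE, FL, RE, TOC, TOF)",
                      keyword), call. = FALSE))
}

#' Training configuration
#'
#' Adam optimization of the summed loss with mini-batches and early stopping
#' on the validation total loss: training stops once no improvement greater
#' than `early_stopping_min_delta` has been seen for
#' `early_stopping_patience` epochs, and the best parameters are restored.
#' The validation split is carved out of the training data (stratified by
#' class when a classification loss is enabled). One seed drives every
#' stochastic component: initialization, shuffling, the validation
#' carve-out, and reparameterization noise.
#'
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param batch_size Mini-batch size (default 128).
#' @param max_epochs Maximum number of epochs (default 3000).
#' @param early_stopping_patience Epochs without improvement before stopping.
#' @param early_stopping_min_delta Minimum loss decrease that counts as
#'   improvement.
#' @param validation_fraction Fraction of training data held out for early
#'   stopping, in \[0, 1).
#' @param seed Integer seed.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 128L,
                         max_epochs = 3000L, early_stopping_patience = 50L,
                         early_stopping_min_delta = 1e-6,
                         validation_fraction = 0.1, seed = 1L) {
  assert_that(learning_rate > 0, "learning_rate must be positive")
  assert_that(batch_size >= 1, "batch_size must be positive")
  assert_that(max_epochs >= 1, "max_epochs must be positive")
  assert_that(early_stopping_patience >= 1 &&
                early_stopping_patience < max_epochs,
              "early_stopping_patience must be in [1, max_epochs)")
  assert_that(early_stopping_min_delta >= 0,
              "early_stopping_min_delta must be non-negative")
  assert_that(validation_fraction >= 0 && validation_fraction < 1,
              "validation_fraction must be in [0, 1)")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 early_stopping_min_delta = early_stopping_min_delta,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build an untrained joint autoencoder model
#'
#' Initializes all parameters (He-scaled Gaussian weights, zero biases)
#' reproducibly from `seed`.
#'
#' @param arch An [architecture_config()].
#' @param loss A [loss_config()].
#' @param seed Integer seed for initialization.
#' @return A list of class `joint_ae_model` with elements `architecture`,
#'   `loss_config`, `params`, `trained`.
#' @export
build_model <- function(arch, loss = loss_config(), seed = 1L) {
  assert_that(inherits(arch, "architecture_config"),
              "arch must be an architecture_config")
  assert_that(inherits(loss, "loss_config"), "loss must be a loss_config")
  params <- with_seed(seed, init_params(arch))
  structure(list(architecture = arch, loss_config = loss,
                 params = params, trained = FALSE),
            class = "joint_ae_model")
}

#' @export
print.joint_ae_model <- function(x, ...) {
  a <- x$architecture
  cat(sprintf("joint_ae_model (%s): %d -> [%s] -> code %d%s\n",
              if (a$variational) "VAE" else "AE", a$input_dim,
              paste(a$encoder_dims, collapse = ", "),
              a$encoder_dims[length(a$encoder_dims)],
              if (x$trained) " [trained]" else " [untrained]"))
  cat(sprintf("loss: %s%s\n", x$loss_config$classification_loss,
              if (x$loss_config$use_reconstruction) " + reconstruction" else ""))
  invisible(x)
}

as_input_matrix <- function(data) {
  if (inherits(data, "expression_dataset")) data$matrix else as.matrix(data)
}

#' Train the joint autoencoder
#'
#' Minimizes the configured total loss (reconstruction MSE, plus the KL term
#' for the variational model, plus cross-entropy or focal classification
#' loss on the code) with Adam, mini-batches, and early stopping on the
#' validation total loss. Inputs must be preprocessed to \[0, 1\] (see
#' [preprocess_for_ae()]). When the classification loss is disabled the
#' labels are never read, so label-free training is possible.
#'
#' @param model A [build_model()] result.
#' @param data An `expression_dataset` (preprocessed) or numeric matrix.
#' @param cfg A [train_config()].
#' @param labels Integer class codes; taken from `data` when it is an
#'   `expression_dataset`.
#' @return A list with `model` (trained) and `history` (data.frame of class
#'   `train_history` with columns `epoch`, `mse`, `classification_loss`,
#'   `kl`, `total`, and attribute `stopped_epoch`).
#' @export
train_joint <- function(model, data, cfg = train_config(), labels = NULL) {
  assert_that(inherits(model, "joint_ae_model"), "model must be a joint_ae_model")
  arch <- model$architecture
  loss_cfg <- model$loss_config
  x <- as_input_matrix(data)
  assert_that(ncol(x) == arch$input_dim,
              sprintf("data has %d genes but model expects %d",
                      ncol(x), arch$input_dim))
  assert_that(min(x) >= 0 && max(x) <= 1,
              "inputs must be preprocessed to [0, 1]; see preprocess_for_ae()")
  use_cls <- loss_cfg$classification_loss != "none"
  if (use_cls) {
    if (is.null(labels) && inherits(data, "expression_dataset"))
      labels <- data$labels
    assert_that(!is.null(labels) && length(labels) == nrow(x),
                "labels are required when a classification loss is enabled")
    labels <- as.integer(labels)
    assert_that(max(labels) <= arch$n_classes, "label code exceeds n_classes")
  }

  params <- model$params
  n <- nrow(x)
  history <- vector("list", cfg$max_epochs)

  result <- with_seed(cfg$seed, {
    # Validation carve-out. Stratified only when labels are in play so that
    # reconstruction-only training is label-independent.
    val_idx <- integer(0)
    if (cfg$validation_fraction > 0) {
      if (use_cls) {
        for (c in sort(unique(labels))) {
          idx <- which(labels == c)
          nv <- floor(cfg$validation_fraction * length(idx))
          if (nv > 0) val_idx <- c(val_idx, sample(idx, nv))
        }
        val_idx <- sort(val_idx)
      } else {
        nv <- floor(cfg$validation_fraction * n)
        if (nv > 0) val_idx <- sort(sample(n, nv))
      }
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    x_tr <- x[tr_idx, , drop = FALSE]
    x_val <- x[val_idx, , drop = FALSE]
    y_tr <- if (use_cls) labels[tr_idx] else NULL
    y_val <- if (use_cls) labels[val_idx] else NULL
    has_val <- length(val_idx) > 0

    state <- adam_init(params)
    best <- Inf
    best_params <- params
    wait <- 0L
    stopped_epoch <- cfg$max_epochs

    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(length(tr_idx))
      starts <- seq(1, length(ord), by = cfg$batch_size)
      acc <- c(mse = 0, kl = 0, classification = 0)
      seen <- 0L
      for (s in starts) {
        bi <- ord[s:min(s + cfg$batch_size - 1, length(ord))]
        xb <- x_tr[bi, , drop = FALSE]
        yb <- if (use_cls) y_tr[bi] else NULL
        eps <- if (arch$variational)
          matrix(stats::rnorm(length(bi) * arch$encoder_dims[length(arch$encoder_dims)]),
                 nrow = length(bi)) else NULL
        fwd <- joint_forward(params, arch, xb, eps = eps,
                             with_head = use_cls,
                             with_decoder = loss_cfg$use_reconstruction)
        bl <- batch_losses(fwd, xb, yb, arch, loss_cfg)
        for (comp in c("mse", "kl", "classification")) {
          v <- bl[[comp]]
          if (!is.na(v) && !is.finite(v))
            stop(sprintf("non-finite %s loss at epoch %d", comp, epoch),
                 call. = FALSE)
        }
        acc <- acc + length(bi) * c(bl$mse, bl$kl, bl$classification)
        seen <- seen + length(bi)
        grads <- joint_backward(params, arch, fwd, xb, yb, loss_cfg)
        stepped <- adam_step(params, grads, state, cfg$learning_rate)
        params <- stepped$params
        state <- stepped$state
      }
      ep <- acc / seen
      total <- sum(ep, na.rm = TRUE)
      history[[epoch]] <- data.frame(
        epoch = epoch,
        mse = ep[["mse"]],
        classification_loss = ep[["classification"]],
        kl = ep[["kl"]],
        total = total)

      monitor <- if (has_val) {
        vfwd <- joint_forward(params, arch, x_val, eps = NULL,
                              with_head = use_cls,
                              with_decoder = loss_cfg$use_reconstruction)
        batch_losses(vfwd, x_val, y_val, arch, loss_cfg)$total
      } else total
      if (!is.finite(monitor))
        stop(sprintf("non-finite validation loss at epoch %d", epoch),
             call. = FALSE)

      if (best - monitor > cfg$early_stopping_min_delta) {
        best <- monitor
        best_params <- params
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$early_stopping_patience) {
          stopped_epoch <- epoch
          break
        }
      }
      stopped_epoch <- epoch
    }
    list(params = best_params, stopped_epoch = stopped_epoch)
  })

  model$params <- result$params
  model$trained <- TRUE
  hist <- do.call(rbind, history[!vapply(history, is.null, logical(1))])
  rownames(hist) <- NULL
  attr(hist, "stopped_epoch") <- result$stopped_epoch
  class(hist) <- c("train_history", "data.frame")
  list(model = model, history = hist)
}

#' Extract low-dimensional features
#'
#' Deterministic forward pass through the trained encoder; the variational
#' model uses the posterior mean (no sampling at extraction time).
#'
#' @param model A trained `joint_ae_model`.
#' @param data An `expression_dataset` preprocessed with the training
#'   scaler, or a numeric matrix.
#' @return Numeric matrix, samples x code dimension.
#' @export
extract_features <- function(model, data) {
  assert_that(inherits(model, "joint_ae_model"), "model must be a joint_ae_model")
  x <- as_input_matrix(data)
  assert_that(ncol(x) == model$architecture$input_dim,
              sprintf("data has %d genes but model expects %d",
                      ncol(x), model$architecture$input_dim))
  enc <- encoder_forward(model$params, model$architecture, x, eps = NULL)
  feats <- enc$code
  rownames(feats) <- rownames(x)
  feats
}

#' Class probabilities from the classifier head
#'
#' Forward pass through encoder and head; used for end-to-end Shapley
#' attribution in gene space.
#'
#' @inheritParams extract_features
#' @return Matrix, samples x classes, rows summing to 1.
#' @export
predict_proba <- function(model, data) {
  x <- as_input_matrix(data)
  enc <- encoder_forward(model$params, model$architecture, x, eps = NULL)
  head_forward(model$params, enc$code)$probs
}

#' Save / load a model checkpoint
#'
#' A single-file checkpoint holding the architecture and loss configs and
#' all parameter arrays; reloading reproduces [extract_features()]
#' bit-identically.
#'
#' @param model A `joint_ae_model`.
#' @param path Checkpoint file path.
#' @return `save_model` returns `model` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  assert_that(inherits(model, "joint_ae_model"), "model must be a joint_ae_model")
  saveRDS(model, path)
  invisible(model)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  assert_that(inherits(model, "joint_ae_model"),
              "file does not contain a joint_ae_model")
  model
}

#' PCA / NMF baseline feature extraction
#'
#' Linear dimensionality-reduction baselines against which the autoencoder
#' features are compared. PCA is fit with [stats::prcomp()]; NMF minimizes
#' the Frobenius reconstruction error with Lee-Seung multiplicative updates
#' (NMF requires non-negative input, i.e. pre-log FPKM). Both are fit on the
#' training matrix and the fitted transform is applied to `newdata`.
#'
#' @param x Training matrix (samples x genes).
#' @param method `"PCA"` or `"NMF"`.
#' @param n_components Number of components (<= min(dim(x))).
#' @param newdata Optional matrix to transform with the train-fit model.
#' @param seed Seed for NMF initialization.
#' @param max_iter Maximum NMF update iterations.
#' @return List with `train` (features), `test` (when `newdata` given) and
#'   `fit` (the fitted transform).
#' @export
baseline_features <- function(x, method = c("PCA", "NMF"), n_components,
                              newdata = NULL, seed = 1L, max_iter = 200L) {
  method <- match.arg(method)
  x <- as_input_matrix(x)
  assert_that(n_components >= 1 && n_components <= min(dim(x)),
              "n_components must be in [1, min(n_samples, n_genes)]")
  if (method == "PCA") {
    fit <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
    train <- fit$x[, seq_len(n_components), drop = FALSE]
    test <- if (!is.null(newdata))
      scale(as_input_matrix(newdata), center = fit$center, scale = FALSE) %*%
        fit$rotation[, seq_len(n_components), drop = FALSE]
  } else {
    assert_that(min(x) >= 0, "NMF requires non-negative input")
    fit <- nmf_fit(x, n_components, seed = seed, max_iter = max_iter)
    train <- fit$W
    test <- if (!is.null(newdata))
      nmf_transform(fit, as_input_matrix(newdata), seed = seed,
                    max_iter = max_iter)
  }
  out <- list(train = train, fit = fit, method = method)
  if (!is.null(newdata)) out$test <- test
  out
}

# Lee-Seung multiplicative updates, Frobenius objective: X ~ W H,
# W (n x k) >= 0, H (k x d) >= 0.
nmf_fit <- function(x, k, seed = 1L, max_iter = 200L, tol = 1e-6) {
  n <- nrow(x); d <- ncol(x)
  eps <- 1e-10
  sc <- sqrt(mean(x) / k)
  with_seed(seed, {
    W <- matrix(stats::runif(n * k), n, k) * sc
    H <- matrix(stats::runif(k * d), k, d) * sc
    err_prev <- Inf
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, x)) / (crossprod(W, W %*% H) + eps)
      W <- W * (x %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
      if (it %% 10 == 0) {
        err <- mean((x - W %*% H)^2)
        if (err_prev - err < tol * err_prev) break
        err_prev <- err
      }
    }
    list(W = W, H = H)
  })
}

# Project new non-negative data onto fixed H by updating W only.
nmf_transform <- function(fit, x, seed = 1L, max_iter = 200L) {
  H <- fit$H
  eps <- 1e-10
  with_seed(seed, {
    W <- matrix(stats::runif(nrow(x) * nrow(H)), nrow(x), nrow(H)) *
      sqrt(mean(x) / nrow(H))
    for (it in seq_len(max_iter))
      W <- W * (x %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
    W
  })
}
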