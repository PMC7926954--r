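# Internal dense-network machinery for the joint autoencoder: parameter
# initialization, forward passes with caches, exact backprop for the summed
# objective, and an Adam optimizer. Written against base matrix ops (BLAS);
# correctness is pinned by a finite-difference gradient-check test.

relu <- function(z) {
  z[z < 0] <- 0
  z
}

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

init_dense <- function(n_in, n_out) {
  # He-style scaling, suited to ReLU hidden units
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)),
                  nrow = n_in, ncol = n_out),
       b = numeric(n_out))
}

dense <- function(a, layer) {
  sweep(a %*% layer$W, 2, layer$b, "+")
}

init_params <- function(arch) {
  enc_dims <- arch$encoder_dims
  dec_dims <- arch$decoder_dims
  p <- list()
  if (arch$variational) {
    hidden <- enc_dims[-length(enc_dims)]
    code_dim <- enc_dims[length(enc_dims)]
    dims <- c(arch$input_dim, hidden)
    p$encoder <- lapply(seq_len(length(dims) - 1),
                        function(i) init_dense(dims[i], dims[i + 1]))
    last_hidden <- dims[length(dims)]
    p$mu <- init_dense(last_hidden, code_dim)
    p$logvar <- init_dense(last_hidden, code_dim)
  } else {
    dims <- c(arch$input_dim, enc_dims)
    p$encoder <- lapply(seq_len(length(dims) - 1),
                        function(i) init_dense(dims[i], dims[i + 1]))
  }
  code_dim <- enc_dims[length(enc_dims)]
  ddims <- c(code_dim, dec_dims, arch$input_dim)
  p$decoder <- lapply(seq_len(length(ddims) - 1),
                      function(i) init_dense(ddims[i], ddims[i + 1]))
  p$head <- list(init_dense(code_dim, arch$head_hidden_dim),
                 init_dense(arch$head_hidden_dim, arch$n_classes))
  p
}

# Forward passes ------------------------------------------------------------

# Encoder. For the variational model, `eps` (a matrix of standard-normal
# draws) triggers reparameterized sampling; eps = NULL gives the
# deterministic code (mu), used at extraction and validation time.
encoder_forward <- function(params, arch, x, eps = NULL) {
  cache <- list(a = list(x), z = list())
  a <- x
  for (i in seq_along(params$encoder)) {
    z <- dense(a, params$encoder[[i]])
    a <- relu(z)
    cache$z[[i]] <- z
    cache$a[[i + 1]] <- a
  }
  if (arch$variational) {
    cache$mu <- dense(a, params$mu)
    cache$logvar <- dense(a, params$logvar)
    cache$eps <- eps
    cache$code <- if (is.null(eps)) cache$mu
                  else cache$mu + exp(0.5 * cache$logvar) * eps
  } else {
    cache$code <- a
  }
  cache
}

decoder_forward <- function(params, code) {
  cache <- list(a = list(code), z = list())
  a <- code
  n_layers <- length(params$decoder)
  for (i in seq_len(n_layers)) {
    z <- dense(a, params$decoder[[i]])
    a <- if (i < n_layers) relu(z) else sigmoid(z)
    cache$z[[i]] <- z
    cache$a[[i + 1]] <- a
  }
  cache$recon <- a
  cache
}

head_forward <- function(params, code) {
  z1 <- dense(code, params$head[[1]])
  h1 <- relu(z1)
  logits <- dense(h1, params$head[[2]])
  list(z1 = z1, h1 = h1, logits = logits, probs = softmax_rows(logits))
}

joint_forward <- function(params, arch, x, eps = NULL, with_head = TRUE,
                          with_decoder = TRUE) {
  enc <- encoder_forward(params, arch, x, eps)
  dec <- if (with_decoder) decoder_forward(params, enc$code) else NULL
  head <- if (with_head) head_forward(params, enc$code) else NULL
  list(enc = enc, dec = dec, head = head)
}

# Loss gradients wrt network outputs ----------------------------------------

# d(mean CE or FL)/d(logits); labels in 1..K
classification_logit_grad <- function(probs, labels, loss_cfg) {
  n <- nrow(probs)
  onehot <- matrix(0, n, ncol(probs))
  onehot[cbind(seq_len(n), labels)] <- 1
  if (loss_cfg$classification_loss == "CE") {
    (probs - onehot) / n
  } else {
    pt <- pmax(probs[cbind(seq_len(n), labels)], PROB_EPS)
    omt <- pmax(1 - pt, PROB_EPS)  # keeps omt^(g-1) finite for g < 1
    g <- loss_cfg$focal_gamma
    dldp <- if (g == 0) -1 / pt
            else g * omt^(g - 1) * log(pt) - omt^g / pt
    (dldp * pt) * (onehot - probs) / n
  }
}

# Backward pass: returns gradients in the same structure as params.
joint_backward <- function(params, arch, fwd, x, labels, loss_cfg) {
  grads <- list()
  code <- fwd$enc$code
  n <- nrow(x)
  dcode <- matrix(0, nrow(code), ncol(code))

  if (loss_cfg$classification_loss != "none") {
    dlogits <- classification_logit_grad(fwd$head$probs, labels, loss_cfg)
    gW2 <- crossprod(fwd$head$h1, dlogits)
    gb2 <- colSums(dlogits)
    dh1 <- dlogits %*% t(params$head[[2]]$W)
    dz1 <- dh1 * (fwd$head$z1 > 0)
    gW1 <- crossprod(code, dz1)
    gb1 <- colSums(dz1)
    grads$head <- list(list(W = gW1, b = gb1), list(W = gW2, b = gb2))
    dcode <- dcode + dz1 %*% t(params$head[[1]]$W)
  } else {
    grads$head <- zero_like(params$head)
  }

  if (loss_cfg$use_reconstruction) {
    recon <- fwd$dec$recon
    drecon <- 2 * (recon - x) / (n * ncol(x))
    grads$decoder <- vector("list", length(params$decoder))
    da <- drecon
    for (i in rev(seq_along(params$decoder))) {
      z <- fwd$dec$z[[i]]
      dz <- if (i == length(params$decoder)) {
        s <- fwd$dec$a[[i + 1]]
        da * s * (1 - s)
      } else {
        da * (z > 0)
      }
      grads$decoder[[i]] <- list(W = crossprod(fwd$dec$a[[i]], dz),
                                 b = colSums(dz))
      da <- dz %*% t(params$decoder[[i]]$W)
    }
    dcode <- dcode + da
  } else {
    grads$decoder <- zero_like(params$decoder)
  }

  if (arch$variational) {
    mu <- fwd$enc$mu
    lv <- fwd$enc$logvar
    dmu <- dcode
    dlv <- if (!is.null(fwd$enc$eps))
      dcode * fwd$enc$eps * 0.5 * exp(0.5 * lv)
    else matrix(0, nrow(lv), ncol(lv))
    if (loss_cfg$use_reconstruction) {
      # KL regularizer rides with the reconstruction term
      dmu <- dmu + mu / n
      dlv <- dlv + 0.5 * (exp(lv) - 1) / n
    }
    h <- fwd$enc$a[[length(fwd$enc$a)]]
    grads$mu <- list(W = crossprod(h, dmu), b = colSums(dmu))
    grads$logvar <- list(W = crossprod(h, dlv), b = colSums(dlv))
    da <- dmu %*% t(params$mu$W) + dlv %*% t(params$logvar$W)
  } else {
    da <- dcode
  }

  grads$encoder <- vector("list", length(params$encoder))
  for (i in rev(seq_along(params$encoder))) {
    dz <- da * (fwd$enc$z[[i]] > 0)
    grads$encoder[[i]] <- list(W = crossprod(fwd$enc$a[[i]], dz),
                               b = colSums(dz))
    da <- dz %*% t(params$encoder[[i]]$W)
  }

  grads[names(params)]
}

zero_like <- function(p) {
  if (is.list(p) && !is.null(p$W))
    return(list(W = array(0, dim(p$W)), b = numeric(length(p$b))))
  lapply(p, zero_like)
}

# Adam ----------------------------------------------------------------------

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p) && !is.null(p$W)) {
      m$W <- beta1 * m$W + (1 - beta1) * g$W
      m$b <- beta1 * m$b + (1 - beta1) * g$b
      v$W <- beta2 * v$W + (1 - beta2) * g$W^2
      v$b <- beta2 * v$b + (1 - beta2) * g$b^2
      mh_W <- m$W / (1 - beta1^t); mh_b <- m$b / (1 - beta1^t)
      vh_W <- v$W / (1 - beta2^t); vh_b <- v$b / (1 - beta2^t)
      p$W <- p$W - lr * mh_W / (sqrt(vh_W) + eps)
      p$b <- p$b - lr * mh_b / (sqrt(vh_b) + eps)
      return(list(p = p, m = m, v = v))
    }
    out <- Map(upd, p, g, m, v)
    list(p = lapply(out, `[[`, "p"),
         m = lapply(out, `[[`, "m"),
         v = lapply(out, `[[`, "v"))
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}

# Batch losses under a loss config; returns the components actually enabled.
batch_losses <- function(fwd, x, labels, arch, loss_cfg) {
  mse <- if (loss_cfg$use_reconstruction)
    reconstruction_mse(x, fwd$dec$recon) else NA_real_
  kl <- if (arch$variational && loss_cfg$use_reconstruction)
    kl_divergence_gaussian(fwd$enc$mu, fwd$enc$logvar) else NA_real_
  cls <- switch(loss_cfg$classification_loss,
                CE = cross_entropy(fwd$head$probs, labels),
                FL = focal_loss(fwd$head$probs, labels, loss_cfg$focal_gamma),
                none = NA_real_)
  total <- sum(c(mse, kl, cls), na.rm = TRUE)
  list(mse = mse, kl = kl, classification = cls, total = total)
}
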