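#' Specification of a synthetic FPKM dataset
#'
#' Describes the generative model used by [generate_synthetic()]: a
#' high-dimensional non-negative expression matrix with imbalanced classes,
#' a small block of class-discriminative signal genes per class, and
#' log-normal noise everywhere. Defaults mirror the hematopoietic cancer
#' study composition: five subtypes (LL, ML, NO, MB, PC) with sizes
#' 550/818/104/113/860.
#'
#' @param class_sizes Positive integer vector of per-class sample counts.
#' @param n_genes Total number of genes.
#' @param n_signal_genes_per_class Number of genes whose log-mean is elevated
#'   in each class.
#' @param signal_effect Additive shift (natural-log scale) applied to a
#'   class's signal genes. 0 produces pure noise.
#' @param noise_sd Standard deviation of log-expression noise.
#' @param base_log_mean Baseline log-expression mean shared by all genes.
#' @param class_names Optional subtype names; defaults to LL/ML/NO/MB/PC for
#'   five classes.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#'
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(class_sizes = c(550L, 818L, 104L, 113L, 860L),
                           n_genes = 2000L,
                           n_signal_genes_per_class = 10L,
                           signal_effect = 2.0,
                           noise_sd = 1.0,
                           base_log_mean = 1.0,
                           class_names = NULL,
                           seed = 1L) {
  class_sizes <- as.integer(class_sizes)
  assert_that(length(class_sizes) >= 1 && all(class_sizes >= 1),
              "class_sizes must be positive integers")
  assert_that(n_genes >= 1, "n_genes must be positive")
  assert_that(n_signal_genes_per_class >= 1,
              "n_signal_genes_per_class must be positive")
  assert_that(n_signal_genes_per_class * length(class_sizes) <= n_genes,
              "n_signal_genes_per_class * n_classes must be <= n_genes")
  assert_that(signal_effect >= 0, "signal_effect must be non-negative")
  assert_that(noise_sd > 0, "noise_sd must be positive")
  if (is.null(class_names)) {
    class_names <- if (length(class_sizes) == 5)
      c("LL", "ML", "NO", "MB", "PC")
    else paste0("C", seq_along(class_sizes))
  }
  assert_that(length(class_names) == length(class_sizes),
              "class_names must match class_sizes in length")
  structure(list(class_sizes = class_sizes,
                 n_genes = as.integer(n_genes),
                 n_signal_genes_per_class = as.integer(n_signal_genes_per_class),
                 signal_effect = signal_effect,
                 noise_sd = noise_sd,
                 base_log_mean = base_log_mean,
                 class_names = as.character(class_names),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic FPKM expression dataset
#'
#' Log-expression of every entry is drawn Normal(`base_log_mean`,
#' `noise_sd`); for class `c` the log-mean of its `n_signal_genes_per_class`
#' designated genes is elevated by `signal_effect`. Values are exponentiated
#' to the non-negative FPKM scale. Signal-gene blocks are disjoint across
#' classes (class `c` owns genes `(c-1)*m + 1 .. c*m`); their IDs are
#' attached as the `signal_genes` attribute of the result for downstream
#' recovery checks. Fully reproducible from `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return An [expression_dataset()] with attribute `signal_genes`, a named
#'   list (one character vector of gene IDs per class).
#' @export
generate_synthetic <- function(spec) {
  assert_that(inherits(spec, "synthetic_spec"),
              "spec must be a synthetic_spec")
  k <- length(spec$class_sizes)
  n <- sum(spec$class_sizes)
  g <- spec$n_genes
  m <- spec$n_signal_genes_per_class
  labels <- rep(seq_len(k), spec$class_sizes)
  gene_ids <- sprintf("ENSG%011d.1", seq_len(g))

  mat <- with_seed(spec$seed, {
    logx <- matrix(stats::rnorm(n * g, mean = spec$base_log_mean,
                                sd = spec$noise_sd), nrow = n, ncol = g)
    for (c in seq_len(k)) {
      genes <- ((c - 1L) * m + 1L):(c * m)
      rows <- which(labels == c)
      logx[rows, genes] <- logx[rows, genes] + spec$signal_effect
    }
    exp(logx)
  })

  ds <- expression_dataset(mat, gene_ids, labels,
                           class_names = spec$class_names)
  attr(ds, "signal_genes") <- stats::setNames(
    lapply(seq_len(k), function(c) gene_ids[((c - 1L) * m + 1L):(c * m)]),
    spec$class_names)
  ds
}

#' Read/write a synthetic spec as a flat YAML config
#'
#' @param path File path.
#' @return `read_synthetic_spec` returns a [synthetic_spec()];
#'   `write_synthetic_spec` returns `spec` invisibly.
#' @export
read_synthetic_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(synthetic_spec, cfg)
}

#' @rdname read_synthetic_spec
#' @param spec A [synthetic_spec()].
#' @export
write_synthetic_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(spec)
}
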