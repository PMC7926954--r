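# Shared fixture builders. Everything is generated in code at test time.

# Well-separated Gaussian blobs in `d` dimensions, one blob per class.
make_blobs <- function(n_per_class, d = 2, sep = 6, sd = 0.5, seed = 1) {
  k <- length(n_per_class)
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", .GlobalEnv)) .GlobalEnv$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed); expr
  }
  withr_seed({
    centers <- matrix(stats::rnorm(k * d), k, d) * sep
    x <- do.call(rbind, lapply(seq_len(k), function(c)
      matrix(stats::rnorm(n_per_class[c] * d, sd = sd), ncol = d) +
        matrix(centers[c, ], n_per_class[c], d, byrow = TRUE)))
    list(x = x, y = factor(rep(seq_len(k), n_per_class)))
  })
}

# Small dataset with planted class signal, for autoencoder tests.
small_signal_spec <- function(seed = 1, sizes = c(40, 60, 15, 15, 70),
                              n_genes = 120, effect = 3) {
  synthetic_spec(class_sizes = sizes, n_genes = n_genes,
                 n_signal_genes_per_class = 8, signal_effect = effect,
                 noise_sd = 1, seed = seed)
}

tiny_arch <- function(input_dim, n_classes = 3, variational = FALSE) {
  architecture_config(input_dim = input_dim, n_classes = n_classes,
                      encoder_dims = c(8L, 5L), decoder_dims = c(5L, 8L),
                      head_hidden_dim = 4L, variational = variational)
}

# Write a tiny expression matrix + labels pair to temp files.
write_fixture_files <- function(mat, sample_ids, gene_ids, subtypes) {
  mp <- tempfile(fileext = ".tsv")
  lp <- tempfile(fileext = ".tsv")
  header <- paste(c("sample_id", gene_ids), collapse = "\t")
  rows <- vapply(seq_len(nrow(mat)), function(i)
    paste(c(sample_ids[i], mat[i, ]), collapse = "\t"), character(1))
  writeLines(c(header, rows), mp)
  writeLines(c("sample_id\tsubtype",
               paste(subtypes$sample_id, subtypes$subtype, sep = "\t")), lp)
  list(matrix = mp, labels = lp)
}
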