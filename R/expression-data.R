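#' Construct an expression dataset
#'
#' The universal input container of the package: a samples x genes matrix of
#' non-negative FPKM-scale expression values together with per-sample subtype
#' labels. Labels are stored as integer codes indexing `class_names`.
#'
#' @param matrix Numeric matrix, samples in rows, genes in columns. All
#'   entries must be finite and non-negative.
#' @param gene_ids Character vector of unique gene identifiers, one per
#'   column (Ensembl-style versioned IDs in real data).
#' @param labels Per-sample subtype labels: a factor, a character vector of
#'   subtype names, or integer codes into `class_names`.
#' @param class_names Ordered character vector of subtype names. Inferred
#'   from `labels` when omitted.
#' @param sample_ids Optional character vector of sample identifiers.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `matrix`, `gene_ids`, `labels` (integer codes), `class_names` and
#'   `sample_ids`.
#' @export
expression_dataset <- function(matrix, gene_ids, labels, class_names = NULL,
                               sample_ids = NULL) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  assert_that(all(is.finite(matrix)),
              "expression matrix contains missing or non-finite values")
  assert_that(all(matrix >= 0), "expression matrix contains negative values")
  gene_ids <- as.character(gene_ids)
  assert_that(length(gene_ids) == ncol(matrix),
              sprintf("length(gene_ids) == %d but matrix has %d genes",
                      length(gene_ids), ncol(matrix)))
  assert_that(!anyDuplicated(gene_ids), "gene_ids must be unique")

  if (is.factor(labels)) {
    if (is.null(class_names)) class_names <- levels(labels)
    labels <- as.character(labels)
  }
  if (is.character(labels)) {
    if (is.null(class_names)) class_names <- sort(unique(labels))
    codes <- match(labels, class_names)
    assert_that(!anyNA(codes), "labels contain subtypes absent from class_names")
    labels <- codes
  } else {
    labels <- as.integer(labels)
    if (is.null(class_names)) class_names <- paste0("C", seq_len(max(labels)))
  }
  assert_that(length(labels) == nrow(matrix),
              sprintf("length(labels) == %d but matrix has %d samples",
                      length(labels), nrow(matrix)))
  assert_that(all(labels >= 1L & labels <= length(class_names)),
              "labels must index class_names")
  if (is.null(sample_ids)) sample_ids <- rownames(matrix) %||%
      paste0("S", seq_len(nrow(matrix)))
  colnames(matrix) <- gene_ids
  rownames(matrix) <- sample_ids

  structure(list(matrix = matrix, gene_ids = gene_ids,
                 labels = labels, class_names = as.character(class_names),
                 sample_ids = as.character(sample_ids)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d samples x %d genes, %d subtypes\n",
              nrow(x$matrix), ncol(x$matrix), length(x$class_names)))
  tab <- table(factor(x$class_names[x$labels], levels = x$class_names))
  print(tab)
  invisible(x)
}

#' Number of samples / genes in an expression dataset
#' @param ds An `expression_dataset`.
#' @return Integer count.
#' @export
n_samples <- function(ds) nrow(ds$matrix)

#' @rdname n_samples
#' @export
n_genes <- function(ds) ncol(ds$matrix)

#' Labels as a factor with subtype-name levels
#' @param ds An `expression_dataset`.
#' @return Factor of length `n_samples(ds)`.
#' @export
label_factor <- function(ds) factor(ds$class_names[ds$labels], levels = ds$class_names)

# Row-subset of a dataset, preserving class_names so that train/test halves
# share one label alphabet even when a class is absent from one side.
subset_samples <- function(ds, idx) {
  expression_dataset(ds$matrix[idx, , drop = FALSE], ds$gene_ids,
                     ds$labels[idx], class_names = ds$class_names,
                     sample_ids = ds$sample_ids[idx])
}

#' Compute FPKM from fragment counts
#'
#' Fragments per kilobase of exon per million mapped reads:
#' `counts / (mapped_reads_millions * exon_length_kb)`, the standard
#' length- and depth-normalized RNA-seq expression estimate.
#'
#' @param fragment_counts Non-negative numeric vector: fragments mapped to
#'   each gene.
#' @param exon_lengths_kb Positive numeric vector: total exon length of each
#'   gene in kilobases.
#' @param mapped_reads_millions Positive scalar: library size in millions of
#'   mapped reads.
#'
#' @return Numeric vector of FPKM values, same length as `fragment_counts`.
#' @examples
#' compute_fpkm(1000, 2, 10)      # 50
#' compute_fpkm(c(7, 7), c(1, 7), 1)
#' @export
compute_fpkm <- function(fragment_counts, exon_lengths_kb, mapped_reads_millions) {
  assert_that(length(fragment_counts) == length(exon_lengths_kb),
              "fragment_counts and exon_lengths_kb must have equal length")
  assert_that(is.numeric(mapped_reads_millions) && length(mapped_reads_millions) == 1,
              "mapped_reads_millions must be a single number")
  if (mapped_reads_millions <= 0)
    stop("mapped_reads_millions must be > 0", call. = FALSE)
  bad <- which(exon_lengths_kb <= 0)
  if (length(bad))
    stop(sprintf("non-positive exon length for gene index %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  bad <- which(fragment_counts < 0)
  if (length(bad))
    stop(sprintf("negative fragment count for gene index %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  fragment_counts / (mapped_reads_millions * exon_lengths_kb)
}

#' Read an expression matrix and labels from delimited text
#'
#' The matrix file has a header row of gene IDs and one sample per row with a
#' leading sample-ID column; the labels file has two columns
#' (sample ID, subtype name). Samples whose expression row contains any
#' missing, non-numeric or negative value are dropped with a message, the
#' standard "eliminate noisy and non-valued instances" preprocessing.
#'
#' @param matrix_path Path to the TSV/CSV expression matrix.
#' @param labels_path Path to the two-column TSV/CSV label file.
#'
#' @return An [expression_dataset()].
#' @export
read_expression <- function(matrix_path, labels_path) {
  dt <- data.table::fread(matrix_path, header = TRUE, data.table = FALSE)
  assert_that(ncol(dt) >= 2, "expression matrix must have >= 1 gene column")
  sample_ids <- as.character(dt[[1]])
  gene_ids <- colnames(dt)[-1]
  mat <- suppressWarnings(
    vapply(dt[-1], function(col) as.numeric(as.character(col)),
           numeric(nrow(dt))))
  mat <- matrix(mat, nrow = nrow(dt),
                dimnames = list(sample_ids, gene_ids))

  ok <- apply(mat, 1, function(r) all(is.finite(r)) && all(r >= 0))
  if (any(!ok))
    message(sprintf("read_expression: dropped %d of %d samples with missing/invalid values",
                    sum(!ok), length(ok)))
  if (!any(ok)) stop("no samples left after removing invalid rows", call. = FALSE)
  mat <- mat[ok, , drop = FALSE]
  sample_ids <- sample_ids[ok]

  lab <- data.table::fread(labels_path, header = TRUE, data.table = FALSE)
  if (ncol(lab) < 2) stop("labels file must have two columns", call. = FALSE)
  lab_ids <- as.character(lab[[1]])
  unmatched <- setdiff(sample_ids, lab_ids)
  if (length(unmatched))
    stop(sprintf("samples missing from labels file: %s",
                 paste(unmatched, collapse = ", ")), call. = FALSE)
  subtype <- as.character(lab[[2]])[match(sample_ids, lab_ids)]

  expression_dataset(mat, gene_ids, subtype, sample_ids = sample_ids)
}

#' Write an expression dataset to delimited text
#'
#' Inverse of [read_expression()]: writes the matrix with a leading
#' `sample_id` column and gene-ID header, and a two-column label file.
#'
#' @param ds An `expression_dataset`.
#' @param matrix_path,labels_path Output paths (TSV).
#' @return `ds`, invisibly.
#' @export
write_expression <- function(ds, matrix_path, labels_path) {
  out <- data.frame(sample_id = ds$sample_ids, ds$matrix,
                    check.names = FALSE)
  data.table::fwrite(out, matrix_path, sep = "\t")
  lab <- data.frame(sample_id = ds$sample_ids,
                    subtype = ds$class_names[ds$labels])
  data.table::fwrite(lab, labels_path, sep = "\t")
  invisible(ds)
}

#' Stratified train/test split
#'
#' Splits per class: each class contributes `floor(train_fraction * n_c)`
#' samples to the training set (matching the 80/20 convention that yields
#' train counts 440/654/83/90/688 for class sizes 550/818/104/113/860), the
#' remainder to the test set. Assignment within a class is randomized by
#' `seed`; the same seed always reproduces the same split.
#'
#' @param ds An `expression_dataset`.
#' @param train_fraction Fraction in (0, 1) of each class assigned to train.
#' @param seed Integer seed for the within-class shuffle.
#'
#' @return A list of class `split_result` with elements `train`, `test`
#'   (both `expression_dataset`), `train_fraction`, `train_indices`,
#'   `test_indices`.
#' @export
stratified_split <- function(ds, train_fraction = 0.8, seed = 1L) {
  assert_that(train_fraction > 0 && train_fraction < 1,
              "train_fraction must be in (0, 1)")
  counts <- tabulate(ds$labels, nbins = length(ds$class_names))
  if (any(counts == 0))
    stop(sprintf("class with 0 samples: %s",
                 paste(ds$class_names[counts == 0], collapse = ", ")),
         call. = FALSE)
  train_idx <- integer(0)
  with_seed(seed, {
    for (c in seq_along(ds$class_names)) {
      idx <- which(ds$labels == c)
      n_train <- floor(train_fraction * length(idx))
      train_idx <- c(train_idx, sample(idx, n_train))
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n_samples(ds)), train_idx)
  structure(list(train = subset_samples(ds, train_idx),
                 test = subset_samples(ds, test_idx),
                 train_fraction = train_fraction,
                 train_indices = train_idx, test_indices = test_idx),
            class = "split_result")
}

#' Log/min-max preprocessing for the autoencoder
#'
#' Applies `log2(x + 1)` followed by per-gene min-max scaling to \[0, 1\].
#' Scaling statistics are fit on the training data only and returned so that
#' test data can be transformed with the training parameters; values of new
#' data falling outside the training range are clipped to \[0, 1\], matching
#' the sigmoid-bounded decoder output. Genes constant on the training data
#' are mapped to all-zeros (reported via a message).
#'
#' @param ds An `expression_dataset` (FPKM scale).
#' @param scaler Optional scaler returned by a previous call; when supplied,
#'   `ds` is transformed with those (training) statistics instead of
#'   refitting.
#'
#' @return A list with elements `dataset` (the transformed
#'   `expression_dataset`) and `scaler` (list with `min`, `max`, `constant`).
#' @export
preprocess_for_ae <- function(ds, scaler = NULL) {
  lg <- log2(ds$matrix + 1)
  if (is.null(scaler)) {
    mins <- apply(lg, 2, min)
    maxs <- apply(lg, 2, max)
    constant <- maxs == mins
    if (any(constant))
      message(sprintf("preprocess_for_ae: %d constant gene(s) scaled to zero",
                      sum(constant)))
    scaler <- list(min = mins, max = maxs, constant = constant)
  }
  rng <- scaler$max - scaler$min
  rng[scaler$constant] <- 1
  scaled <- sweep(sweep(lg, 2, scaler$min), 2, rng, "/")
  scaled[, scaler$constant] <- 0
  scaled[scaled < 0] <- 0
  scaled[scaled > 1] <- 1
  out <- ds
  out$matrix <- scaled
  list(dataset = out, scaler = scaler)
}
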