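#' Construct a count matrix with a sample sheet
#'
#' The container shared by the ATAC and RNA differential stages: an integer
#' matrix of features (regions or genes) by samples plus a sample sheet
#' describing each column. Library sizes default to column sums.
#'
#' @param counts Integer matrix, features x samples, with dimnames.
#' @param samples Tibble with at least a `sample` column matching
#'   `colnames(counts)`; typically also `condition`, `genotype`, `replicate`.
#' @param lib_sizes Optional named numeric vector of library sizes.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, samples, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("count_matrix requires row and column names")
  }
  samples <- as_tibble(samples)
  if (!"sample" %in% names(samples)) abort("sample sheet needs a 'sample' column")
  if (!setequal(samples$sample, colnames(counts)) ||
      nrow(samples) != ncol(counts)) {
    abort("sample sheet does not match count matrix columns")
  }
  samples <- samples[match(colnames(counts), samples$sample), ]
  if (any(counts < 0)) abort("counts must be non-negative")
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  lib_sizes <- lib_sizes[colnames(counts)]
  structure(
    list(counts = counts, samples = samples, lib_sizes = lib_sizes),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(x$samples, n = 6)
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Tidy a count matrix into long form
#' @param x A `count_matrix`.
#' @param ... Unused.
#' @return Long tibble: `feature, sample, count` plus sample-sheet columns.
#' @export
tidy.count_matrix <- function(x, ...) {
  long <- as_tibble(x$counts, rownames = "feature")
  long <- pivot_longer(long, -"feature", names_to = "sample", values_to = "count")
  left_join(long, x$samples, by = "sample")
}

#' Counts per million
#'
#' Scales every sample (column) to a library of one million using the stored
#' library sizes, so each column of the result sums to 1e6 when library sizes
#' are the column sums.
#'
#' @param x A `count_matrix` or plain matrix.
#' @param lib_sizes Library sizes when `x` is a plain matrix (default column
#'   sums).
#' @return Numeric matrix of CPM values.
#' @export
cpm <- function(x, lib_sizes = NULL) {
  if (inherits(x, "count_matrix")) {
    m <- x$counts
    lib_sizes <- x$lib_sizes
  } else {
    m <- as.matrix(x)
    if (is.null(lib_sizes)) lib_sizes <- colSums(m)
  }
  zero <- which(lib_sizes <= 0)
  if (length(zero) > 0) {
    nm <- names(lib_sizes)[zero[1]] %||% as.character(zero[1])
    abort(paste0("cpm: zero library size for sample ", nm))
  }
  sweep(m, 2, lib_sizes, "/") * 1e6
}

#' Write / read a count matrix as TSV (counts + sample sheet)
#' @param x A `count_matrix`.
#' @param counts_path,samples_path Output paths.
#' @return `counts_path`, invisibly.
#' @export
write_count_matrix <- function(x, counts_path, samples_path) {
  readr::write_tsv(as_tibble(x$counts, rownames = "feature"), counts_path,
                   progress = FALSE)
  readr::write_tsv(mutate(x$samples, lib_size = unname(x$lib_sizes)),
                   samples_path, progress = FALSE)
  invisible(counts_path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  ct <- readr::read_tsv(counts_path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(ct[, -1])
  rownames(m) <- ct[[1]]
  storage.mode(m) <- "integer"
  ss <- readr::read_tsv(samples_path, show_col_types = FALSE, progress = FALSE)
  lib <- NULL
  if ("lib_size" %in% names(ss)) {
    lib <- setNames(ss$lib_size, ss$sample)
    ss$lib_size <- NULL
  }
  count_matrix(m, ss, lib_sizes = lib)
}
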