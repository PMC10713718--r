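#' Genomic intervals as tibbles
#'
#' Throughout t3chrom a set of genomic intervals is an ordinary tibble with at
#' least the columns `chrom` (character), `start` and `end` (0-based,
#' half-open, so a single base at position p is `start = p, end = p + 1`).
#' Extra columns (`name`, `score`, `strand`, per-condition signal, category
#' labels, ...) ride along untouched. `as_intervals()` validates and sorts.
#'
#' @param x A data frame with columns `chrom`, `start`, `end`.
#' @param sort Sort by `(chrom, start, end)`? Default `TRUE`.
#' @return A tibble of validated intervals.
#' @examples
#' as_intervals(data.frame(chrom = "chr1", start = 100, end = 200))
#' @export
as_intervals <- function(x, sort = TRUE) {
  x <- as_tibble(x)
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("interval table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  validate_intervals(x)
  if (sort) x <- arrange(x, .data$chrom, .data$start, .data$end)
  x
}

validate_intervals <- function(x) {
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    abort("interval validation: empty or NA chromosome name")
  }
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    abort(sprintf(
      "interval validation: start/end invariant violated (0 <= start < end) at row(s) %s",
      paste(head(bad, 5), collapse = ", ")))
  }
  invisible(x)
}

#' Pairwise overlap length of two interval sets
#'
#' Vectorised over rows: `a` and `b` must have one row each or equal row
#' counts. Intervals on different chromosomes overlap by 0; half-open
#' convention means abutting intervals ([0,100) vs [100,200)) overlap by 0.
#'
#' @param a,b Interval tibbles (see [as_intervals()]), recycled if single-row.
#' @return Integer vector of overlap lengths, `>= 0`.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
#' b <- tibble::tibble(chrom = "chr1", start = 50, end = 150)
#' overlap_length(a, b)  # 50
#' @export
overlap_length <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1) a <- a[rep(1L, n), ]
  if (nrow(b) == 1) b <- b[rep(1L, n), ]
  stopifnot(nrow(a) == nrow(b))
  ov <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  as.integer(ifelse(a$chrom == b$chrom, ov, 0L))
}

# Internal: tibble intervals -> GRanges (1-based closed) and back.
intervals_to_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

gr_to_intervals <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

# Internal: error if intervals within one set overlap each other.
assert_nonoverlapping <- function(x, label = "interval set") {
  if (nrow(x) < 2) return(invisible(x))
  x <- arrange(x, .data$chrom, .data$start)
  same <- x$chrom == dplyr::lag(x$chrom)
  clash <- same & (x$start < dplyr::lag(x$end))
  if (any(clash, na.rm = TRUE)) {
    abort(sprintf("%s contains internally overlapping intervals", label))
  }
  invisible(x)
}
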