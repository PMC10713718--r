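#' Classify binding sites by hormonal condition
#'
#' Maintained sites are hypothyroid-condition (MMI) peaks that overlap a
#' hyperthyroid (+T3) peak by at least 1 bp; abolished sites are the remaining
#' MMI peaks; de novo sites are +T3 peaks with no MMI overlap. The maintained
#' site keeps the MMI peak's coordinates (the hypothyroid ground state); its
#' +T3 partner count is recorded in `n_t3_partners`. Because overlap need not
#' be one-to-one, the count of +T3 peaks overlapping MMI
#' (`maintained_t3side`) is reported separately and never silently merged.
#'
#' @param mmi_peaks,t3_peaks Peak tibbles, each internally non-overlapping.
#' @return A `category_result`: list with `peaks` (all peaks labelled by
#'   `category`) and `counts`.
#' @export
classify_by_condition <- function(mmi_peaks, t3_peaks) {
  mmi_peaks <- as_intervals(mmi_peaks)
  t3_peaks <- as_intervals(t3_peaks)
  assert_nonoverlapping(mmi_peaks, "MMI peak set")
  assert_nonoverlapping(t3_peaks, "+T3 peak set")
  if (nrow(mmi_peaks) > 0 && nrow(t3_peaks) > 0) {
    hits <- GenomicRanges::findOverlaps(intervals_to_gr(mmi_peaks),
                                        intervals_to_gr(t3_peaks))
    mmi_hit <- S4Vectors::queryHits(hits)
    t3_hit <- S4Vectors::subjectHits(hits)
  } else {
    mmi_hit <- t3_hit <- integer()
  }
  partners <- tabulate(mmi_hit, nbins = nrow(mmi_peaks))
  mmi_peaks$category <- if_else(partners > 0, "maintained", "abolished")
  mmi_peaks$n_t3_partners <- partners
  de_novo <- t3_peaks[setdiff(seq_len(nrow(t3_peaks)), unique(t3_hit)), ]
  if (nrow(de_novo) > 0) {
    de_novo$category <- "de_novo"
    de_novo$n_t3_partners <- NA_integer_
  }
  peaks <- bind_rows(mmi_peaks, de_novo)
  counts <- list(
    n_mmi = nrow(mmi_peaks),
    n_t3 = nrow(t3_peaks),
    maintained = sum(mmi_peaks$category == "maintained"),
    abolished = sum(mmi_peaks$category == "abolished"),
    de_novo = nrow(de_novo),
    maintained_t3side = length(unique(t3_hit))
  )
  counts$total <- counts$maintained + counts$abolished + counts$de_novo
  structure(list(peaks = peaks, counts = counts), class = "category_result")
}

#' @export
print.category_result <- function(x, ...) {
  c <- x$counts
  cat(sprintf(
    "<category_result> MMI %d, +T3 %d -> maintained %d, abolished %d, de novo %d (total %d)\n",
    c$n_mmi, c$n_t3, c$maintained, c$abolished, c$de_novo, c$total))
  if (c$maintained != c$maintained_t3side) {
    cat(sprintf("  note: %d +T3 peaks overlap MMI (multi-overlap; MMI-side count %d)\n",
                c$maintained_t3side, c$maintained))
  }
  invisible(x)
}

#' @export
tidy.category_result <- function(x, ...) x$peaks

#' @export
glance.category_result <- function(x, ...) as_tibble(x$counts)

#' Partition peaks into TSS-proximal and distal
#'
#' A peak is proximal iff it overlaps the window `[tss - radius,
#' tss + radius]` (inclusive of both flanks, i.e. half-open
#' `[tss - radius, tss + radius + 1)`) of any gene; all other peaks are
#' distal.
#'
#' @param peaks Peak tibble.
#' @param genes Gene tibble with a `tss` column (see [add_tss()]).
#' @param radius TSS window radius in bp (default 1000).
#' @return List with `proximal` and `distal` tibbles (disjoint; union is the
#'   input).
#' @export
partition_tss <- function(peaks, genes, radius = 1000) {
  peaks <- as_intervals(peaks)
  if (nrow(peaks) == 0 || nrow(genes) == 0) {
    return(list(proximal = peaks[0, ], distal = peaks))
  }
  tss_win <- tibble(
    chrom = genes$chrom,
    start = pmax(0L, as.integer(genes$tss - radius)),
    end = as.integer(genes$tss + radius + 1L)
  )
  hits <- GenomicRanges::findOverlaps(intervals_to_gr(peaks),
                                      intervals_to_gr(tss_win))
  prox <- sort(unique(S4Vectors::queryHits(hits)))
  list(proximal = peaks[prox, ],
       distal = peaks[setdiff(seq_len(nrow(peaks)), prox), ])
}

#' Intersect replicate peak sets into a consensus list
#'
#' Anchored on the first replicate: an anchor peak survives iff every other
#' replicate has a peak overlapping it by at least 1 bp where the overlap
#' covers at least `min_frac` of the shorter of the two peaks. The consensus
#' interval is the intersection span of the anchor with its best-overlapping
#' match from each other replicate.
#'
#' @param rep_peak_sets List of >= 2 peak tibbles (a single set is returned
#'   unchanged with a warning).
#' @param min_frac Minimum overlap fraction of the shorter peak (default
#'   0.75).
#' @return Consensus peak tibble.
#' @export
intersect_replicates <- function(rep_peak_sets, min_frac = 0.75) {
  rep_peak_sets <- map(rep_peak_sets, as_intervals)
  if (length(rep_peak_sets) < 2) {
    warn("intersect_replicates: single replicate returned unchanged")
    return(rep_peak_sets[[1]])
  }
  anchors <- rep_peak_sets[[1]]
  others <- rep_peak_sets[-1]
  if (nrow(anchors) == 0) return(anchors)
  keep <- rep(TRUE, nrow(anchors))
  lo <- anchors$start
  hi <- anchors$end
  for (other in others) {
    if (nrow(other) == 0) return(anchors[0, ])
    hits <- GenomicRanges::findOverlaps(intervals_to_gr(anchors),
                                        intervals_to_gr(other))
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- overlap_length(anchors[qh, ], other[sh, ])
    shorter <- pmin(anchors$end[qh] - anchors$start[qh],
                    other$end[sh] - other$start[sh])
    ok <- ov >= 1 & ov >= min_frac * shorter
    matched <- rep(FALSE, nrow(anchors))
    best_lo <- rep(NA_integer_, nrow(anchors))
    best_hi <- rep(NA_integer_, nrow(anchors))
    if (any(ok)) {
      d <- tibble(qh = qh[ok], sh = sh[ok], ov = ov[ok]) |>
        arrange(.data$qh, desc(.data$ov)) |>
        distinct(.data$qh, .keep_all = TRUE)
      matched[d$qh] <- TRUE
      best_lo[d$qh] <- other$start[d$sh]
      best_hi[d$qh] <- other$end[d$sh]
    }
    keep <- keep & matched
    lo <- pmax(lo, if_else(is.na(best_lo), lo, best_lo))
    hi <- pmin(hi, if_else(is.na(best_hi), hi, best_hi))
  }
  out <- anchors[keep, ]
  out$start <- lo[keep]
  out$end <- hi[keep]
  out
}

#' Attach per-condition normalized read counts to peaks
#'
#' Counts read starts falling in each peak per condition and scales them to a
#' common depth. The default scaling normalizes by background depth (reads
#' falling outside the peak set, per million), which is robust when the
#' treatment itself changes the total amount of binding; `"library"` scales by
#' total reads per million.
#'
#' @param peaks Peak tibble.
#' @param reads_mmi,reads_t3 Read tables (`chrom, pos`).
#' @param normalization `"background"` or `"library"`.
#' @param chrom_lengths Optional named vector of chromosome lengths; when
#'   given, the expected ambient (background) read count within each peak
#'   span is subtracted before scaling, so the signal estimates
#'   site-specific binding rather than site-plus-ambient coverage.
#' @return `peaks` with `reads_mmi` and `reads_t3` columns (normalized).
#' @export
peak_condition_signal <- function(peaks, reads_mmi, reads_t3,
                                  normalization = c("background", "library"),
                                  chrom_lengths = NULL) {
  normalization <- match.arg(normalization)
  peaks <- as_intervals(peaks)
  gr <- intervals_to_gr(peaks)
  count_in <- function(reads) {
    rg <- GenomicRanges::GRanges(reads$chrom,
                                 IRanges::IRanges(reads$pos + 1L, width = 1L))
    GenomicRanges::countOverlaps(gr, rg)
  }
  widths <- peaks$end - peaks$start
  span <- sum(widths)
  one_condition <- function(reads) {
    raw <- count_in(reads)
    total <- nrow(reads)
    bg_reads <- total - sum(raw)
    if (!is.null(chrom_lengths)) {
      bg_rate <- bg_reads / max(1, sum(chrom_lengths) - span)
      raw <- pmax(0, raw - bg_rate * widths)
    }
    denom <- switch(normalization, background = bg_reads, library = total)
    if (denom <= 0) abort("peak_condition_signal: non-positive normalization depth")
    raw * 1e6 / denom
  }
  peaks$reads_mmi <- one_condition(reads_mmi)
  peaks$reads_t3 <- one_condition(reads_t3)
  peaks
}

#' Per-category occupancy shift between conditions
#'
#' Ratio of mean +T3 to mean MMI normalized read counts per site category.
#' The headline statistic is the ratio over maintained sites (the category
#' the hormone quantitatively modulates rather than switches).
#'
#' @param x A `category_result` whose peaks carry `reads_mmi`/`reads_t3`
#'   columns (see [peak_condition_signal()]), or such a peak tibble.
#' @return Tibble `category, mean_mmi, mean_t3, ratio`.
#' @export
occupancy_shift <- function(x) {
  peaks <- if (inherits(x, "category_result")) x$peaks else x
  if (!all(c("reads_mmi", "reads_t3") %in% names(peaks))) {
    abort("occupancy_shift: peaks need reads_mmi/reads_t3 columns")
  }
  peaks |>
    group_by(.data$category) |>
    summarise(mean_mmi = mean(.data$reads_mmi),
              mean_t3 = mean(.data$reads_t3),
              n = dplyr::n(), .groups = "drop") |>
    mutate(ratio = if_else(.data$mean_mmi > 0,
                           .data$mean_t3 / .data$mean_mmi, NA_real_))
}
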