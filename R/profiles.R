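#' Coverage track from read starts
#'
#' Each read start is extended to a fragment of `fragment` bp (the pileup
#' convention used for all site-anchored displays) and per-base coverage is
#' accumulated as run-length encodings per chromosome. With
#' `normalize = "rpm"` coverage is scaled to reads per million.
#'
#' @param reads Tibble of read starts (`chrom, pos`).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param fragment Fragment extension length, bp (default 150).
#' @param normalize `"rpm"` or `"raw"`.
#' @return A `coverage_track`: list of per-chromosome [S4Vectors::Rle]
#'   coverage vectors plus the library size.
#' @export
coverage_from_reads <- function(reads, chrom_lengths, fragment = 150,
                                normalize = c("rpm", "raw")) {
  normalize <- match.arg(normalize)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(reads$chrom, levels = names(chrom_lengths)),
    ranges = IRanges::IRanges(start = reads$pos + 1L, width = fragment)
  )
  cov <- GenomicRanges::coverage(gr, width = as.list(chrom_lengths))
  scale <- if (normalize == "rpm" && nrow(reads) > 0) 1e6 / nrow(reads) else 1
  structure(
    list(cov = as.list(cov), lib = nrow(reads), scale = scale,
         chrom_lengths = chrom_lengths),
    class = "coverage_track"
  )
}

#' Coverage track from a bedGraph table
#'
#' @param bg Tibble `chrom, start, end, value` (non-overlapping segments).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return A `coverage_track` (values used as-is; `scale = 1`).
#' @export
coverage_from_bedgraph <- function(bg, chrom_lengths) {
  cov <- map(names(chrom_lengths), function(cn) {
    L <- chrom_lengths[[cn]]
    seg <- filter(bg, .data$chrom == cn) |> arrange(.data$start)
    v <- S4Vectors::Rle(0, L)
    if (nrow(seg) > 0) {
      # concatenate runs: the gap before each segment, then the segment
      runs_len <- integer(0); runs_val <- numeric(0)
      prev <- 0L
      for (i in seq_len(nrow(seg))) {
        if (seg$start[i] > prev) {
          runs_len <- c(runs_len, seg$start[i] - prev)
          runs_val <- c(runs_val, 0)
        }
        runs_len <- c(runs_len, seg$end[i] - seg$start[i])
        runs_val <- c(runs_val, seg$value[i])
        prev <- seg$end[i]
      }
      if (prev < L) {
        runs_len <- c(runs_len, L - prev)
        runs_val <- c(runs_val, 0)
      }
      v <- S4Vectors::Rle(values = runs_val, lengths = runs_len)
    }
    v
  })
  names(cov) <- names(chrom_lengths)
  structure(list(cov = cov, lib = NA_real_, scale = 1,
                 chrom_lengths = chrom_lengths),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %d chromosome(s), library %s\n",
              length(x$cov), format(x$lib)))
  invisible(x)
}

# Extract the binned coverage row around one center; zero-padded at edges.
site_row <- function(cov_rle, center, flank, bin, scale) {
  L <- length(cov_rle)
  lo <- center - flank          # 0-based inclusive
  hi <- center + flank          # exclusive
  take_lo <- max(lo, 0L)
  take_hi <- min(hi, L)
  v <- numeric(2L * flank)
  if (take_hi > take_lo) {
    v[(take_lo - lo + 1):(take_hi - lo)] <-
      as.numeric(S4Vectors::window(cov_rle, take_lo + 1L, take_hi))
  }
  colMeans(matrix(v * scale, nrow = bin)) # one value per bin
}

#' Site-anchored signal matrix
#'
#' Builds the heatmap matrix behind site-ranked displays: one row per site,
#' one column per `bin`-bp bin across `center +/- flank`, each entry the mean
#' coverage in that bin. Rows are ordered by descending center-bin intensity
#' (ties by coordinate). Sites too close to a chromosome edge are zero-padded
#' and flagged.
#'
#' @param sites Interval tibble; the anchor is each interval's midpoint.
#' @param coverage A `coverage_track`.
#' @param flank Half-window, bp (default 4000).
#' @param bin Bin width, bp (default 50); must divide `2 * flank`.
#' @return A `signal_matrix`: list with `values` (sites x bins matrix),
#'   `sites` (ordered, with `edge_flagged`), `flank`, `bin`.
#' @export
build_matrix <- function(sites, coverage, flank = 4000, bin = 50) {
  stopifnot((2 * flank) %% bin == 0)
  sites <- as_intervals(sites, sort = FALSE)
  centers <- (sites$start + sites$end) %/% 2L
  vals <- matrix(0, nrow = nrow(sites), ncol = 2L * flank %/% bin)
  edge <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    rle <- coverage$cov[[sites$chrom[i]]]
    if (is.null(rle)) abort(paste0("no coverage for chromosome ", sites$chrom[i]))
    vals[i, ] <- site_row(rle, centers[i], as.integer(flank), as.integer(bin),
                          coverage$scale)
    edge[i] <- centers[i] - flank < 0 || centers[i] + flank > length(rle)
  }
  sites$edge_flagged <- edge
  nb <- ncol(vals)
  center_bin <- nb %/% 2 + 1L   # first bin right of the anchor
  ord <- order(-vals[, center_bin], sites$chrom, sites$start)
  structure(
    list(values = vals[ord, , drop = FALSE], sites = sites[ord, ],
         flank = flank, bin = bin,
         positions = -flank + (seq_len(nb) - 0.5) * bin),
    class = "signal_matrix"
  )
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("<signal_matrix> %d sites x %d bins (+/- %d bp, %d bp bins)\n",
              nrow(x$values), ncol(x$values), x$flank, x$bin))
  invisible(x)
}

#' @export
tidy.signal_matrix <- function(x, ...) {
  out <- as_tibble(x$values, .name_repair = ~ as.character(x$positions))
  out$site_rank <- seq_len(nrow(out))
  pivot_longer(out, -"site_rank", names_to = "position", values_to = "value") |>
    mutate(position = as.numeric(.data$position))
}

#' Average signal profile around site centers
#'
#' Column means of the (unranked) site-anchored matrix: the mean coverage per
#' bin across sites, reported at bin midpoints relative to the site center.
#'
#' @inheritParams build_matrix
#' @param flank Half-window, bp (default 2000).
#' @return A `profile_curve` tibble: `position, value`.
#' @export
average_profile <- function(sites, coverage, flank = 2000, bin = 50) {
  m <- build_matrix(sites, coverage, flank = flank, bin = bin)
  out <- tibble(position = m$positions, value = colMeans(m$values))
  class(out) <- c("profile_curve", class(out))
  out
}

#' Center-notch statistic of a profile curve
#'
#' Ratio of the center-bin value to the mean of the two flanking local maxima
#' (searched within `search` bp either side of the center, excluding the
#' center bin). A ratio below 1 indicates a central dip - the nucleosome-
#' clearance notch seen in histone-mark profiles over inducibly opened sites.
#' A flat curve returns exactly 1.
#'
#' @param curve A `profile_curve` tibble (`position, value`), >= 5 bins.
#' @param search Search radius for flanking maxima, bp (default 1000).
#' @return Single numeric ratio in `[0, Inf)`.
#' @export
notch_statistic <- function(curve, search = 1000) {
  if (nrow(curve) < 5) abort("notch_statistic: need at least 5 bins")
  ci <- which.min(abs(curve$position))
  center <- curve$value[ci]
  side_max <- function(idx) {
    if (length(idx) == 0) return(NA_real_)
    v <- curve$value[idx]
    if (length(v) >= 3) {
      interior <- which(v >= c(-Inf, head(v, -1)) & v >= c(v[-1], -Inf))
      max(v[interior])
    } else max(v)
  }
  left <- side_max(which(curve$position < curve$position[ci] &
                           curve$position >= curve$position[ci] - search))
  right <- side_max(which(curve$position > curve$position[ci] &
                            curve$position <= curve$position[ci] + search))
  flank_ref <- mean(c(left, right), na.rm = TRUE)
  if (!is.finite(flank_ref) || (flank_ref == 0 && center == 0)) return(1)
  if (flank_ref == 0) return(Inf)
  center / flank_ref
}
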