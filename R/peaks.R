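#' Caller parameter profiles
#'
#' The two published parameterizations: the transcription-factor profile
#' (50 bp windows, FDR 1e-6, used for tagged-receptor ChAP differential
#' calls) and the histone profile (200 bp windows, FDR 1e-3). The gap is the
#' longest unqualified span bridged inside an island (default 3 windows,
#' mirroring the island caller's gap-to-window ratio); `min_fold` is the
#' library-normalized treatment/control fold a differential island must reach;
#' `window_p` is the per-window Poisson qualification threshold.
#'
#' @param profile `"tf"` or `"histone"`.
#' @param w Window size in bp.
#' @param fdr Island-level BH FDR threshold.
#' @param gap Maximum bridged unqualified span, bp.
#' @param min_fold Minimum treatment/control fold for differential retention.
#' @param window_p Per-window Poisson upper-tail threshold for qualification.
#' @return A list of caller parameters.
#' @examples
#' caller_params("tf")
#' caller_params("histone", fdr = 1e-3)
#' @export
caller_params <- function(profile = c("tf", "histone"), w = NULL, fdr = NULL,
                          gap = NULL, min_fold = 2, window_p = 0.01) {
  profile <- match.arg(profile)
  defaults <- switch(profile,
    tf = list(w = 50L, fdr = 1e-6),
    histone = list(w = 200L, fdr = 1e-3)
  )
  w <- as.integer(w %||% defaults$w)
  fdr <- fdr %||% defaults$fdr
  gap <- as.integer(gap %||% (3L * w))
  stopifnot(w > 0, fdr > 0, fdr < 1, gap >= 0, min_fold >= 1)
  list(profile = profile, w = w, fdr = fdr, gap = gap,
       min_fold = min_fold, window_p = window_p)
}

#' Bin read starts into fixed-width windows
#'
#' @param read_starts Integer vector of read-start positions on one
#'   chromosome, each in `[0, chrom_length)`.
#' @param chrom_length Chromosome length, bp.
#' @param w Window width, bp.
#' @param chrom Chromosome name to record.
#' @return A window-track tibble `chrom, start, end, count` covering the
#'   chromosome in `ceiling(chrom_length / w)` windows, with attributes `w`
#'   and `library_size`; `sum(count)` equals the number of reads.
#' @export
bin_reads <- function(read_starts, chrom_length, w, chrom = "chr1") {
  stopifnot(w > 0, chrom_length > 0)
  read_starts <- as.integer(read_starts)
  if (length(read_starts) > 0 &&
      (min(read_starts) < 0 || max(read_starts) >= chrom_length)) {
    abort("bin_reads: read start outside [0, chrom_length)")
  }
  nwin <- as.integer(ceiling(chrom_length / w))
  counts <- tabulate(read_starts %/% w + 1L, nbins = nwin)
  track <- tibble(
    chrom = chrom,
    start = (seq_len(nwin) - 1L) * as.integer(w),
    end = pmin(seq_len(nwin) * as.integer(w), as.integer(chrom_length)),
    count = counts
  )
  attr(track, "w") <- as.integer(w)
  attr(track, "library_size") <- length(read_starts)
  track
}

#' Bin a genome-wide read table into windows
#'
#' @param reads Tibble with `chrom, pos` read starts.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param w Window width, bp.
#' @return Window track covering every chromosome (see [bin_reads()]);
#'   `library_size` is the total read count.
#' @export
bin_reads_genome <- function(reads, chrom_lengths, w) {
  tracks <- map(names(chrom_lengths), function(cn) {
    bin_reads(reads$pos[reads$chrom == cn], chrom_lengths[[cn]], w, chrom = cn)
  })
  out <- bind_rows(tracks)
  attr(out, "w") <- as.integer(w)
  attr(out, "library_size") <- nrow(reads)
  out
}

# Segment qualified windows of one chromosome into islands, bridging
# unqualified gaps of <= gap bp. Returns a tibble of island window-index runs.
segment_islands <- function(qualified, w, gap) {
  q <- which(qualified)
  if (length(q) == 0) {
    return(tibble(first = integer(), last = integer()))
  }
  gap_windows <- gap %/% w
  new_island <- c(TRUE, diff(q) - 1L > gap_windows)
  id <- cumsum(new_island)
  tibble(
    first = tapply(q, id, min)[unique(id)] |> as.integer(),
    last = tapply(q, id, max)[unique(id)] |> as.integer()
  )
}

#' Call enriched islands on a window track
#'
#' Windows whose counts beat a Poisson upper-tail test at `window_p` against
#' the background rate `lambda` are "qualified"; consecutive qualified windows
#' separated by at most `gap` bp of unqualified span merge into candidate
#' islands. Each island gets a score (sum of `-ln p` over its qualified
#' windows) and a Poisson p-value for its total count against
#' `lambda * n_windows`; Benjamini-Hochberg q-values are computed across
#' candidate islands and islands at `q <= fdr` are returned.
#'
#' @param track Window track from [bin_reads()]/[bin_reads_genome()].
#' @param params Caller parameters from [caller_params()].
#' @param lambda Background rate per window; defaults to the genome-wide mean
#'   count per window.
#' @return Tibble of scored peaks: `chrom, start, end, score, count, p, q`
#'   with `score = -log10(q)`.
#' @export
call_islands <- function(track, params = caller_params("tf"), lambda = NULL) {
  w <- attr(track, "w") %||% params$w
  if (nrow(track) == 0) return(empty_peaks())
  lambda <- lambda %||% mean(track$count)
  if (lambda <= 0) abort("call_islands: background rate must be > 0")
  p_win <- ppois(track$count - 1, lambda, lower.tail = FALSE)
  qualified <- p_win <= params$window_p
  cand <- map_dfr(unique(track$chrom), function(cn) {
    sel <- which(track$chrom == cn)
    runs <- segment_islands(qualified[sel], w, params$gap)
    if (nrow(runs) == 0) return(NULL)
    pmap(list(runs$first, runs$last), function(f, l) {
      idx <- sel[f:l]
      qi <- idx[qualified[idx]]
      tibble(
        chrom = cn,
        start = track$start[idx[1]],
        end = track$end[idx[length(idx)]],
        score = sum(-log(pmax(p_win[qi], 1e-300))),
        count = sum(track$count[idx]),
        n_windows = length(idx)
      )
    }) |> bind_rows()
  })
  if (nrow(cand) == 0) return(empty_peaks())
  cand$p <- ppois(cand$count - 1, lambda * cand$n_windows, lower.tail = FALSE)
  cand$q <- p.adjust(cand$p, method = "BH")
  out <- filter(cand, .data$q <= params$fdr)
  if (nrow(out) == 0) return(empty_peaks())
  out$score <- -log10(pmax(out$q, 1e-300))
  select(out, "chrom", "start", "end", "score", "count", "p", "q")
}

empty_peaks <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         score = numeric(), count = integer(), p = numeric(), q = numeric())
}

#' Differential island calling against a control track
#'
#' Islands are called on the treatment track (Poisson null with the
#' treatment's genome-wide rate), then retained only if (i) the
#' reads-per-million-normalized treatment/control fold over the island span is
#' at least `params$min_fold` (one read is added to the control count so empty
#' control spans stay finite), and (ii) a control-conditioned Poisson test -
#' treatment count against the library-scaled control expectation - passes
#' Benjamini-Hochberg at `params$fdr`. A zero-library control falls back to
#' plain background calling with a warning.
#'
#' @param treatment_track,control_track Window tracks on the same grid.
#' @param params Caller parameters ([caller_params()]).
#' @return Scored peak tibble with `treat_rpm`, `control_rpm`, `fold` columns;
#'   `score = -log10(q)` of the differential test.
#' @export
differential_call <- function(treatment_track, control_track,
                              params = caller_params("tf")) {
  w <- attr(treatment_track, "w") %||% params$w
  stopifnot(identical(w, attr(control_track, "w") %||% params$w))
  t_lib <- attr(treatment_track, "library_size") %||% sum(treatment_track$count)
  c_lib <- attr(control_track, "library_size") %||% sum(control_track$count)
  if (c_lib <= 0) {
    warn("differential_call: control library empty; falling back to background-rate calling")
    return(call_islands(treatment_track, params))
  }
  islands <- call_islands(treatment_track, params)
  if (nrow(islands) == 0) return(mutate(islands, treat_rpm = numeric(),
                                        control_rpm = numeric(), fold = numeric()))
  key <- paste(control_track$chrom, control_track$start)
  c_count_by_win <- setNames(control_track$count, key)
  ctrl_counts <- map_dbl(seq_len(nrow(islands)), function(i) {
    wins <- seq(islands$start[i], islands$end[i] - 1L, by = w)
    sum(c_count_by_win[paste(islands$chrom[i], wins)], na.rm = TRUE)
  })
  islands$treat_rpm <- islands$count / t_lib * 1e6
  islands$control_rpm <- ctrl_counts / c_lib * 1e6
  islands$fold <- islands$treat_rpm / ((ctrl_counts + 1) / c_lib * 1e6)
  expected <- (ctrl_counts + 1) * t_lib / c_lib
  p_diff <- ppois(islands$count - 1, expected, lower.tail = FALSE)
  islands$q <- p.adjust(p_diff, method = "BH")
  islands$p <- p_diff
  out <- filter(islands, .data$fold >= params$min_fold, .data$q <= params$fdr)
  mutate(out, score = -log10(pmax(.data$q, 1e-300)))
}
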