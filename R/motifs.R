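#' Reporter response-element sequences
#'
#' The two reporter elements used as worked validation inputs for the
#' direct-repeat scanner: a DR4 element (two copies of an AGGTCA direct
#' repeat with 4-base spacer) and the TREpal0 element (two copies of a
#' 0-spacer palindromic repeat).
#'
#' @return Named character vector with elements `dr4` and `trepal0`.
#' @examples
#' scan_dr(reporter_elements()["dr4"], max_mismatch = 0)
#' @export
reporter_elements <- function() {
  c(
    dr4 = "AGGTCACTTCAGGTCATCACGTAACTGATGTAGGTCACTTCAGGTCA",
    trepal0 = "AGGTCATGACCTGAGATCTCAGGTCATGACCT"
  )
}

hamming_at <- function(seq_chars, pattern_chars, offset) {
  sum(seq_chars[offset + seq_along(pattern_chars)] != pattern_chars)
}

#' Scan a sequence for nuclear-receptor half-sites
#'
#' Reports every offset (0-based) where the sequence matches the half-site
#' consensus within `max_mismatch` Hamming distance, on both strands (a `-`
#' hit means the reverse complement of the consensus occurs at that offset).
#'
#' @param sequence A single DNA string (character or
#'   [Biostrings::DNAString]).
#' @param consensus Half-site consensus (default `"AGGTCA"`).
#' @param max_mismatch Maximum mismatches per half-site (default 0).
#' @return Tibble: `offset, strand, mismatches`.
#' @export
scan_half_sites <- function(sequence, consensus = "AGGTCA", max_mismatch = 0) {
  subject <- Biostrings::DNAString(as.character(sequence))
  pat <- Biostrings::DNAString(consensus)
  one_strand <- function(p, strand) {
    m <- Biostrings::matchPattern(p, subject, max.mismatch = max_mismatch)
    if (length(m) == 0) {
      return(tibble(offset = integer(), strand = character(),
                    mismatches = integer()))
    }
    starts <- Biostrings::start(m)
    mm <- Biostrings::neditStartingAt(p, subject, starting.at = starts)
    tibble(offset = starts - 1L, strand = strand, mismatches = as.integer(mm))
  }
  bind_rows(
    one_strand(pat, "+"),
    one_strand(Biostrings::reverseComplement(pat), "-")
  ) |> arrange(.data$offset, .data$strand)
}

#' Pair half-site hits into direct, palindromic or everted repeats
#'
#' Direct repeats are two half-sites on the same strand separated by a spacer
#' `s`; palindromic (inverted, head-to-head) repeats are a `+` half-site
#' followed by a `-` half-site; everted repeats the reverse. Half-sites in a
#' pair never share bases (spacer >= 0). Hits are ranked by total mismatches,
#' then leftmost offset, then smallest spacer.
#'
#' @param hits Half-site table from [scan_half_sites()].
#' @param orientation `"direct"`, `"palindromic"` or `"everted"`.
#' @param s_range Integer vector of spacers to consider (default `0:8`).
#' @param half_width Half-site width (default 6).
#' @return Tibble: `offset, spacer, orientation, strand, mismatches`, ranked.
#' @export
pair_hits <- function(hits, orientation = c("direct", "palindromic", "everted"),
                      s_range = 0:8, half_width = 6L) {
  orientation <- match.arg(orientation)
  empty <- tibble(offset = integer(), spacer = integer(),
                  orientation = character(), strand = character(),
                  mismatches = integer())
  if (nrow(hits) < 2) return(empty)
  pairs <- switch(orientation,
    direct = inner_join(hits, hits, by = "strand",
                        relationship = "many-to-many", suffix = c("", "2")),
    palindromic = inner_join(
      mutate(filter(hits, .data$strand == "+"), key = 1L),
      mutate(filter(hits, .data$strand == "-"), key = 1L),
      by = "key", relationship = "many-to-many", suffix = c("", "2")),
    everted = inner_join(
      mutate(filter(hits, .data$strand == "-"), key = 1L),
      mutate(filter(hits, .data$strand == "+"), key = 1L),
      by = "key", relationship = "many-to-many", suffix = c("", "2"))
  )
  pairs <- mutate(pairs, spacer = .data$offset2 - .data$offset - half_width) |>
    filter(.data$spacer %in% s_range)
  if (nrow(pairs) == 0) return(empty)
  ori <- orientation
  pairs |>
    mutate(strand = if (ori == "direct") .data$strand else "+/-",
           orientation = ori,
           mismatches = .data$mismatches + .data$mismatches2) |>
    select("offset", "spacer", "orientation", "strand", "mismatches") |>
    arrange(.data$mismatches, .data$offset, .data$spacer)
}

#' Scan sequences for direct/palindromic repeats of a half-site
#'
#' Convenience wrapper: [scan_half_sites()] then [pair_hits()] per sequence.
#'
#' @param sequences Character vector or [Biostrings::DNAStringSet] (names
#'   used as `seq_id`).
#' @inheritParams pair_hits
#' @inheritParams scan_half_sites
#' @return Tibble of motif hits with a `seq_id` column, ranked within
#'   sequence.
#' @export
scan_dr <- function(sequences, orientation = "direct", s_range = 0:8,
                    consensus = "AGGTCA", max_mismatch = 0) {
  seqs <- as.character(sequences)
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  if (is.null(names(seqs))) names(seqs) <- ids
  out <- map_dfr(ids, function(id) {
    h <- scan_half_sites(seqs[[id]], consensus, max_mismatch)
    ph <- pair_hits(h, orientation, s_range,
                    half_width = nchar(consensus))
    if (nrow(ph) > 0) ph$seq_id <- id
    ph
  })
  if (!"seq_id" %in% names(out)) out$seq_id <- character(nrow(out))
  dplyr::relocate(out, "seq_id")
}

#' Best direct-repeat hit in a sequence
#' @inheritParams scan_dr
#' @return One-row tibble (the top-ranked hit) or a zero-row tibble.
#' @export
best_dr_hit <- function(sequences, orientation = "direct", s_range = 0:8,
                        consensus = "AGGTCA", max_mismatch = 0) {
  head(scan_dr(sequences, orientation, s_range, consensus, max_mismatch), 1)
}

#' Per-spacer repeat enrichment of foreground vs background sequences
#'
#' For each spacer `s`, counts sequences carrying at least one repeat hit in
#' foreground and background, and computes the hypergeometric upper-tail
#' p-value of the foreground count given the pooled counts. Fold is the
#' ratio of hit-bearing fractions (with a 0.5/1 pseudocount so an identical
#' foreground and background give exactly fold 1). Rows are ranked by p.
#'
#' @param foreground_seqs,background_seqs Character vectors /
#'   [Biostrings::DNAStringSet] of sequences.
#' @inheritParams scan_dr
#' @return A `spacer_enrichment` tibble: `spacer, fg_hits, bg_hits, fg_frac,
#'   bg_frac, fold, p`, ranked by `p`.
#' @export
spacer_enrichment <- function(foreground_seqs, background_seqs,
                              orientation = "direct", s_range = 0:8,
                              consensus = "AGGTCA", max_mismatch = 1) {
  fg <- as.character(foreground_seqs)
  bg <- as.character(background_seqs)
  if (length(fg) == 0) abort("spacer_enrichment: empty foreground")
  if (length(bg) == 0) abort("spacer_enrichment: empty background")
  names(fg) <- paste0("fg", seq_along(fg))
  names(bg) <- paste0("bg", seq_along(bg))
  count_by_spacer <- function(seqs) {
    hits <- scan_dr(seqs, orientation, s_range, consensus, max_mismatch)
    vapply(s_range, function(s) {
      length(unique(hits$seq_id[hits$spacer == s]))
    }, integer(1))
  }
  k_fg <- count_by_spacer(fg)
  k_bg <- count_by_spacer(bg)
  n_fg <- length(fg); n_bg <- length(bg)
  p <- phyper(k_fg - 1, k_fg + k_bg, n_fg + n_bg - k_fg - k_bg, n_fg,
              lower.tail = FALSE)
  out <- tibble(
    spacer = as.integer(s_range),
    fg_hits = k_fg, bg_hits = k_bg,
    fg_frac = k_fg / n_fg, bg_frac = k_bg / n_bg,
    fold = ((k_fg + 0.5) / (n_fg + 1)) / ((k_bg + 0.5) / (n_bg + 1)),
    p = p
  ) |> arrange(.data$p, desc(.data$fold))
  class(out) <- c("spacer_enrichment", class(out))
  out
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson doublet shuffle: each shuffled sequence has exactly the
#' original's dinucleotide (hence mononucleotide) composition. Used as the
#' default scanner background.
#'
#' @param sequences Character vector of DNA sequences.
#' @param seed Integer seed (shuffle is deterministic given it).
#' @return Character vector of shuffled sequences, same lengths.
#' @export
dinuc_shuffle <- function(sequences, seed = 1) {
  with_seed(as.integer(seed), vapply(as.character(sequences),
                                     shuffle_one, character(1),
                                     USE.NAMES = FALSE))
}

shuffle_one <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  if (n < 3) return(seq)
  verts <- unique(s)
  edges <- split(s[-1], factor(s[-n], levels = verts))
  last_vert <- s[n]
  # choose random "last edges" whose chains all reach the terminal vertex
  repeat {
    last_edge <- vapply(verts, function(v) {
      if (v == last_vert || length(edges[[v]]) == 0) NA_character_
      else sample(edges[[v]], 1)
    }, character(1))
    ok <- TRUE
    for (v in verts) {
      if (v == last_vert || is.na(last_edge[[v]])) next
      seen <- character(0); cur <- v
      while (cur != last_vert) {
        if (cur %in% seen || is.na(last_edge[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  # permute remaining edges, append the designated last edge
  pools <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (!is.na(last_edge[[v]])) {
      e <- e[-match(last_edge[[v]], e)]
      c(sample(e), last_edge[[v]])
    } else sample(e)
  })
  names(pools) <- verts
  used <- setNames(integer(length(verts)), verts)
  out <- character(n)
  out[1] <- s[1]
  cur <- s[1]
  for (i in 2:n) {
    used[[cur]] <- used[[cur]] + 1L
    nxt <- pools[[cur]][used[[cur]]]
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}
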