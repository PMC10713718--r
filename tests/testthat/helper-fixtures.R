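# Shared fixtures and brute-force oracles used across the suite.

# A small simulation configuration that keeps per-test runtime low while
# preserving the structural features (categories, linkage, replicates).
small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_chroms = 2, chrom_length = 1.5e6,
         n_sites = c(maintained = 30, abolished = 30, de_novo = 24),
         n_genes = 60, n_depleted_free = 4, rng_seed = seed),
    list(...))
  do.call(t3_sim_config, args)
}

random_intervals <- function(n, chrom = "chr1", max_pos = 10000, width = 100) {
  s <- sort(sample.int(max_pos, n))
  tibble::tibble(chrom = chrom, start = s, end = s + width)
}

# Non-overlapping random intervals (for classification inputs).
random_disjoint_intervals <- function(n, chrom = "chr1", gap_scale = 300,
                                      width_range = c(50, 200)) {
  w <- sample(seq(width_range[1], width_range[2]), n, replace = TRUE)
  gaps <- sample.int(gap_scale, n, replace = TRUE)
  s <- cumsum(gaps + dplyr::lag(w, default = 0))
  tibble::tibble(chrom = chrom, start = s, end = s + w)
}

# Quadratic all-pairs overlap oracle for condition classification.
oracle_classify <- function(mmi, t3) {
  ov <- function(a, b) {
    max(0, min(a$end, b$end) - max(a$start, b$start)) > 0 &&
      a$chrom == b$chrom
  }
  mmi_hit <- vapply(seq_len(nrow(mmi)), function(i) {
    any(vapply(seq_len(nrow(t3)), function(j) ov(mmi[i, ], t3[j, ]),
               logical(1)))
  }, logical(1))
  t3_hit <- vapply(seq_len(nrow(t3)), function(j) {
    any(vapply(seq_len(nrow(mmi)), function(i) ov(mmi[i, ], t3[j, ]),
               logical(1)))
  }, logical(1))
  list(maintained = sum(mmi_hit), abolished = sum(!mmi_hit),
       de_novo = sum(!t3_hit), maintained_t3side = sum(t3_hit))
}

# Exhaustive island segmentation oracle: maximal runs of qualified windows
# bridged across unqualified gaps of <= gap bp.
oracle_islands <- function(qualified, w, gap) {
  islands <- list()
  cur <- NULL
  pending_gap <- 0L
  for (i in seq_along(qualified)) {
    if (qualified[i]) {
      if (is.null(cur)) {
        cur <- c(i, i)
      } else if (pending_gap * w <= gap) {
        cur[2] <- i
      } else {
        islands <- c(islands, list(cur))
        cur <- c(i, i)
      }
      pending_gap <- 0L
    } else {
      pending_gap <- pending_gap + 1L
    }
  }
  if (!is.null(cur)) islands <- c(islands, list(cur))
  islands
}
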