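test_that("read binning counts every read exactly once", {
  tr <- bin_reads(c(10, 60, 61), 200, 50)
  expect_equal(tr$count, c(1L, 2L, 0L, 0L))
  expect_equal(tr$start, c(0L, 50L, 100L, 150L))

  expect_equal(sum(bin_reads(integer(0), 1000, 50)$count), 0L)

  withr::with_seed(3, {
    reads <- sample.int(1e5, 10000, replace = TRUE) - 1L
    expect_equal(sum(bin_reads(reads, 1e5, 50)$count), 10000L)
  })

  expect_error(bin_reads(c(5, 250), 200, 50), "outside")
})

test_that("island calling finds spikes, not uniform background", {
  params <- caller_params("tf")
  # uniform track at the background rate: nothing qualifies
  flat <- bin_reads(integer(0), 5000, 50)
  flat$count <- rep(1L, nrow(flat))
  expect_equal(nrow(call_islands(flat, params, lambda = 1)), 0L)

  # one window with count 50 over lambda = 1: Poisson tail ~ 1e-64
  spike <- flat
  spike$count <- rep(0L, nrow(spike))
  spike$count[40] <- 50L
  out <- call_islands(spike, params, lambda = 1)
  expect_equal(nrow(out), 1L)
  expect_equal(out$end - out$start, 50L)
  expect_lt(ppois(49, 1, lower.tail = FALSE), params$fdr)
})

test_that("islands merge across gaps of at most the gap parameter", {
  params <- caller_params("tf")  # gap = 150 bp = 3 windows
  base <- bin_reads(integer(0), 5000, 50)
  base$count <- rep(0L, nrow(base))
  near <- far <- base
  near$count[c(10, 14)] <- 50L   # 3 unqualified windows between: merge
  far$count[c(10, 15)] <- 50L    # 4 between: split
  expect_equal(nrow(call_islands(near, params, lambda = 1)), 1L)
  expect_equal(nrow(call_islands(far, params, lambda = 1)), 2L)
})

test_that("differential calling is null on matched tracks and rejects control spikes", {
  withr::with_seed(11, {
    reads <- sample.int(2e5, 5000, replace = TRUE) - 1L
    t_track <- bin_reads(reads, 2e5, 50)
    expect_equal(nrow(differential_call(t_track, t_track)), 0L)

    # treatment spike matched by an equal control spike is not called
    spike <- sample(0:499, 400, replace = TRUE) + 10000L
    t2 <- bin_reads(c(reads, spike), 2e5, 50)
    c2 <- bin_reads(c(sample.int(2e5, 5000, replace = TRUE) - 1L, spike),
                    2e5, 50)
    called <- differential_call(t2, c2)
    expect_false(any(called$start < 10500 & called$end > 10000))
  })
})

test_that("zero-library control falls back to background calling with a warning", {
  t_track <- bin_reads(c(rep(500L, 60), 1000L, 2000L), 1e4, 50)
  c_track <- bin_reads(integer(0), 1e4, 50)
  expect_warning(out <- differential_call(t_track, c_track), "control library")
  expect_gt(nrow(out), 0)
})

test_that("called peaks are disjoint with boundaries on the window grid", {
  withr::with_seed(5, {
    reads <- c(sample.int(1e5, 2000, replace = TRUE) - 1L,
               rep(c(10000L, 30025L, 70010L), each = 150))
    track <- bin_reads(reads, 1e5, 50)
    out <- call_islands(track, caller_params("tf"))
    expect_gt(nrow(out), 0)
    expect_true(all(out$start %% 50 == 0))
    expect_true(all(out$end %% 50 == 0))
    out <- dplyr::arrange(out, chrom, start)
    expect_true(all(diff(out$start) > 0))
    expect_true(all(out$start[-1] >= out$end[-nrow(out)]))
  })
})

test_that("stricter FDR never increases the peak count", {
  withr::with_seed(9, {
    reads <- c(sample.int(1e5, 3000, replace = TRUE) - 1L,
               unlist(lapply(seq(5000, 95000, by = 10000),
                             function(p) rep(p, sample(8:60, 1)))))
    track <- bin_reads(reads, 1e5, 50)
    qs <- c(0.1, 1e-2, 1e-4, 1e-6, 1e-8)
    n <- vapply(qs, function(q) {
      nrow(call_islands(track, caller_params("tf", fdr = q)))
    }, numeric(1))
    expect_true(all(diff(n) <= 0))
  })
})

test_that("island segmentation matches exhaustive enumeration on short tracks", {
  params <- caller_params("tf", fdr = 0.999)  # keep all candidate islands
  withr::with_seed(21, {
    for (k in 1:60) {
      nwin <- sample(5:30, 1)
      counts <- rpois(nwin, 0.5) + sample(c(0L, 40L), nwin, replace = TRUE,
                                          prob = c(0.7, 0.3))
      track <- bin_reads(integer(0), nwin * 50, 50)
      track$count <- as.integer(counts)
      lambda <- 1
      qualified <- ppois(counts - 1, lambda, lower.tail = FALSE) <=
        params$window_p
      expected <- oracle_islands(qualified, 50, params$gap)
      got <- call_islands(track, params, lambda = lambda)
      expect_equal(nrow(got), length(expected))
      if (length(expected) > 0) {
        first_q <- vapply(expected, `[`, numeric(1), 1)
        last_q <- vapply(expected, `[`, numeric(1), 2)
        expect_equal(got$start, (first_q - 1L) * 50L)
        expect_equal(got$end, last_q * 50L)
      }
    }
  })
})

test_that("synthetic planted sites are recovered by differential calls", {
  cfg <- small_config(seed = 4)
  truth <- simulate_truth(cfg)
  reads <- simulate_chap_reads(cfg, truth, conditions = "MMI")
  lens <- truth$chrom_lengths
  hab <- dplyr::filter(reads, genotype == "hab")
  bira <- dplyr::filter(reads, genotype == "bira")
  peaks <- differential_call(bin_reads_genome(hab, lens, 50),
                             bin_reads_genome(bira, lens, 50),
                             caller_params("tf"))
  planted <- dplyr::filter(truth$sites,
                           category %in% c("maintained", "abolished"))
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(planted$chrom,
                           IRanges::IRanges(planted$start + 1, planted$end)),
    GenomicRanges::GRanges(peaks$chrom,
                           IRanges::IRanges(peaks$start + 1, peaks$end)))
  # every planted MMI-occupied site is hit by at least one called peak
  expect_equal(length(unique(S4Vectors::queryHits(hits))), nrow(planted))
  # and at least 95% of called peaks land on planted sites
  expect_gte(length(unique(S4Vectors::subjectHits(hits))) / nrow(peaks), 0.95)
})
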