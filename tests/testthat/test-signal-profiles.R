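make_cov <- function(values_by_chrom) {
  structure(list(
    cov = lapply(values_by_chrom, S4Vectors::Rle),
    lib = NA_real_, scale = 1,
    chrom_lengths = vapply(values_by_chrom, length, numeric(1))
  ), class = "coverage_track")
}

test_that("signal matrix reproduces uniform and delta coverage exactly", {
  L <- 20000L
  sites <- tibble::tibble(chrom = "chr1", start = 9950L, end = 10050L)

  uni <- make_cov(list(chr1 = rep(2.5, L)))
  m <- build_matrix(sites, uni, flank = 1000, bin = 50)
  expect_true(all(m$values == 2.5))
  expect_equal(dim(m$values), c(1L, 40L))

  delta <- rep(0, L); delta[10001] <- 1  # 0-based center position 10000
  md <- build_matrix(sites, make_cov(list(chr1 = delta)),
                     flank = 1000, bin = 50)
  nonzero <- which(md$values[1, ] != 0)
  expect_equal(length(nonzero), 1L)
  expect_equal(md$positions[nonzero], 25)  # first bin right of the anchor
})

test_that("signal matrix matches direct per-base averaging", {
  withr::with_seed(8, {
    L <- 30000L
    cov <- runif(L)
    sites <- tibble::tibble(chrom = "chr1",
                            start = sort(sample(5000:25000, 5)), end = 0L)
    sites$end <- sites$start + 200L
    m <- build_matrix(sites, make_cov(list(chr1 = cov)),
                      flank = 2000, bin = 50)
    for (r in seq_len(5)) {
      site <- m$sites[r, ]
      center <- (site$start + site$end) %/% 2
      expected <- colMeans(matrix(cov[(center - 2000 + 1):(center + 2000)],
                                  nrow = 50))
      expect_equal(m$values[r, ], expected)
    }
  })
})

test_that("rows are ranked by center intensity without altering their content", {
  withr::with_seed(12, {
    L <- 50000L
    cov <- runif(L)
    sites <- tibble::tibble(chrom = "chr1",
                            start = seq(5000, 45000, by = 5000), end = 0L)
    sites$end <- sites$start + 100L
    m <- build_matrix(sites, make_cov(list(chr1 = cov)),
                      flank = 1000, bin = 50)
    center_col <- ncol(m$values) %/% 2 + 1
    expect_true(all(diff(m$values[, center_col]) <= 0))
    # the sorted matrix is a permutation of the unsorted row multiset
    sums <- sort(rowSums(m$values))
    m2 <- build_matrix(dplyr::arrange(sites, start),
                       make_cov(list(chr1 = cov)), flank = 1000, bin = 50)
    expect_equal(sort(rowSums(m2$values)), sums)
  })
})

test_that("sites at chromosome edges are zero-padded and flagged", {
  cov <- make_cov(list(chr1 = rep(1, 3000)))
  sites <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L)
  m <- build_matrix(sites, cov, flank = 1000, bin = 50)
  expect_true(m$sites$edge_flagged[1])
  expect_equal(m$values[1, 1], 0)  # left flank falls off the chromosome
})

test_that("average profile equals the column means of the matrix", {
  withr::with_seed(19, {
    L <- 40000L
    cov <- runif(L)
    sites <- tibble::tibble(chrom = "chr1",
                            start = sort(sample(5000:35000, 8)), end = 0L)
    sites$end <- sites$start + 300L
    ct <- make_cov(list(chr1 = cov))
    prof <- average_profile(sites, ct, flank = 2000, bin = 50)
    m <- build_matrix(sites, ct, flank = 2000, bin = 50)
    expect_equal(prof$value, unname(colMeans(m$values)))
    expect_equal(prof$position, m$positions)
  })
})

test_that("average profile of zero coverage is zero and symmetric signal stays symmetric", {
  L <- 20000L
  sites <- tibble::tibble(chrom = "chr1", start = 9950L, end = 10050L)
  zero <- average_profile(sites, make_cov(list(chr1 = rep(0, L))))
  expect_true(all(zero$value == 0))

  bump <- exp(-((seq_len(L) - 0.5 - 10000)^2) / (2 * 300^2))
  prof <- average_profile(sites, make_cov(list(chr1 = bump)), flank = 2000)
  expect_equal(prof$value, rev(prof$value), tolerance = 1e-6)
})

test_that("the notch statistic detects central dips", {
  flat <- tibble::tibble(position = seq(-500, 500, by = 250),
                         value = rep(4, 5))
  expect_equal(notch_statistic(flat), 1)

  w_shape <- tibble::tibble(position = c(-500, -250, 0, 250, 500),
                            value = c(1, 3, 1, 3, 1))
  expect_equal(notch_statistic(w_shape), 1 / 3)

  expect_error(notch_statistic(flat[1:3, ]), "at least 5")
})

test_that("simulated inducible sites show the +T3 histone notch", {
  cfg <- small_config(seed = 3)
  truth <- simulate_truth(cfg)
  ha <- simulate_histone_atac(cfg, truth)
  inducible <- dplyr::filter(truth$sites, atac_class == "increased")
  k27_t3 <- dplyr::filter(ha$histone, mark == "H3K27ac", condition == "T3")
  cov <- coverage_from_bedgraph(k27_t3, truth$chrom_lengths)
  prof <- average_profile(inducible, cov)
  expect_lt(notch_statistic(prof), 1)
  # constitutive maintained sites show no dip
  constit <- dplyr::filter(truth$sites, atac_class == "constitutive", distal)
  prof_c <- average_profile(constit, cov)
  expect_gte(notch_statistic(prof_c), 0.99)
})

test_that("maintained distal sites gain H3K27ac under +T3", {
  cfg <- small_config(seed = 3)
  truth <- simulate_truth(cfg)
  ha <- simulate_histone_atac(cfg, truth)
  md <- dplyr::filter(truth$sites, category == "maintained", distal)
  cov_of <- function(cond) {
    coverage_from_bedgraph(
      dplyr::filter(ha$histone, mark == "H3K27ac", condition == cond),
      truth$chrom_lengths)
  }
  p_mmi <- average_profile(md, cov_of("MMI"))
  p_t3 <- average_profile(md, cov_of("T3"))
  expect_gt(max(p_t3$value), max(p_mmi$value))
})

test_that("coverage from read starts extends fragments and normalizes", {
  reads <- tibble::tibble(chrom = "chr1", pos = c(100L, 100L, 400L))
  ct <- coverage_from_reads(reads, c(chr1 = 1000L), fragment = 150,
                            normalize = "raw")
  v <- as.numeric(ct$cov$chr1)
  expect_equal(v[101], 2)   # both fragments cover their start
  expect_equal(v[260], 0)   # beyond 150 bp extension
  expect_equal(sum(v), 3 * 150)
  rpm <- coverage_from_reads(reads, c(chr1 = 1000L), fragment = 150)
  expect_equal(rpm$scale, 1e6 / 3)  # values scaled to reads-per-million
})
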