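test_that("the generator is deterministic given a seed and varies across seeds", {
  cfg <- small_config(seed = 42)
  d1 <- simulate_t3_dataset(cfg)
  d2 <- simulate_t3_dataset(cfg)
  expect_identical(d1$truth$sites, d2$truth$sites)
  expect_identical(d1$chap_reads, d2$chap_reads)
  expect_identical(as.character(d1$sequences), as.character(d2$sequences))
  expect_identical(d1$rna$counts, d2$rna$counts)

  d3 <- simulate_t3_dataset(small_config(seed = 43))
  expect_false(identical(d1$chap_reads, d3$chap_reads))
})

test_that("degenerate and infeasible layouts are handled", {
  cfg0 <- small_config(seed = 1, n_genes = 0, p_induced_near = 0,
                       p_suppressed_near = 0, frac_induced = 0,
                       frac_suppressed = 0, frac_distal = 1,
                       n_sites = c(maintained = 10, abolished = 10,
                                   de_novo = 10))
  g <- simulate_genome(cfg0)
  expect_equal(nrow(g$genes), 0L)
  expect_equal(length(g$sequences), cfg0$n_chroms)

  too_many <- small_config(seed = 1, n_genes = 5000)
  expect_error(simulate_truth(too_many), "capacity")
})

test_that("site placement and truth invariants hold", {
  cfg <- small_config(seed = 8)
  truth <- simulate_truth(cfg)
  # sites are non-overlapping
  s <- dplyr::arrange(truth$sites, chrom, start)
  same <- s$chrom == dplyr::lag(s$chrom)
  expect_false(any(same & s$start < dplyr::lag(s$end), na.rm = TRUE))
  # genes are non-overlapping with valid strand-aware TSS
  g <- dplyr::arrange(truth$genes, chrom, start)
  sameg <- g$chrom == dplyr::lag(g$chrom)
  expect_false(any(sameg & g$start < dplyr::lag(g$end), na.rm = TRUE))
  expect_true(all(g$tss >= g$start & g$tss < g$end))
  # category counts match the configuration
  expect_equal(sum(truth$sites$category == "maintained"),
               unname(cfg$n_sites["maintained"]))
  expect_equal(sum(truth$sites$category == "none"), cfg$n_depleted_free)
  # inducible ATAC only at distal maintained sites
  ind <- dplyr::filter(truth$sites, atac_class == "increased")
  expect_true(all(ind$category == "maintained" & ind$distal))
})

test_that("planted motifs appear in the emitted sequence", {
  cfg <- small_config(seed = 9)
  g <- simulate_genome(cfg)
  motifs <- g$truth$motifs
  expect_gt(nrow(motifs), 0)
  for (i in seq_len(nrow(motifs))) {
    seq <- as.character(Biostrings::subseq(
      g$sequences[[motifs$chrom[i]]], motifs$pos[i] + 1L,
      motifs$pos[i] + 16L))
    expect_equal(substr(seq, 1, 6), "AGGTCA")
    expect_equal(substr(seq, 11, 16), "AGGTCA")
  }
})

test_that("ChAP reads follow the category-by-condition occupancy design", {
  cfg <- small_config(seed = 16)
  truth <- simulate_truth(cfg)
  reads <- simulate_chap_reads(cfg, truth)
  in_sites <- function(gt, cond, cats) {
    r <- dplyr::filter(reads, genotype == gt, condition == cond)
    s <- dplyr::filter(truth$sites, category %in% cats)
    hits <- GenomicRanges::countOverlaps(
      GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$start + 1, s$end)),
      GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$pos + 1, width = 1)))
    hits
  }
  # abolished sites carry only background under +T3
  ab_t3 <- in_sites("hab", "T3", "abolished")
  bg_rate <- cfg$lambda_bg * cfg$site_width
  expect_lt(mean(ab_t3), 10 * bg_rate)
  # de novo sites are silent under MMI, occupied under +T3
  expect_lt(mean(in_sites("hab", "MMI", "de_novo")), 10 * bg_rate)
  expect_gt(mean(in_sites("hab", "T3", "de_novo")),
            0.5 * cfg$reads_per_site)
  # control genotype is background-only everywhere
  expect_lt(mean(in_sites("bira", "T3", c("maintained", "de_novo"))),
            10 * bg_rate)
  # untreated condition occupies maintained sites at an intermediate level
  un <- mean(in_sites("hab", "Un", "maintained"))
  mmi <- mean(in_sites("hab", "MMI", "maintained"))
  t3 <- mean(in_sites("hab", "T3", "maintained"))
  expect_gt(un, 0.5 * mmi)
  expect_gt(mean(in_sites("hab", "Un", "abolished")), -1) # defined
  expect_lt(mean(in_sites("hab", "Un", "abolished")), 10 * bg_rate)
})

test_that("the +T3 occupancy boost is recovered by Monte Carlo at maintained sites", {
  cfg <- t3_sim_config(n_chroms = 2, chrom_length = 3e6,
                       n_sites = c(maintained = 200, abolished = 10,
                                   de_novo = 10),
                       n_genes = 50, frac_induced = 0, frac_suppressed = 0,
                       site_dispersion = Inf, rng_seed = 18)
  truth <- simulate_truth(cfg)
  reads <- simulate_chap_reads(cfg, truth, conditions = c("MMI", "T3"))
  count_at <- function(cond) {
    r <- dplyr::filter(reads, genotype == "hab", condition == cond)
    s <- dplyr::filter(truth$sites, category == "maintained")
    sum(GenomicRanges::countOverlaps(
      GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$start + 1, s$end)),
      GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$pos + 1, width = 1))))
  }
  ratio <- count_at("T3") / count_at("MMI")
  expect_equal(ratio, cfg$t3_boost, tolerance = 0.05)
})

test_that("ATAC counts encode inducible opening and depletion", {
  cfg <- small_config(seed = 20)
  truth <- simulate_truth(cfg)
  ha <- simulate_histone_atac(cfg, truth)
  td <- tidy(ha$atac)
  byclass <- dplyr::left_join(
    td, dplyr::select(truth$sites, feature = site_id, atac_class),
    by = "feature") |>
    dplyr::group_by(atac_class, condition) |>
    dplyr::summarise(mean = mean(count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = condition, values_from = mean)
  expect_gt(byclass$T3[byclass$atac_class == "increased"],
            2 * byclass$MMI[byclass$atac_class == "increased"])
  expect_lt(byclass$T3[byclass$atac_class == "depleted"],
            0.6 * byclass$MMI[byclass$atac_class == "depleted"])
  # constitutive sites are condition-balanced within sampling error
  con_ratio <- byclass$T3[byclass$atac_class == "constitutive"] /
    byclass$MMI[byclass$atac_class == "constitutive"]
  expect_equal(con_ratio, 1, tolerance = 0.15)

  # zero inducible fraction: every maintained site is condition-independent
  cfg0 <- small_config(seed = 20, fraction_inducible_atac = 0)
  ha0 <- simulate_histone_atac(cfg0, simulate_truth(cfg0))
  expect_false(any(ha0$atac_regions$atac_class == "increased"))
})

test_that("RNA counts encode responses, blunting and the CPM-expressed design", {
  cfg <- small_config(seed = 23)
  truth <- simulate_truth(cfg)
  rna <- simulate_rna_counts(cfg, truth)
  td <- tidy(rna) |>
    dplyr::left_join(dplyr::select(truth$genes, feature = gene_id,
                                   response, ko_impaired),
                     by = "feature")
  means <- td |>
    dplyr::group_by(response, genotype, condition) |>
    dplyr::summarise(mean = mean(count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = condition, values_from = mean)
  wt <- dplyr::filter(means, genotype == "WT")
  expect_gt(wt$T3[wt$response == "induced"] / wt$MMI[wt$response == "induced"],
            1.5)
  expect_lt(wt$T3[wt$response == "suppressed"] /
              wt$MMI[wt$response == "suppressed"], 1 / 1.5)
  un_ratio <- wt$T3[wt$response == "unchanged"] /
    wt$MMI[wt$response == "unchanged"]
  expect_equal(un_ratio, 1, tolerance = 0.15)

  # full blunting: responsive genes flat in KO in expectation
  cfg1 <- small_config(seed = 23,
                       ko_blunting_prob = c(induced = 1, suppressed = 1),
                       ko_residual = 0)
  truth1 <- simulate_truth(cfg1)
  rna1 <- simulate_rna_counts(cfg1, truth1)
  td1 <- tidy(rna1) |>
    dplyr::left_join(dplyr::select(truth1$genes, feature = gene_id, response),
                     by = "feature") |>
    dplyr::filter(response != "unchanged", genotype == "KO") |>
    dplyr::group_by(condition) |>
    dplyr::summarise(mean = mean(count), .groups = "drop")
  expect_equal(td1$mean[td1$condition == "T3"] /
                 td1$mean[td1$condition == "MMI"], 1, tolerance = 0.15)
})

test_that("emitted files feed every downstream reader unchanged", {
  cfg <- small_config(seed = 44)
  ds <- simulate_t3_dataset(cfg)
  outdir <- withr::local_tempdir()
  write_t3_dataset(ds, outdir)

  reads <- read_bed(file.path(outdir, "chap_hab_MMI.bed"))
  expect_gt(nrow(reads), 0)
  expect_true(all(reads$end - reads$start == 1L))

  genes <- read_gtf(file.path(outdir, "genes.gtf"))
  expect_setequal(genes$gene_id, ds$genes$gene_id)
  expect_equal(
    dplyr::arrange(genes, gene_id)$tss,
    dplyr::arrange(ds$genes, gene_id)$tss)

  bg <- read_bedgraph(file.path(outdir, "H3K27ac_T3.bedgraph"))
  expect_gt(nrow(bg), 0)

  atac <- read_count_matrix(file.path(outdir, "atac_counts.tsv"),
                            file.path(outdir, "atac_samples.tsv"))
  expect_equal(atac$counts, ds$atac$counts)

  fa <- Biostrings::readDNAStringSet(file.path(outdir, "genome.fa"))
  expect_equal(unname(Biostrings::width(fa)),
               unname(ds$truth$chrom_lengths))

  truth_json <- jsonlite::read_json(file.path(outdir, "ground_truth.json"),
                                    simplifyVector = TRUE)
  expect_equal(nrow(truth_json$sites), nrow(ds$truth$sites))
})
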