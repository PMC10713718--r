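#' Run the full synthetic-study analysis pipeline
#'
#' Orchestrates simulate -> differential peak calling (per condition, tagged
#' vs control genotype) -> site classification and TSS partition ->
#' occupancy shift -> ATAC differential accessibility -> average profiles
#' and notch -> DR spacer enrichment -> RNA response, knockout blunting and
#' site-gene association -> matched inducible-vs-constitutive comparison.
#' Every stage consumes the previous stage's tidy output; the report's
#' numbers are all recomputable from the returned intermediates.
#' Deterministic given `config$rng_seed`.
#'
#' @param config A [t3_sim_config()].
#' @param outdir Optional directory: when given, the simulated dataset is
#'   also written there via [write_t3_dataset()].
#' @param params Caller parameters for the ChAP differential calls
#'   (default the 50 bp / FDR 1e-6 transcription-factor profile).
#' @return A `t3_run` list with the dataset, per-stage results and a
#'   `summary` list; see [glance.t3_run()].
#' @export
run_t3_pipeline <- function(config = t3_sim_config(), outdir = NULL,
                            params = caller_params("tf")) {
  dataset <- simulate_t3_dataset(config)
  if (!is.null(outdir)) write_t3_dataset(dataset, outdir)
  lens <- dataset$truth$chrom_lengths
  reads_of <- function(gt, cond) {
    filter(dataset$chap_reads, .data$genotype == gt, .data$condition == cond)
  }

  # stage 1: differential peak calling per condition (tagged vs control)
  peaks <- lapply(c(MMI = "MMI", T3 = "T3"), function(cond) {
    differential_call(
      bin_reads_genome(reads_of("hab", cond), lens, params$w),
      bin_reads_genome(reads_of("bira", cond), lens, params$w),
      params)
  })

  # stage 2: classification, condition signal, TSS partition, occupancy
  classification <- classify_by_condition(peaks$MMI, peaks$T3)
  classification$peaks <- peak_condition_signal(
    classification$peaks, reads_of("hab", "MMI"), reads_of("hab", "T3"),
    chrom_lengths = lens)
  tss_split <- partition_tss(classification$peaks, dataset$genes)
  occupancy <- occupancy_shift(classification)

  # stage 3: ATAC differential accessibility
  atac_diff <- atac_differential(dataset$atac)

  # stage 4: profiles and the notch at inducible sites
  maintained_distal <- filter(tss_split$distal, .data$category == "maintained")
  cov_t3 <- coverage_from_bedgraph(
    filter(dataset$histone, .data$mark == "H3K27ac", .data$condition == "T3"),
    lens)
  cov_mmi <- coverage_from_bedgraph(
    filter(dataset$histone, .data$mark == "H3K27ac", .data$condition == "MMI"),
    lens)
  profiles <- list(
    k27ac_mmi = average_profile(maintained_distal, cov_mmi),
    k27ac_t3 = average_profile(maintained_distal, cov_t3)
  )
  inducible_regions <- filter(dataset$atac_regions,
                              .data$atac_class == "increased")
  notch <- notch_statistic(average_profile(inducible_regions, cov_t3))

  # stage 5: DR spacer enrichment at maintained sites vs shuffled background
  maintained_sites <- filter(classification$peaks,
                             .data$category == "maintained")
  fg <- site_sequences(maintained_sites, dataset$sequences)
  bg <- dinuc_shuffle(fg, seed = config$rng_seed)
  enrichment <- spacer_enrichment(fg, bg)

  # stage 6: RNA responses, blunting, association
  rna_wt <- rna_differential(filter_samples(dataset$rna, genotype == "WT"))
  rna_ko <- rna_differential(filter_samples(dataset$rna, genotype == "KO"))
  blunting <- classify_blunting(rna_wt, rna_ko)
  genes_cls <- left_join(select(dataset$genes, -dplyr::any_of("response")),
                         select(rna_wt, "gene_id", "response"),
                         by = "gene_id") |>
    mutate(response = dplyr::coalesce(.data$response, "unchanged"))
  incidence <- genes_with_site_within(genes_cls, maintained_sites)
  curve <- association_curve(genes_cls, maintained_sites)

  # stage 7: matched inducible vs constitutive comparison
  atac_norm <- cpm(dataset$atac)
  region_signal <- mutate(dataset$atac_regions,
                          mean_signal = rowMeans(atac_norm))
  inducible <- filter(region_signal, .data$site_id %in%
                        atac_diff$feature[atac_diff$class == "increased"])
  pool <- filter(region_signal, .data$site_id %in%
                   atac_diff$feature[atac_diff$class == "unchanged"])
  matched <- matched_group_comparison(
    inducible, pool, genes_cls,
    select(rna_wt, "gene_id", "log2fc"))

  recovery <- category_recovery(classification, dataset$truth)
  summary <- list(
    counts = classification$counts,
    n_proximal = nrow(tss_split$proximal),
    n_distal = nrow(tss_split$distal),
    occupancy = occupancy,
    atac_increased = sum(atac_diff$class == "increased"),
    atac_depleted = sum(atac_diff$class == "depleted"),
    notch = notch,
    top_spacer = enrichment$spacer[1],
    n_induced = sum(rna_wt$response == "induced"),
    n_suppressed = sum(rna_wt$response == "suppressed"),
    blunting = blunting,
    incidence = incidence,
    matched_p = matched$test$p,
    recovery = recovery
  )
  structure(
    list(dataset = dataset, peaks = peaks, classification = classification,
         tss = tss_split, occupancy = occupancy, atac = atac_diff,
         profiles = profiles, notch = notch, enrichment = enrichment,
         rna = list(wt = rna_wt, ko = rna_ko), blunting = blunting,
         incidence = incidence, curve = curve, matched = matched,
         summary = summary),
    class = "t3_run"
  )
}

# Fraction of true sites recovered by a called peak of the correct category.
category_recovery <- function(classification, truth) {
  true_sites <- filter(truth$sites, .data$category != "none")
  called <- classification$peaks
  if (nrow(called) == 0) {
    return(tibble(n_true = nrow(true_sites), recovered = 0L, fraction = 0))
  }
  hits <- GenomicRanges::findOverlaps(intervals_to_gr(true_sites),
                                      intervals_to_gr(called))
  lab <- tibble(
    i = S4Vectors::queryHits(hits),
    category = called$category[S4Vectors::subjectHits(hits)]
  ) |> distinct(.data$i, .keep_all = TRUE)
  correct <- lab$category == true_sites$category[lab$i]
  tibble(n_true = nrow(true_sites), recovered = sum(correct),
         fraction = sum(correct) / nrow(true_sites))
}

#' Extract site sequences from the genome
#' @param sites Interval tibble.
#' @param sequences [Biostrings::DNAStringSet] keyed by chromosome.
#' @return Named character vector of site sequences.
#' @export
site_sequences <- function(sites, sequences) {
  out <- vapply(seq_len(nrow(sites)), function(i) {
    as.character(Biostrings::subseq(sequences[[sites$chrom[i]]],
                                    sites$start[i] + 1L, sites$end[i]))
  }, character(1))
  names(out) <- if ("site_id" %in% names(sites)) sites$site_id else
    paste0(sites$chrom, ":", sites$start)
  out
}

#' @export
print.t3_run <- function(x, ...) {
  s <- x$summary
  cat("<t3_run>\n")
  print(x$classification)
  cat(sprintf("  TSS partition: %d proximal, %d distal\n",
              s$n_proximal, s$n_distal))
  occ <- s$occupancy$ratio[s$occupancy$category == "maintained"]
  cat(sprintf("  maintained occupancy shift (+T3/MMI): %.3f\n", occ))
  cat(sprintf("  ATAC: %d increased, %d depleted; notch %.2f\n",
              s$atac_increased, s$atac_depleted, s$notch))
  cat(sprintf("  top DR spacer: %d\n", s$top_spacer))
  cat(sprintf("  RNA: %d induced, %d suppressed\n",
              s$n_induced, s$n_suppressed))
  print(s$blunting)
  cat(sprintf("  site-category recovery: %.1f%%\n", 100 * s$recovery$fraction))
  invisible(x)
}

#' One-row pipeline summary
#' @param x A `t3_run`.
#' @param ... Unused.
#' @return One-row tibble of headline statistics.
#' @export
glance.t3_run <- function(x, ...) {
  s <- x$summary
  tibble(
    n_mmi_peaks = s$counts$n_mmi,
    n_t3_peaks = s$counts$n_t3,
    maintained = s$counts$maintained,
    abolished = s$counts$abolished,
    de_novo = s$counts$de_novo,
    n_proximal = s$n_proximal,
    n_distal = s$n_distal,
    occupancy_ratio = s$occupancy$ratio[s$occupancy$category == "maintained"],
    atac_increased = s$atac_increased,
    atac_depleted = s$atac_depleted,
    notch = s$notch,
    top_spacer = s$top_spacer,
    n_induced = s$n_induced,
    n_suppressed = s$n_suppressed,
    pct_impaired_induced =
      s$blunting$pct_impaired[s$blunting$response == "induced"],
    pct_impaired_suppressed =
      s$blunting$pct_impaired[s$blunting$response == "suppressed"],
    matched_p = s$matched_p,
    recovery = s$recovery$fraction
  )
}
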