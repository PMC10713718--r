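#' Simulate the genome sequence and gene models
#'
#' Random background sequence with the configured chromosome layout; DR4
#' elements (AGGTCA, 4-base spacer, AGGTCA) are planted at the ground-truth
#' motif positions. Deterministic given `config$rng_seed`.
#'
#' @param config A [t3_sim_config()].
#' @param truth Optional [simulate_truth()] output (generated if missing).
#' @return List: `sequences` ([Biostrings::DNAStringSet]), `genes` (tibble),
#'   `truth`.
#' @export
simulate_genome <- function(config, truth = NULL) {
  truth <- truth %||% simulate_truth(config)
  seqs <- with_seed(config$rng_seed + 2L, {
    out <- lapply(truth$chrom_lengths, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                   prob = c(0.29, 0.21, 0.21, 0.29)), collapse = "")
    })
    spacers <- vapply(seq_len(nrow(truth$motifs)), function(i) {
      paste(sample(c("A", "C", "G", "T"), 4, replace = TRUE), collapse = "")
    }, character(1))
    for (i in seq_len(nrow(truth$motifs))) {
      cn <- truth$motifs$chrom[i]
      pos <- truth$motifs$pos[i]        # 0-based offset of the element
      element <- paste0("AGGTCA", spacers[i], "AGGTCA")
      substr(out[[cn]], pos + 1L, pos + nchar(element)) <- element
    }
    out
  })
  sequences <- Biostrings::DNAStringSet(unlist(seqs))
  names(sequences) <- names(truth$chrom_lengths)
  list(sequences = sequences, genes = truth$genes, truth = truth)
}

# Negative-binomial site count; size = Inf -> Poisson, size = 0 -> exact mean.
site_count <- function(n, mu, size) {
  if (size == 0) return(round(rep(mu, n)))
  if (!is.finite(size)) return(rpois(n, mu))
  rnbinom(n, mu = mu, size = size)
}

#' Simulate ChAP-seq read starts per condition and genotype
#'
#' The tagged genotype (`hab`) emits background reads everywhere plus
#' site-specific reads: maintained sites in every condition (+T3 counts
#' scaled by `t3_boost`, untreated at the intermediate `untreated_level`),
#' abolished sites only under MMI, de novo sites only under +T3. The control
#' genotype (`bira`) emits background only. Site counts are negative
#' binomial around `reads_per_site`; read starts are uniform within the
#' site. Deterministic given `config$rng_seed`.
#'
#' @inheritParams simulate_genome
#' @param conditions Conditions to emit (default MMI, T3, Un).
#' @return Tibble of read starts: `genotype, condition, chrom, pos`.
#' @export
simulate_chap_reads <- function(config, truth = NULL,
                                conditions = c("MMI", "T3", "Un")) {
  truth <- truth %||% simulate_truth(config)
  with_seed(config$rng_seed + 3L, {
    sites <- filter(truth$sites, .data$category != "none")
    level <- function(category, condition) {
      dplyr::case_when(
        category == "maintained" & condition == "MMI" ~ 1,
        category == "maintained" & condition == "T3" ~ config$t3_boost,
        category == "maintained" & condition == "Un" ~ config$untreated_level,
        category == "abolished" & condition == "MMI" ~ 1,
        category == "de_novo" & condition == "T3" ~ 1,
        TRUE ~ 0
      )
    }
    bg_reads <- function() {
      map_dfr(names(truth$chrom_lengths), function(cn) {
        L <- truth$chrom_lengths[[cn]]
        n <- rpois(1, config$lambda_bg * L)
        tibble(chrom = cn, pos = as.integer(floor(runif(n) * L)))
      })
    }
    out <- map_dfr(conditions, function(cond) {
      # per-site NB draws at condition-specific means
      mult <- level(sites$category, cond)
      counts <- integer(nrow(sites))
      active <- which(mult > 0)
      counts[active] <- vapply(active, function(i) {
        site_count(1, config$reads_per_site * mult[i],
                   config$site_dispersion)
      }, numeric(1))
      pos <- unlist(map(seq_len(nrow(sites)), function(i) {
        if (counts[i] == 0) return(integer(0))
        sites$start[i] +
          as.integer(floor(runif(counts[i]) *
                             (sites$end[i] - sites$start[i])))
      }))
      hab <- bind_rows(
        tibble(chrom = rep(sites$chrom, counts), pos = as.integer(pos)),
        bg_reads()
      ) |> mutate(genotype = "hab", condition = cond)
      bira <- bg_reads() |> mutate(genotype = "bira", condition = cond)
      bind_rows(hab, bira)
    })
    select(out, "genotype", "condition", "chrom", "pos")
  })
}

#' Simulate histone-mark tracks and the ATAC count matrix
#'
#' Histone tracks (H3K27ac, H3K4me1, H3K4me3) are emitted as deterministic
#' expected coverage in 50 bp bins: enhancer marks form Gaussian bumps at
#' receptor sites, induced by T3 only at distal maintained sites, with a
#' central dip (the nucleosome-clearance notch) under +T3 at
#' inducible-opening sites; H3K4me3 marks promoters, condition-independent.
#' The ATAC matrix counts every maintained site plus the configured
#' receptor-free depleted sites, with replicate negative-binomial counts and
#' +T3 fold changes at inducible (`atac_open_fold`) and depleted
#' (`atac_depleted_fold`) sites. Deterministic given `config$rng_seed`.
#'
#' @inheritParams simulate_genome
#' @param bin Histone track bin width, bp.
#' @return List: `histone` (tibble `mark, condition, chrom, start, end,
#'   value`), `atac` ([count_matrix()]), `atac_regions` (tibble with truth
#'   classes).
#' @export
simulate_histone_atac <- function(config, truth = NULL, bin = 50) {
  truth <- truth %||% simulate_truth(config)
  with_seed(config$rng_seed + 4L, {
    histone <- simulate_histone_tracks(config, truth, bin)
    atac <- simulate_atac_counts(config, truth)
    c(list(histone = histone), atac)
  })
}

simulate_histone_tracks <- function(config, truth, bin) {
  sites <- truth$sites
  genes <- truth$genes
  sd_bump <- 400
  reach <- 2000L
  amp_enh <- 4
  induction <- 2
  notch_depth <- 0.7
  notch_sd <- 120
  specs <- tidyr::expand_grid(
    mark = c("H3K27ac", "H3K4me1", "H3K4me3"),
    condition = c("MMI", "T3")
  )
  map_dfr(seq_len(nrow(specs)), function(si) {
    mark <- specs$mark[si]
    cond <- specs$condition[si]
    map_dfr(names(truth$chrom_lengths), function(cn) {
      L <- truth$chrom_lengths[[cn]]
      nb <- L %/% bin
      v <- rep(1, nb)    # baseline coverage
      add_bump <- function(center, amp, notched) {
        b0 <- max(1L, (center - reach) %/% bin)
        b1 <- min(nb, (center + reach) %/% bin)
        if (b1 < b0) return(invisible())
        x <- (seq(b0, b1) - 0.5) * bin
        bump <- amp * exp(-(x - center)^2 / (2 * sd_bump^2))
        if (notched) {
          bump <- bump * (1 - notch_depth * exp(-(x - center)^2 /
                                                  (2 * notch_sd^2)))
        }
        v[b0:b1] <<- v[b0:b1] + bump
      }
      if (mark == "H3K4me3") {
        g <- genes[genes$chrom == cn, ]
        for (i in seq_len(nrow(g))) add_bump(g$tss[i], 5, FALSE)
      } else {
        s <- sites[sites$chrom == cn & sites$category != "none", ]
        for (i in seq_len(nrow(s))) {
          center <- (s$start[i] + s$end[i]) %/% 2L
          induced <- s$category[i] == "maintained" && s$distal[i]
          amp <- amp_enh * (if (induced && cond == "T3") induction else 1)
          notched <- cond == "T3" &&
            identical(s$atac_class[i], "increased")
          add_bump(center, amp, notched)
        }
      }
      r <- rle(v)
      ends <- cumsum(r$lengths) * bin
      tibble(mark = mark, condition = cond, chrom = cn,
             start = as.integer(ends - r$lengths * bin),
             end = as.integer(pmin(ends, L)), value = r$values)
    })
  })
}

simulate_atac_counts <- function(config, truth) {
  regions <- filter(truth$sites, !is.na(.data$atac_class))
  fold <- dplyr::case_when(
    regions$atac_class == "increased" ~ config$atac_open_fold,
    regions$atac_class == "depleted" ~ config$atac_depleted_fold,
    TRUE ~ 1
  )
  reps <- config$atac_replicates
  samples <- tidyr::expand_grid(condition = c("MMI", "T3"),
                                replicate = seq_len(reps)) |>
    mutate(sample = sprintf("ATAC_%s_r%d", .data$condition, .data$replicate))
  counts <- vapply(seq_len(nrow(samples)), function(j) {
    mult <- if (samples$condition[j] == "T3") fold else rep(1, nrow(regions))
    vapply(config$atac_mean * mult,
           function(m) site_count(1, m, config$atac_dispersion),
           numeric(1))
  }, numeric(nrow(regions)))
  counts <- matrix(as.integer(counts), nrow = nrow(regions),
                   dimnames = list(regions$site_id, samples$sample))
  list(atac = count_matrix(counts, samples), atac_regions = regions)
}

#' Simulate the RNA count matrix across genotypes and conditions
#'
#' Genes carry a log-normal baseline; responsive genes change expression
#' under +T3 by their true fold (induced up, suppressed down) in the wild
#' type. In the knockout, genes flagged as blunted retain only
#' `ko_residual` of their log fold change; unblunted genes respond as in
#' the wild type. Counts are negative binomial with `rna_dispersion`.
#' Deterministic given `config$rng_seed`.
#'
#' @inheritParams simulate_genome
#' @return A [count_matrix()] of genes by `{WT,KO} x {MMI,T3} x replicates`.
#' @export
simulate_rna_counts <- function(config, truth = NULL) {
  truth <- truth %||% simulate_truth(config)
  with_seed(config$rng_seed + 5L, {
    genes <- truth$genes
    baseline <- rlnorm(nrow(genes), config$rna_baseline_meanlog,
                       config$rna_baseline_sdlog)
    lfc_wt <- log2(genes$fold) *
      dplyr::case_when(genes$response == "induced" ~ 1,
                       genes$response == "suppressed" ~ -1,
                       TRUE ~ 0)
    lfc_ko <- if_else(!is.na(genes$ko_impaired) & genes$ko_impaired,
                      config$ko_residual * lfc_wt, lfc_wt)
    samples <- tidyr::expand_grid(genotype = c("WT", "KO"),
                                  condition = c("MMI", "T3"),
                                  replicate = seq_len(config$rna_replicates)) |>
      mutate(sample = sprintf("RNA_%s_%s_r%d", .data$genotype,
                              .data$condition, .data$replicate))
    counts <- vapply(seq_len(nrow(samples)), function(j) {
      lfc <- if (samples$genotype[j] == "WT") lfc_wt else lfc_ko
      mu <- baseline * if (samples$condition[j] == "T3") 2^lfc else 1
      vapply(mu, function(m) site_count(1, m, config$rna_dispersion),
             numeric(1))
    }, numeric(nrow(genes)))
    counts <- matrix(as.integer(counts), nrow = nrow(genes),
                     dimnames = list(genes$gene_id, samples$sample))
    count_matrix(counts, samples)
  })
}

#' Simulate a complete synthetic study
#'
#' Runs every generator stage under one seed and returns the full dataset
#' with its ground truth.
#'
#' @param config A [t3_sim_config()].
#' @return A `t3_dataset` list: `config`, `truth`, `sequences`, `genes`,
#'   `chap_reads`, `histone`, `atac`, `atac_regions`, `rna`.
#' @export
simulate_t3_dataset <- function(config = t3_sim_config()) {
  truth <- simulate_truth(config)
  genome <- simulate_genome(config, truth)
  chap <- simulate_chap_reads(config, truth)
  ha <- simulate_histone_atac(config, truth)
  rna <- simulate_rna_counts(config, truth)
  structure(
    list(config = config, truth = truth, sequences = genome$sequences,
         genes = truth$genes, chap_reads = chap, histone = ha$histone,
         atac = ha$atac, atac_regions = ha$atac_regions, rna = rna),
    class = "t3_dataset"
  )
}

#' @export
print.t3_dataset <- function(x, ...) {
  cat(sprintf(
    "<t3_dataset> %d sites, %d genes, %s ChAP reads, %d ATAC regions, seed %d\n",
    nrow(x$truth$sites), nrow(x$genes),
    format(nrow(x$chap_reads), big.mark = ","),
    nrow(x$atac_regions), x$config$rng_seed))
  invisible(x)
}

#' Write a simulated dataset to standard-format files
#'
#' Emits FASTA, GTF, per-sample read-start BEDs, histone bedGraphs, ATAC and
#' RNA count TSVs with sample sheets, and a ground-truth JSON, all valid
#' inputs for the downstream modules.
#'
#' @param dataset A [simulate_t3_dataset()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_t3_dataset <- function(dataset, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  Biostrings::writeXStringSet(dataset$sequences, p("genome.fa"))
  write_gtf(dataset$genes, p("genes.gtf"))
  reads <- dataset$chap_reads
  for (gt in unique(reads$genotype)) {
    for (cond in unique(reads$condition)) {
      r <- filter(reads, .data$genotype == gt, .data$condition == cond)
      write_bed(tibble(chrom = r$chrom, start = r$pos, end = r$pos + 1L),
                p(sprintf("chap_%s_%s.bed", gt, cond)))
    }
  }
  hist <- dataset$histone
  for (mk in unique(hist$mark)) {
    for (cond in unique(hist$condition)) {
      h <- filter(hist, .data$mark == mk, .data$condition == cond)
      write_bedgraph(h, p(sprintf("%s_%s.bedgraph", mk, cond)))
    }
  }
  write_count_matrix(dataset$atac, p("atac_counts.tsv"), p("atac_samples.tsv"))
  write_count_matrix(dataset$rna, p("rna_counts.tsv"), p("rna_samples.tsv"))
  truth <- dataset$truth
  jsonlite::write_json(
    list(chrom_lengths = as.list(truth$chrom_lengths),
         sites = truth$sites, genes = truth$genes, motifs = truth$motifs),
    p("ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
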