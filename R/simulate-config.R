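#' Configuration for the synthetic T3 chromatin study
#'
#' Defaults emulate the statistical structure of the pituitary T3 study at
#' roughly 1/40 genome scale: three site categories in the printed
#' proportions (maintained/abolished/de novo = 210/216/159), 80% of sites
#' distal to any TSS, ~15% of maintained sites with hormone-inducible
#' chromatin opening, a +T3 occupancy boost of 1.34 at maintained sites,
#' gene response classes linked to maintained sites within 20 kb at the
#' published incidences (73% of induced, 24% of suppressed genes), and
#' knockout blunting probabilities of 0.89 (induced) and 0.79 (suppressed).
#' Read counts are negative binomial (size = dispersion parameter) so
#' replicate overdispersion is present; background reads are uniform at
#' `lambda_bg` per bp.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome, bp.
#' @param n_sites Named integer vector: sites per category
#'   (`maintained`, `abolished`, `de_novo`).
#' @param site_width Width of each binding site, bp.
#' @param frac_distal Fraction of sites placed distal to every TSS.
#' @param fraction_inducible_atac Fraction of maintained sites (all drawn
#'   from the distal pool) given hormone-inducible chromatin opening.
#' @param n_depleted_free Number of receptor-free, T3-depleted ATAC sites.
#' @param n_genes Number of genes.
#' @param gene_length_range Gene body length range, bp.
#' @param frac_induced,frac_suppressed Fractions of genes induced/suppressed
#'   by T3.
#' @param p_induced_near,p_suppressed_near Probability that an
#'   induced/suppressed gene lies within `near_distance` of a maintained
#'   site.
#' @param near_distance Distance defining "near", bp.
#' @param ko_blunting_prob Named vector: probability that an
#'   induced/suppressed gene's response is blunted in the knockout.
#' @param reads_per_site Mean site read count per condition.
#' @param site_dispersion Negative-binomial size for site counts (`Inf` for
#'   Poisson, `0` for deterministic counts).
#' @param lambda_bg Background read rate per bp.
#' @param t3_boost Multiplier on maintained-site occupancy under +T3.
#' @param untreated_level Maintained-site occupancy multiplier in the
#'   untreated condition (intermediate between MMI and +T3).
#' @param motif_plant_rate Fraction of maintained sites with a planted DR4.
#' @param atac_mean,atac_dispersion,atac_replicates ATAC count model.
#' @param atac_open_fold,atac_depleted_fold +T3 fold change at inducible /
#'   depleted ATAC sites.
#' @param rna_baseline_meanlog,rna_baseline_sdlog Log-normal baseline
#'   expression.
#' @param rna_dispersion,rna_replicates RNA count model.
#' @param fc_range True fold-change range for responsive genes.
#' @param ko_residual Fraction of the log fold change retained by a blunted
#'   gene in the knockout.
#' @param inducible_expression_bias Sampling weight favouring genes near
#'   inducible-ATAC sites when induced genes are assigned.
#' @param inducible_fc_boost Fold-change multiplier for induced genes near an
#'   inducible-ATAC site.
#' @param rng_seed Integer seed; every generator stage is deterministic
#'   given it.
#' @return A `t3_sim_config` list.
#' @export
t3_sim_config <- function(
    n_chroms = 4,
    chrom_length = 5e6,
    n_sites = c(maintained = 210, abolished = 216, de_novo = 159),
    site_width = 300,
    frac_distal = 0.8,
    fraction_inducible_atac = 0.15,
    n_depleted_free = 10,
    n_genes = 400,
    gene_length_range = c(2000, 10000),
    frac_induced = 0.15,
    frac_suppressed = 0.21,
    p_induced_near = 0.73,
    p_suppressed_near = 0.24,
    near_distance = 20000,
    ko_blunting_prob = c(induced = 0.89, suppressed = 0.79),
    reads_per_site = 100,
    site_dispersion = 25,
    lambda_bg = 0.01,
    t3_boost = 1.34,
    untreated_level = NULL,
    motif_plant_rate = 0.5,
    atac_mean = 100,
    atac_dispersion = 30,
    atac_replicates = 4,
    atac_open_fold = 3,
    atac_depleted_fold = 1 / 3,
    rna_baseline_meanlog = log(200),
    rna_baseline_sdlog = 1,
    rna_dispersion = 50,
    rna_replicates = 4,
    fc_range = c(2, 4),
    ko_residual = 0.1,
    inducible_expression_bias = 4,
    inducible_fc_boost = 1.5,
    rng_seed = 1) {
  untreated_level <- untreated_level %||% (1 + t3_boost) / 2
  cfg <- as.list(environment())
  probs <- c(frac_distal, fraction_inducible_atac, frac_induced,
             frac_suppressed, p_induced_near, p_suppressed_near,
             ko_blunting_prob, motif_plant_rate)
  if (any(probs < 0 | probs > 1)) {
    abort("t3_sim_config: all probabilities must lie in [0, 1]")
  }
  if (lambda_bg <= 0) abort("t3_sim_config: lambda_bg must be > 0")
  if (frac_induced + frac_suppressed > 1) {
    abort("t3_sim_config: response fractions exceed 1")
  }
  if (!all(c("maintained", "abolished", "de_novo") %in% names(n_sites))) {
    abort("t3_sim_config: n_sites needs maintained/abolished/de_novo entries")
  }
  structure(cfg, class = "t3_sim_config")
}

#' @export
print.t3_sim_config <- function(x, ...) {
  cat(sprintf(
    "<t3_sim_config> genome %d x %s bp; sites m/a/d = %d/%d/%d; %d genes; seed %d\n",
    x$n_chroms, format(x$chrom_length, big.mark = ","),
    x$n_sites[["maintained"]], x$n_sites[["abolished"]],
    x$n_sites[["de_novo"]], x$n_genes, x$rng_seed))
  invisible(x)
}

sim_chrom_lengths <- function(config) {
  setNames(rep(as.integer(config$chrom_length), config$n_chroms),
           paste0("chr", seq_len(config$n_chroms)))
}

#' Ground-truth layout for a synthetic study
#'
#' Places genes and binding sites on the genome (non-overlapping sites,
#' non-overlapping genes), assigns site categories, distal/proximal status,
#' inducible/depleted ATAC classes, planted-motif positions, and gene
#' response labels with the configured linkage to maintained sites.
#' Response labels are assigned by sampling genes at the configured
#' near-site probabilities, which reproduces the preferential placement of
#' induced genes near maintained sites. Deterministic given
#' `config$rng_seed`.
#'
#' @param config A [t3_sim_config()].
#' @return A `t3_truth` list: `chrom_lengths`, `sites`, `genes`, `motifs`.
#' @export
simulate_truth <- function(config) {
  with_seed(config$rng_seed + 1L, simulate_truth_impl(config))
}

simulate_truth_impl <- function(config) {
  chrom_lengths <- sim_chrom_lengths(config)
  n_cat <- config$n_sites
  n_cat_distal <- round(config$frac_distal * n_cat)
  n_cat_prox <- n_cat - n_cat_distal
  n_distal <- sum(n_cat_distal) + config$n_depleted_free
  n_prox <- sum(n_cat_prox)
  margin <- 1000L

  # one block per placed element (genes + distal sites); uniform offset inside
  n_elements <- config$n_genes + n_distal
  max_len <- max(config$gene_length_range)
  per_chrom <- diff(round(seq(0, n_elements, length.out = config$n_chroms + 1)))
  if (floor(chrom_lengths[1] / max(per_chrom)) < max_len + 2 * margin) {
    abort("simulate_truth: genome too small for requested genes and sites (capacity)")
  }
  kind <- sample(c(rep("gene", config$n_genes), rep("site", n_distal)))
  chrom_of <- rep(names(chrom_lengths), per_chrom)
  block_start <- unlist(lapply(per_chrom, function(k) {
    (seq_len(k) - 1L)
  }))
  block_of_chrom <- floor(chrom_lengths[1] / max(per_chrom)) # equal chroms
  el <- tibble(
    kind = kind,
    chrom = chrom_of,
    block_lo = block_start * block_of_chrom,
    block_hi = (block_start + 1L) * block_of_chrom
  )

  # genes first: random interval inside the block
  genes_el <- filter(el, .data$kind == "gene")
  glen <- round(runif(nrow(genes_el), config$gene_length_range[1],
                      config$gene_length_range[2]))
  gstart <- genes_el$block_lo + margin +
    floor(runif(nrow(genes_el)) *
            pmax(1, genes_el$block_hi - genes_el$block_lo -
                   2 * margin - glen))
  genes <- tibble(
    gene_id = sprintf("gene%04d", seq_len(nrow(genes_el))),
    chrom = genes_el$chrom,
    start = as.integer(gstart),
    end = as.integer(gstart + glen),
    strand = sample(c("+", "-"), nrow(genes_el), replace = TRUE)
  ) |> add_tss()

  # distal sites: rejection-sample an offset clear of every TSS +/- 1 kb
  sites_el <- filter(el, .data$kind == "site")
  w <- as.integer(config$site_width)
  tss_by_chrom <- split(genes$tss, genes$chrom)
  place_distal <- function(chrom, lo, hi) {
    tss <- tss_by_chrom[[chrom]] %||% integer(0)
    for (try in 1:100) {
      s <- lo + margin + floor(runif(1) * max(1, hi - lo - 2 * margin - w))
      if (length(tss) == 0 || all(s + w <= tss - 1000 | s >= tss + 1001)) {
        return(as.integer(s))
      }
    }
    abort("simulate_truth: could not place a distal site (capacity)")
  }
  dstart <- map_int(seq_len(nrow(sites_el)), function(i) {
    place_distal(sites_el$chrom[i], sites_el$block_lo[i], sites_el$block_hi[i])
  })
  distal_sites <- tibble(chrom = sites_el$chrom, start = dstart,
                         end = dstart + w, distal = TRUE)

  # proximal sites: centered near the TSS of distinct random genes
  prox_gene <- genes[sample(nrow(genes), n_prox), ]
  pstart <- as.integer(prox_gene$tss - w %/% 2 +
                         round(runif(n_prox, -200, 200)))
  prox_sites <- tibble(chrom = prox_gene$chrom, start = pstart,
                       end = pstart + w, distal = FALSE)

  sites <- bind_rows(distal_sites, prox_sites)

  # category assignment: depleted-free sites are distal and receptor-free
  distal_idx <- which(sites$distal)
  prox_idx <- which(!sites$distal)
  free_idx <- sample(distal_idx, config$n_depleted_free)
  categories <- rep(NA_character_, nrow(sites))
  categories[free_idx] <- "none"
  pool_d <- sample(setdiff(distal_idx, free_idx))
  pool_p <- sample(prox_idx)
  stopifnot(length(pool_d) >= sum(n_cat_distal),
            length(pool_p) >= sum(n_cat_prox))
  categories[pool_d[seq_len(sum(n_cat_distal))]] <-
    rep(names(n_cat), n_cat_distal)
  categories[pool_p[seq_len(sum(n_cat_prox))]] <-
    rep(names(n_cat), n_cat_prox)
  # any leftover placed-but-unneeded slots become extra background (drop)
  sites$category <- categories
  sites <- filter(sites, !is.na(.data$category))

  # ATAC classes: inducible opening only at distal maintained sites
  maint_idx <- which(sites$category == "maintained")
  maint_distal_idx <- which(sites$category == "maintained" & sites$distal)
  n_inducible <- round(config$fraction_inducible_atac * length(maint_idx))
  inducible_idx <- sample(maint_distal_idx, n_inducible)
  sites$atac_class <- NA_character_
  sites$atac_class[maint_idx] <- "constitutive"
  sites$atac_class[inducible_idx] <- "increased"
  sites$atac_class[sites$category == "none"] <- "depleted"

  # planted DR4 motifs at maintained sites
  sites$motif_planted <- FALSE
  planted <- maint_idx[runif(length(maint_idx)) < config$motif_plant_rate]
  sites$motif_planted[planted] <- TRUE
  sites$site_id <- sprintf("site%04d", seq_len(nrow(sites)))
  sites <- select(sites, "site_id", "chrom", "start", "end", "category",
                  "distal", "atac_class", "motif_planted") |>
    arrange(.data$chrom, .data$start)
  motifs <- sites |>
    filter(.data$motif_planted) |>
    mutate(pos = (.data$start + .data$end) %/% 2L - 8L, spacer = 4L) |>
    select("chrom", "pos", "spacer")

  genes <- assign_gene_responses(config, genes, sites)

  structure(
    list(chrom_lengths = chrom_lengths, sites = sites, genes = genes,
         motifs = motifs),
    class = "t3_truth"
  )
}

# Sample response labels so that P(near maintained site | class) matches the
# configured incidences, with extra weight for genes near inducible sites.
assign_gene_responses <- function(config, genes, sites) {
  maint <- filter(sites, .data$category == "maintained")
  induc <- filter(sites, .data$atac_class %in% "increased")
  d_maint <- gene_site_distance(genes, maint)
  d_induc <- gene_site_distance(genes, induc)
  near <- d_maint <= config$near_distance
  near_induc <- d_induc <= config$near_distance
  n_ind <- round(config$frac_induced * nrow(genes))
  n_sup <- round(config$frac_suppressed * nrow(genes))
  pick <- function(pool, n, weights = NULL) {
    if (n == 0) return(integer(0))
    if (length(pool) < n) abort("simulate_truth: too few genes in a linkage pool")
    if (is.null(weights)) sample(pool, n) else sample(pool, n, prob = weights)
  }
  available <- seq_len(nrow(genes))
  # induced: configured share from the near pool, biased toward inducible sites
  n_ind_near <- round(config$p_induced_near * n_ind)
  pool_near <- available[near[available]]
  wts <- ifelse(near_induc[pool_near], config$inducible_expression_bias, 1)
  ind_near <- pick(pool_near, n_ind_near, wts)
  available <- setdiff(available, ind_near)
  ind_far <- pick(available[!near[available]], n_ind - n_ind_near)
  available <- setdiff(available, ind_far)
  induced <- c(ind_near, ind_far)
  n_sup_near <- round(config$p_suppressed_near * n_sup)
  sup_near <- pick(available[near[available]], n_sup_near)
  available <- setdiff(available, sup_near)
  sup_far <- pick(available[!near[available]], n_sup - n_sup_near)
  suppressed <- c(sup_near, sup_far)

  genes$response <- "unchanged"
  genes$response[induced] <- "induced"
  genes$response[suppressed] <- "suppressed"
  genes$ko_impaired <- NA
  genes$ko_impaired[induced] <-
    runif(length(induced)) < config$ko_blunting_prob[["induced"]]
  genes$ko_impaired[suppressed] <-
    runif(length(suppressed)) < config$ko_blunting_prob[["suppressed"]]
  fold <- runif(nrow(genes), config$fc_range[1], config$fc_range[2])
  boost <- genes$response == "induced" & near_induc
  fold[boost] <- fold[boost] * config$inducible_fc_boost
  genes$fold <- if_else(genes$response == "unchanged", 1, fold)
  genes
}
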