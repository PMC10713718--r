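#' Fraction of genes with a chromatin site within a distance
#'
#' A gene counts iff some site interval lies within `d` bp of its gene body
#' (distance 0 inside the body). Fractions are reported per response class
#' when the gene table carries a `response` column.
#'
#' @param genes Gene tibble (`chrom, start, end`, optionally `response`).
#' @param sites Site interval tibble.
#' @param d Distance from the gene body, bp (default 20000).
#' @return Tibble: `response, n_genes, n_with_site, fraction`.
#' @export
genes_with_site_within <- function(genes, sites, d = 20000) {
  genes <- as_tibble(genes)
  if (!"response" %in% names(genes)) genes$response <- "all"
  has_site <- gene_site_distance(genes, sites) <= d
  genes |>
    mutate(has_site = has_site) |>
    group_by(.data$response) |>
    summarise(n_genes = dplyr::n(), n_with_site = sum(.data$has_site),
              .groups = "drop") |>
    mutate(fraction = .data$n_with_site / .data$n_genes)
}

# Distance from each gene body to its nearest site (0 when overlapping,
# Inf when the chromosome has no site).
gene_site_distance <- function(genes, sites) {
  if (nrow(sites) == 0 || nrow(genes) == 0) return(rep(Inf, nrow(genes)))
  g <- intervals_to_gr(genes)
  s <- intervals_to_gr(sites)
  hit <- GenomicRanges::distanceToNearest(g, s)
  out <- rep(Inf, nrow(genes))
  out[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  out
}

#' Distance-resolved site-gene association curve
#'
#' For a grid of distances up to `d_max`, the fraction of genes in each
#' response class with at least one site within that distance of the gene
#' body, plus the induced/suppressed fraction ratio per distance. Fractions
#' are non-decreasing in distance by construction.
#'
#' @inheritParams genes_with_site_within
#' @param d_max Maximum distance, bp (default 100000).
#' @param step Grid step, bp (default 5000).
#' @return An `association_curve` tibble: `distance, response, n_genes,
#'   n_with_site, fraction`, with the per-distance induced/suppressed ratio
#'   in `attr(, "ratio")`.
#' @export
association_curve <- function(genes, sites, d_max = 100000, step = 5000) {
  genes <- as_tibble(genes)
  if (!"response" %in% names(genes)) genes$response <- "all"
  dist <- gene_site_distance(genes, sites)
  grid <- seq(0, d_max, by = step)
  out <- map_dfr(grid, function(d) {
    genes |>
      mutate(has_site = dist <= d) |>
      group_by(.data$response) |>
      summarise(n_genes = dplyr::n(), n_with_site = sum(.data$has_site),
                .groups = "drop") |>
      mutate(distance = d, fraction = .data$n_with_site / .data$n_genes)
  }) |>
    select("distance", "response", "n_genes", "n_with_site", "fraction")
  ratio <- NULL
  if (all(c("induced", "suppressed") %in% out$response)) {
    wide <- pivot_wider(out, id_cols = "distance", names_from = "response",
                        values_from = "fraction")
    ratio <- tibble(distance = wide$distance,
                    ratio = wide$induced / wide$suppressed)
  }
  attr(out, "ratio") <- ratio
  class(out) <- c("association_curve", class(out))
  out
}

#' Knockout blunting of hormone-responsive genes
#'
#' For every gene the wild type calls responsive, the knockout is
#' `unimpaired` iff it shows a same-direction fold change passing the same
#' thresholds that defined the wild-type response (>= 1.5-fold, p < 0.05 by
#' default, i.e. the gene's knockout response class matches its wild-type
#' class); otherwise the gene is `impaired` (blunted). Percentages are
#' reported to the nearest integer with raw fractions alongside.
#'
#' @param wt_results,ko_results Outputs of [rna_differential()] for the two
#'   genotypes on the same gene universe.
#' @return A `blunting_summary` tibble: `response, total, impaired,
#'   unimpaired, fraction_impaired, pct_impaired`.
#' @export
classify_blunting <- function(wt_results, ko_results) {
  responsive <- filter(wt_results, .data$response != "unchanged")
  missing_genes <- setdiff(responsive$gene_id, ko_results$gene_id)
  if (length(missing_genes) > 0) {
    abort(sprintf("classify_blunting: gene(s) missing in KO results: %s",
                  paste(head(missing_genes, 3), collapse = ", ")))
  }
  joined <- left_join(responsive,
                      select(ko_results, "gene_id", ko_response = "response"),
                      by = "gene_id")
  joined <- mutate(joined,
                   impaired = .data$ko_response != .data$response)
  per_gene <- select(joined, "gene_id", "response", "ko_response", "impaired")
  out <- joined |>
    group_by(.data$response) |>
    summarise(total = dplyr::n(), impaired = sum(.data$impaired),
              .groups = "drop") |>
    mutate(unimpaired = .data$total - .data$impaired)
  out <- blunting_summary(out$response, out$total, out$impaired)
  attr(out, "per_gene") <- per_gene
  out
}

#' Blunting summary from class counts
#'
#' The percentage arithmetic of [classify_blunting()], applied directly to
#' per-class totals and impaired counts: `pct_impaired` is
#' `100 * impaired / total` rounded to the nearest integer, with the raw
#' fraction always reported alongside.
#'
#' @param response Class labels (e.g. `"induced"`, `"suppressed"`).
#' @param total,impaired Integer counts per class.
#' @return A `blunting_summary` tibble.
#' @examples
#' blunting_summary(c("induced", "suppressed"), c(516, 714), c(460, 570))
#' @export
blunting_summary <- function(response, total, impaired) {
  stopifnot(length(response) == length(total), length(total) == length(impaired),
            all(impaired <= total), all(impaired >= 0))
  out <- tibble(
    response = response,
    total = as.integer(total),
    impaired = as.integer(impaired),
    unimpaired = as.integer(total - impaired),
    fraction_impaired = impaired / total,
    pct_impaired = round(100 * impaired / total)
  )
  class(out) <- c("blunting_summary", class(out))
  out
}

#' Matched inducible-vs-constitutive site comparison
#'
#' Selects the top-N constitutive sites by mean normalized accessibility
#' (N = number of inducible sites; ties broken by coordinate), collects for
#' each group every gene whose body lies within `window` bp of at least one
#' group site (deduplicated), and compares the two groups' gene log2
#' fold-change distributions by Mann-Whitney.
#'
#' @param inducible_sites Site tibble of hormone-inducible open-chromatin
#'   sites.
#' @param constitutive_pool Site tibble of non-regulated sites; must carry a
#'   `mean_signal` column (mean normalized count) and have at least
#'   N rows.
#' @param genes Gene tibble.
#' @param gene_fc Tibble `gene_id, log2fc` of gene expression responses.
#' @param window Distance window, bp (default 100000).
#' @return A `matched_comparison` list: `constitutive_selected`,
#'   `genes_inducible`, `genes_constitutive` (gene-id vectors),
#'   `fc_inducible`, `fc_constitutive`, and `test` (see
#'   [mann_whitney_u()]).
#' @export
matched_group_comparison <- function(inducible_sites, constitutive_pool,
                                     genes, gene_fc, window = 100000) {
  n <- nrow(inducible_sites)
  if (nrow(constitutive_pool) < n) {
    abort("matched_group_comparison: constitutive pool smaller than inducible group")
  }
  if (!"mean_signal" %in% names(constitutive_pool)) {
    abort("matched_group_comparison: constitutive pool needs a mean_signal column")
  }
  selected <- constitutive_pool |>
    arrange(desc(.data$mean_signal), .data$chrom, .data$start) |>
    head(n)
  group_genes <- function(sites) {
    d <- gene_site_distance(genes, sites)
    unique(genes$gene_id[d <= window])
  }
  g_ind <- group_genes(inducible_sites)
  g_con <- group_genes(selected)
  fc_of <- function(ids) {
    gene_fc$log2fc[match(intersect(ids, gene_fc$gene_id), gene_fc$gene_id)]
  }
  fc_ind <- fc_of(g_ind)
  fc_con <- fc_of(g_con)
  structure(
    list(constitutive_selected = selected,
         genes_inducible = g_ind, genes_constitutive = g_con,
         fc_inducible = fc_ind, fc_constitutive = fc_con,
         test = mann_whitney_u(fc_ind, fc_con)),
    class = "matched_comparison"
  )
}

#' @export
print.matched_comparison <- function(x, ...) {
  cat(sprintf(
    "<matched_comparison> %d matched sites per group\n",
    nrow(x$constitutive_selected)))
  cat(sprintf("  genes: %d vs %d; median log2FC %.3f vs %.3f; MW p = %.3g\n",
              x$test$n_a, x$test$n_b, x$test$median_a, x$test$median_b,
              x$test$p))
  invisible(x)
}

#' @export
glance.matched_comparison <- function(x, ...) x$test
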