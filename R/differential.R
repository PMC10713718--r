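#' Differential ATAC accessibility between conditions
#'
#' Per region, the log2 fold change of mean CPM (+0.5 pseudocount) between
#' the two condition groups, and a two-sided exact conditional-binomial test:
#' given the pooled count of a region, the group-B share is binomial with
#' success probability equal to group B's share of the summed library sizes
#' under the null of equal rates. P-values are Benjamini-Hochberg adjusted.
#' A region is `increased` iff `log2FC >= lfc_threshold` and adjusted
#' `p <= alpha`, `depleted` iff `log2FC <= -lfc_threshold` and adjusted
#' `p <= alpha`, else `unchanged`.
#'
#' @param x A [count_matrix()] whose sample sheet has a `condition` column.
#' @param group_a,group_b Condition labels (baseline, treatment). Default
#'   MMI vs T3.
#' @param lfc_threshold Absolute log2 fold-change threshold (default 0.58,
#'   i.e. 1.5-fold).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return Tibble: `feature, log2fc, p, p_adj, class`.
#' @export
atac_differential <- function(x, group_a = "MMI", group_b = "T3",
                              lfc_threshold = 0.58, alpha = 0.05) {
  a_cols <- which(x$samples$condition == group_a)
  b_cols <- which(x$samples$condition == group_b)
  if (length(a_cols) < 2 || length(b_cols) < 2) {
    abort("atac_differential: need >= 2 replicates per group")
  }
  cpm_m <- cpm(x)
  mean_a <- rowMeans(cpm_m[, a_cols, drop = FALSE])
  mean_b <- rowMeans(cpm_m[, b_cols, drop = FALSE])
  log2fc <- log2((mean_b + 0.5) / (mean_a + 0.5))
  sum_a <- rowSums(x$counts[, a_cols, drop = FALSE])
  sum_b <- rowSums(x$counts[, b_cols, drop = FALSE])
  lib_a <- sum(x$lib_sizes[a_cols])
  lib_b <- sum(x$lib_sizes[b_cols])
  pr_b <- lib_b / (lib_a + lib_b)
  p <- vapply(seq_along(sum_a), function(i) {
    tot <- sum_a[i] + sum_b[i]
    if (tot == 0) return(1)
    binom.test(sum_b[i], tot, p = pr_b)$p.value
  }, numeric(1))
  p_adj <- p.adjust(p, method = "BH")
  cls <- dplyr::case_when(
    log2fc >= lfc_threshold & p_adj <= alpha ~ "increased",
    log2fc <= -lfc_threshold & p_adj <= alpha ~ "depleted",
    TRUE ~ "unchanged"
  )
  tibble(feature = rownames(x$counts), log2fc = unname(log2fc),
         p = unname(p), p_adj = unname(p_adj), class = cls)
}

#' Per-gene T3 response classification from RNA counts
#'
#' Genes are first filtered to those with CPM above `cpm_min` in every sample
#' of the matrix. Per gene, the mean-CPM T3/MMI fold and a two-sided
#' two-sample Student t-test (pooled variance by default) on log2(CPM + 0.5)
#' decide the class: `induced` iff fold >= `fc_threshold` and raw
#' `p < alpha`; `suppressed` symmetric; else `unchanged`. The raw (not
#' adjusted) p-value is thresholded, matching the published RNA criteria;
#' the ATAC stage, by contrast, uses adjusted p.
#'
#' @param x A [count_matrix()] with `condition` in its sample sheet;
#'   restrict to one genotype before calling (see examples).
#' @param group_a,group_b Condition labels (default MMI, T3).
#' @param fc_threshold Fold-change threshold (default 1.5).
#' @param cpm_min CPM expression floor applied to all samples (default 1).
#' @param alpha Raw-p threshold (default 0.05).
#' @param welch Use Welch instead of pooled-variance Student (default FALSE).
#' @return Tibble: `gene_id, fold, log2fc, p, response`.
#' @export
rna_differential <- function(x, group_a = "MMI", group_b = "T3",
                             fc_threshold = 1.5, cpm_min = 1, alpha = 0.05,
                             welch = FALSE) {
  a_cols <- which(x$samples$condition == group_a)
  b_cols <- which(x$samples$condition == group_b)
  if (length(a_cols) < 2 || length(b_cols) < 2) {
    abort("rna_differential: need >= 2 replicates per group")
  }
  cpm_m <- cpm(x)
  keep <- rowSums(cpm_m > cpm_min) == ncol(cpm_m)
  cpm_m <- cpm_m[keep, , drop = FALSE]
  if (nrow(cpm_m) == 0) {
    return(tibble(gene_id = character(), fold = numeric(), log2fc = numeric(),
                  p = numeric(), response = character()))
  }
  lm_a <- log2(cpm_m[, a_cols, drop = FALSE] + 0.5)
  lm_b <- log2(cpm_m[, b_cols, drop = FALSE] + 0.5)
  fold <- rowMeans(cpm_m[, b_cols, drop = FALSE]) /
    rowMeans(cpm_m[, a_cols, drop = FALSE])
  p <- vapply(seq_len(nrow(cpm_m)), function(i) {
    va <- lm_a[i, ]; vb <- lm_b[i, ]
    if (stats::sd(c(va, vb)) == 0) return(1)
    t.test(vb, va, var.equal = !welch)$p.value
  }, numeric(1))
  response <- dplyr::case_when(
    fold >= fc_threshold & p < alpha ~ "induced",
    fold <= 1 / fc_threshold & p < alpha ~ "suppressed",
    TRUE ~ "unchanged"
  )
  tibble(gene_id = rownames(cpm_m), fold = unname(fold),
         log2fc = unname(log2(fold)), p = unname(p), response = response)
}

#' Subset a count matrix to selected samples
#' @param x A `count_matrix`.
#' @param keep Logical/integer vector over samples, or an expression on the
#'   sample sheet via `filter_samples(x, genotype == "WT")`.
#' @return A `count_matrix` restricted to those samples.
#' @export
filter_samples <- function(x, keep) {
  expr <- rlang::enquo(keep)
  sel <- rlang::eval_tidy(expr, data = x$samples)
  if (is.logical(sel)) sel <- which(sel)
  count_matrix(x$counts[, sel, drop = FALSE], x$samples[sel, ],
               lib_sizes = x$lib_sizes[sel])
}

#' Mann-Whitney U test (two-sided, tie-corrected)
#'
#' Wraps the rank-sum machinery of [stats::wilcox.test()] (exact enumeration
#' for small untied samples, otherwise normal approximation with continuity
#' and tie correction) and reports the U statistic and group medians.
#'
#' @param values_a,values_b Numeric vectors.
#' @return Tibble: `u, p, median_a, median_b, n_a, n_b`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(values_a, values_b) {
  wt <- suppressWarnings(wilcox.test(values_a, values_b,
                                     alternative = "two.sided"))
  tibble(
    u = unname(wt$statistic),
    p = wt$p.value,
    median_a = median(values_a),
    median_b = median(values_b),
    n_a = length(values_a),
    n_b = length(values_b)
  )
}
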