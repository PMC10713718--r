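#' Plot a site-anchored signal heatmap
#' @param object A `signal_matrix` from [build_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.signal_matrix <- function(object, ...) {
  tidy(object) |>
    ggplot(aes(x = .data$position, y = .data$site_rank,
               fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(name = "signal") +
    labs(x = "distance from site center (bp)",
         y = "site (ranked by center intensity)") +
    theme_minimal()
}

#' Plot an average profile curve
#' @param object A `profile_curve` from [average_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.profile_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$position, y = .data$value)) +
    geom_line() +
    labs(x = "distance from site center (bp)", y = "mean signal") +
    theme_minimal()
}

#' Plot a distance-resolved association curve
#' @param object An `association_curve` from [association_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.association_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$distance / 1000, y = .data$fraction,
                     colour = .data$response)) +
    geom_step() +
    labs(x = "distance from gene body (kb)",
         y = "fraction of genes with a site") +
    theme_minimal()
}

#' Plot per-spacer repeat enrichment
#' @param object A `spacer_enrichment` from [spacer_enrichment()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spacer_enrichment <- function(object, ...) {
  ggplot(object, aes(x = factor(.data$spacer), y = -log10(.data$p))) +
    geom_col() +
    labs(x = "spacer (bp between half-sites)",
         y = expression(-log[10] ~ p)) +
    theme_minimal()
}

#' Compare average profiles across conditions
#'
#' @param curves Named list of `profile_curve` tibbles (names become the
#'   condition legend).
#' @return A ggplot.
#' @export
plot_profiles <- function(curves) {
  bind_rows(purrr::imap(curves, ~ mutate(.x, condition = .y))) |>
    ggplot(aes(x = .data$position, y = .data$value,
               colour = .data$condition)) +
    geom_line() +
    labs(x = "distance from site center (bp)", y = "mean signal") +
    theme_minimal()
}
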