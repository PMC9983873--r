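#' Kaplan-Meier curve plot
#'
#' Step plot of survival curves from [km_estimate()], one step function per
#' group, with censoring ticks.
#'
#' @param km Tibble from [km_estimate()].
#' @return A ggplot object.
#' @export
plot_km <- function(km) {
  if (!"group" %in% names(km)) km$group <- "all"
  start <- km |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, survival = 1, n_censor = 0)
  df <- dplyr::bind_rows(start, km) |> dplyr::arrange(.data$group, .data$time)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = dplyr::filter(df, .data$n_censor > 0), shape = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Enrichment dot plot
#'
#' Shows each tested gene set's overlap and Benjamini-Hochberg q-value.
#'
#' @param enrichment Tibble from [enrich_overrep()].
#' @param q_cutoff Significance line to draw (default 0.05).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, q_cutoff = 0.05) {
  df <- enrichment |>
    dplyr::mutate(set_name = stats::reorder(.data$set_name, -log10(.data$q_value)))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$q_value), y = .data$set_name,
                                   size = .data$overlap)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = -log10(q_cutoff), linetype = 2) +
    ggplot2::labs(x = expression(-log[10] ~ "q"), y = NULL, size = "overlap") +
    ggplot2::theme_minimal()
}

#' IHC bin proportion plot
#'
#' Proportion of specimens in the negative / weak / strong staining bins per
#' tissue, mirroring the histogram view of a tissue-microarray comparison.
#'
#' @param ihc Tibble with columns `tissue` and `score` (half-point grid).
#' @return A ggplot object.
#' @export
plot_ihc_bins <- function(ihc) {
  df <- ihc |>
    dplyr::mutate(bin = bin_ihc(.data$score)) |>
    dplyr::count(.data$tissue, .data$bin) |>
    dplyr::group_by(.data$tissue) |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tissue, y = .data$prop, fill = .data$bin)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of specimens", fill = "IHC bin") +
    ggplot2::theme_minimal()
}
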