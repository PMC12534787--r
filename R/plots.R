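#' Amino-acid frequency barplot per region
#'
#' @param aa_frequencies Tibble from the pipeline report (`region`, `aa`,
#'   `percent`) or a single-region [aa_frequency_profile()].
#' @return A ggplot object.
#' @export
plot_aa_frequencies <- function(aa_frequencies) {
  df <- aa_frequencies
  if (!"region" %in% names(df)) df$region <- "set"
  df$region <- factor(df$region, levels = REGIONS)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$aa, y = .data$percent,
                                   fill = .data$region)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "amino acid", y = "frequency (%)", fill = "region") +
    ggplot2::theme_minimal()
}

#' Region mean barplot with per-protein points
#'
#' Mirrors the standard three-bar region comparison: mean of per-protein
#' region means with 95% confidence intervals, annotated with the paired
#' t-test star tiers when supplied.
#'
#' @param summaries Region summaries concatenated over proteins.
#' @param tests Optional `tg_paired_tests` tibble for star annotations.
#' @return A ggplot object.
#' @export
plot_region_means <- function(summaries, tests = NULL) {
  df <- summaries %>%
    dplyr::filter(!is.na(.data$mean_score)) %>%
    dplyr::mutate(region = factor(.data$region, levels = REGIONS))
  agg <- df %>%
    dplyr::group_by(.data$region) %>%
    dplyr::summarise(
      m = mean(.data$mean_score),
      se = stats::sd(.data$mean_score) / sqrt(dplyr::n()),
      .groups = "drop"
    ) %>%
    dplyr::mutate(lo = .data$m - 1.96 * .data$se,
                  hi = .data$m + 1.96 * .data$se)
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$region, y = .data$m)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.2) +
    ggplot2::geom_jitter(data = df,
                         ggplot2::aes(x = .data$region, y = .data$mean_score),
                         width = 0.08, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = NULL, y = "mean pathogenicity") +
    ggplot2::theme_minimal()
  if (!is.null(tests)) {
    ymax <- max(df$mean_score)
    lab <- paste(tests$comparison, tests$stars, sep = ": ")
    p <- p + ggplot2::annotate("text", x = 2, y = ymax * 1.08,
                               label = paste(lab, collapse = "   "),
                               size = 3)
  }
  p
}

#' Score-frequency heatmap per region
#'
#' @param heatmap_counts Tibble from [score_frequency_heatmap()].
#' @return A ggplot object (amino acid x score bin, faceted by region).
#' @export
plot_score_heatmap <- function(heatmap_counts) {
  df <- heatmap_counts %>%
    dplyr::mutate(region = factor(.data$region, levels = REGIONS),
                  mid = (.data$bin_lo + .data$bin_hi) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$aa,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~region) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "mean pathogenicity", y = "amino acid",
                  fill = "residues") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tg_report <- function(object, ...) {
  plot_region_means(object$summaries, object$paired_tests)
}
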