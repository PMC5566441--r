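#' Droplet amplitude scatter plot
#'
#' One panel per well: droplet index against fluorescence amplitude,
#' colored by classification when thresholds are supplied (mimicking the
#' droplet reader's 1D scatter view).
#'
#' @param wells a `droplet_wells` tibble.
#' @param counts optional `classified_counts` providing per-well thresholds.
#' @return a ggplot object.
#' @export
plot_droplets <- function(wells, counts = NULL) {
  long <- wells |>
    select("well_id", "amplitudes") |>
    unnest("amplitudes") |>
    rename(amplitude = "amplitudes") |>
    group_by(.data$well_id) |>
    mutate(droplet = row_number()) |>
    ungroup()
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$droplet,
                                          y = .data$amplitude))
  if (!is.null(counts)) {
    long <- long |>
      left_join(counts |> select("well_id", "threshold"), by = "well_id") |>
      mutate(class = ifelse(.data$amplitude > .data$threshold,
                            "positive", "negative"))
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$droplet,
                                            y = .data$amplitude,
                                            colour = .data$class)) +
      ggplot2::geom_hline(ggplot2::aes(yintercept = .data$threshold),
                          data = counts, linetype = "dashed") +
      ggplot2::scale_colour_manual(values = c(positive = "#2166ac",
                                              negative = "grey60"))
  }
  p + ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$well_id)) +
    ggplot2::labs(x = "droplet", y = "fluorescence amplitude (a.u.)")
}

#' Plot transcripts-per-gene results with confidence intervals
#'
#' @param object a `selfie_results` tibble ([transcripts_per_gene()]).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.selfie_results <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$sample_id,
                               y = .data$transcripts_per_gene,
                               colour = .data$target)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = NULL, y = "transcripts per gene")
}

#' Plot a tandem-linkage bias curve
#'
#' @param object a `linkage_curve` tibble ([linkage_bias_experiment()]).
#' @param ... unused.
#' @return a ggplot object on log-log axes with the no-linkage expectation.
#' @export
autoplot.linkage_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$copies_per_fragment,
                                       y = .data$estimate)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected_fragments_per_genome),
                       linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "tandem copies per DNA fragment",
                  y = "estimated copies per genome")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
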