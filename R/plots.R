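#' Inflow/outflow scatter of a Markov fit
#'
#' One point per BGC in (outflow, inflow) space, colored by classification,
#' with the decision thresholds drawn as dashed lines — the standard
#' portrait of persistent (upper-left) versus transient (lower-right)
#' clusters.
#'
#' @param fit A `markov_fit` from [fit_markov()].
#' @return A ggplot object.
#' @export
plot_inflow_outflow <- function(fit) {
  est <- tidy(fit)
  ggplot2::ggplot(
    dplyr::filter(est, !is.na(.data$p_inflow), !is.na(.data$p_outflow)),
    ggplot2::aes(x = .data$p_outflow, y = .data$p_inflow,
                 colour = .data$classification)
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 1.2) +
    ggplot2::geom_vline(xintercept = fit$threshold, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = fit$threshold, linetype = "dashed") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "outflow probability (present → absent)",
                  y = "inflow probability (absent → present)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.markov_fit <- function(object, ...) plot_inflow_outflow(object)

#' Prevalence against the inflow/outflow ratio
#'
#' @param fit A `markov_fit`.
#' @return A ggplot object: log10(inflow/outflow) vs the fraction of
#'   subjects carrying the BGC at least once.
#' @export
plot_prevalence_ratio <- function(fit) {
  est <- dplyr::filter(tidy(fit), is.finite(.data$log10_ratio))
  ggplot2::ggplot(est, ggplot2::aes(x = .data$log10_ratio,
                                    y = .data$prevalence,
                                    colour = .data$classification)) +
    ggplot2::geom_point(alpha = 0.6, size = 1.2) +
    ggplot2::labs(x = "log10(inflow / outflow)",
                  y = "prevalence (subjects with ≥ 1 detection)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of the cutoff-optimization grid
#'
#' F1 at each (gene cutoff, BGC cutoff) grid point, with the selected pair
#' outlined.
#'
#' @param object A `cutoff_grid` from [evaluate_cutoffs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cutoff_grid <- function(object, ...) {
  sel <- attr(object, "selected")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$gene_cutoff, y = .data$bgc_cutoff,
                               fill = .data$f1)) +
    ggplot2::geom_tile() +
    ggplot2::annotate("point", x = sel$gene_cutoff, y = sel$bgc_cutoff,
                      shape = 21, size = 4, colour = "red", fill = NA) +
    ggplot2::labs(x = "gene coverage cutoff", y = "BGC gene-fraction cutoff",
                  fill = "F1") +
    ggplot2::theme_minimal()
}

#' Boxplot of triad colonization rates by BGC class
#'
#' @param rates Output of [fmt_colonization()].
#' @param by_response Facet by clinical response.
#' @return A ggplot object.
#' @export
plot_colonization <- function(rates, by_response = FALSE) {
  p <- ggplot2::ggplot(
    dplyr::filter(rates, !is.na(.data$rate)),
    ggplot2::aes(x = .data$classification, y = .data$rate,
                 fill = .data$classification)
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.8, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "triad colonization rate") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (by_response) p <- p + ggplot2::facet_wrap(~response)
  p
}

#' Shared-fraction scatter for FMT triads
#'
#' Each point is one triad within one BGC class: the fraction of its
#' post-FMT BGCs shared with the donor (x) against the fraction shared
#' with the pre-FMT sample (y).
#'
#' @param rates Output of [fmt_colonization()].
#' @return A ggplot object.
#' @export
plot_shared_fractions <- function(rates) {
  ggplot2::ggplot(
    dplyr::filter(rates, !is.na(.data$frac_post_in_donor)),
    ggplot2::aes(x = .data$frac_post_in_donor, y = .data$frac_post_in_pre,
                 colour = .data$classification)
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "fraction of post-FMT BGCs shared with donor",
                  y = "fraction of post-FMT BGCs shared with pre-FMT",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
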