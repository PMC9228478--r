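#' Plot MZ and DZ twin correlations per metabolite
#'
#' Dot plot of the ML twin correlations from a [run_twin_pipeline()]
#' result, faceted by platform, with the reliability-band edges drawn as
#' reference lines.
#'
#' @param results A `twin_results` tibble.
#' @return A ggplot object.
#' @export
plot_twin_correlations <- function(results) {
  long <- tidyr::pivot_longer(
    dplyr::select(results, "metabolite_id", "platform", "r_mz", "r_dz"),
    cols = c("r_mz", "r_dz"), names_to = "zygosity", values_to = "r"
  )
  long$zygosity <- toupper(sub("r_", "", long$zygosity))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$r,
    y = stats::reorder(.data$metabolite_id, .data$r),
    colour = .data$zygosity
  )) +
    ggplot2::geom_vline(xintercept = c(0.4, 0.6, 0.75),
                        linetype = "dotted", colour = "grey60") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::facet_wrap(~platform, scales = "free_y") +
    ggplot2::labs(x = "twin correlation", y = NULL, colour = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot standardized variance components per metabolite
#'
#' Stacked bars of the standardized A, D/C and E shares from a
#' [run_twin_pipeline()] result, faceted by platform. For ADE fits the
#' genetic shares are pooled into the broad-sense heritability, matching
#' how such models are reported when DZ pairs are scarce.
#'
#' @param results A `twin_results` tibble.
#' @return A ggplot object.
#' @export
plot_variance_components <- function(results) {
  shares <- dplyr::mutate(
    results,
    genetic = ifelse(.data$model == "ADE", .data$h2, .data$a2),
    shared_env = ifelse(.data$model == "ACE", .data$d2_or_c2, 0),
    unique_env = .data$e2
  )
  long <- tidyr::pivot_longer(
    dplyr::select(shares, "metabolite_id", "platform", "genetic",
                  "shared_env", "unique_env"),
    cols = c("genetic", "shared_env", "unique_env"),
    names_to = "component", values_to = "share"
  )
  long$component <- factor(long$component,
                           levels = c("unique_env", "shared_env", "genetic"))
  ord <- shares$metabolite_id[order(shares$genetic)]
  long$metabolite_id <- factor(long$metabolite_id, levels = ord)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$metabolite_id, y = .data$share, fill = .data$component
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~platform, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "standardized variance share", fill = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @describeIn run_twin_pipeline Autoplot method: twin correlations.
#' @param object A `twin_results` tibble.
#' @param type `"correlations"` or `"components"`.
#' @param ... Unused.
#' @export
autoplot.twin_results <- function(object,
                                  type = c("correlations", "components"),
                                  ...) {
  type <- match.arg(type)
  if (type == "correlations") {
    plot_twin_correlations(object)
  } else {
    plot_variance_components(object)
  }
}

#' @describeIn run_association_scan Autoplot method: effect sizes with
#'   significance marks.
#' @param object A `twinmetab_scan` tibble.
#' @param ... Unused.
#' @export
autoplot.twinmetab_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$estimate,
    y = stats::reorder(.data$metabolite_id, .data$estimate),
    colour = .data$significant
  )) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error
    ), height = 0) +
    ggplot2::facet_grid(platform ~ term, scales = "free") +
    ggplot2::labs(x = "standardized effect", y = NULL,
                  colour = "q below threshold") +
    ggplot2::theme_minimal(base_size = 9)
}
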