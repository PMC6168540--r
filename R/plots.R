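#' Boxplot-style summary of projected burned-area changes
#'
#' Draws the ensemble-change summaries (median, interquartile box,
#' 2.5-97.5 % whiskers) per warming level, model variant and uncertainty
#' mode, mirroring the usual warming-level change figure.
#'
#' @param summaries the `summaries` tibble of a [run_fire_pipeline()] result
#'   (columns `level`, `variant`, `mode`, `median`, `q25`, `q75`, `q025`,
#'   `q975`).
#' @return A ggplot object.
#' @export
plot_change_summary <- function(summaries) {
  summaries <- dplyr::mutate(
    summaries,
    spec = paste0(toupper(.data$variant), "-", toupper(.data$mode)))
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$spec, fill = .data$spec)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$q025, lower = .data$q25,
                   middle = .data$median, upper = .data$q75,
                   ymax = .data$q975),
      stat = "identity", width = 0.6, show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(y = .data$q975, label = round(.data$median)),
                       vjust = -0.5, size = 3) +
    ggplot2::facet_wrap(~level, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "Burned-area change (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Drought sensitivity versus a climate normal
#'
#' Scatter of per-region `beta2` against the model covariate with the fitted
#' cross-region line, coloured by latitude when available.
#'
#' @param model a [fit_beta2_model()] object.
#' @return A ggplot object.
#' @export
plot_beta2_relation <- function(model) {
  df <- model$data
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[model$covariate]],
                                        y = .data$beta2))
  p <- if ("lat" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$lat), size = 2)
  } else p + ggplot2::geom_point(size = 2)
  p +
    ggplot2::geom_abline(intercept = model$gamma1, slope = model$gamma2) +
    ggplot2::labs(
      x = model$covariate, y = expression(beta[2]),
      colour = "Latitude",
      subtitle = sprintf("r = %.2f (p = %.3f), Moran's I p = %.2f",
                         model$correlation, model$cor_p, model$moran_p)) +
    ggplot2::theme_minimal()
}

#' SPEI series for selected regions
#'
#' @param spei a [spei_panel()] tibble.
#' @param regions optional subset of region ids.
#' @return A ggplot object.
#' @export
plot_spei_series <- function(spei, regions = NULL) {
  if (!is.null(regions)) {
    spei <- dplyr::filter(spei, .data$region %in% regions)
  }
  ggplot2::ggplot(spei, ggplot2::aes(x = .data$year, y = .data$spei)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = NULL, y = "SPEI") +
    ggplot2::theme_minimal()
}
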