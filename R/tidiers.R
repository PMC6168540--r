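#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the per-region drought-fire fits
#'
#' One row per region and coefficient, with bootstrap percentile confidence
#' intervals when replicates are attached.
#'
#' @param x a [calibrate_fire_models()] result.
#' @param conf.level CI level (default 0.95).
#' @param ... unused.
#' @return Tibble `region`, `term`, `estimate`, `conf.low`, `conf.high`.
#' @export
tidy.fire_model_set <- function(x, conf.level = 0.95, ...) {
  long <- x %>%
    dplyr::filter(.data$modelled) %>%
    dplyr::select("region", "beta1", "beta2", "beta3") %>%
    tidyr::pivot_longer(-"region", names_to = "term", values_to = "estimate")
  reps <- attr(x, "replicates")
  if (is.null(reps)) return(long)
  a <- (1 - conf.level) / 2
  ci <- reps %>%
    tidyr::pivot_longer(c("beta1", "beta2", "beta3"),
                        names_to = "term", values_to = "value") %>%
    dplyr::group_by(.data$region, .data$term) %>%
    dplyr::summarise(conf.low = quantile(.data$value, a, na.rm = TRUE),
                     conf.high = quantile(.data$value, 1 - a, na.rm = TRUE),
                     .groups = "drop")
  dplyr::left_join(long, ci, by = c("region", "term"))
}

#' One-row summary of a calibration
#'
#' @param x a [calibrate_fire_models()] result.
#' @param ... unused.
#' @return Tibble with region counts and mean in-sample / cross-validated
#'   correlations over modelled regions.
#' @export
glance.fire_model_set <- function(x, ...) {
  m <- dplyr::filter(x, .data$modelled)
  tibble::tibble(
    n_regions = nrow(x), n_modelled = nrow(m),
    mean_r = mean(m$r_insample), mean_cv = mean(m$cv_cor),
    mean_beta2 = mean(m$beta2), frac_trend = mean(m$include_trend))
}

#' Tidy the cross-region drought-sensitivity model
#'
#' @param x a [fit_beta2_model()] object.
#' @param ... unused.
#' @return Tibble `term`, `estimate`, `conf.low`, `conf.high` (bootstrap
#'   95 % percentile intervals).
#' @export
tidy.beta2_model <- function(x, ...) x$ci

#' One-row summary of the cross-region model
#'
#' @param x a [fit_beta2_model()] object.
#' @param ... unused.
#' @return Tibble `covariate`, `correlation`, `cor_p`, `moran_I`, `moran_p`,
#'   `n_regions`.
#' @export
glance.beta2_model <- function(x, ...) {
  tibble::tibble(covariate = x$covariate, correlation = x$correlation,
                 cor_p = x$cor_p, moran_I = x$moran_I, moran_p = x$moran_p,
                 n_regions = nrow(x$data))
}
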