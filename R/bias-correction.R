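#' Fit linear-scaling bias-correction factors
#'
#' Per region, calendar month and variable: a multiplicative factor
#' `mean(obs)/mean(sim)` for lower-bounded variables (`pre`, `dtr`, and `pet`
#' when present) and an additive offset `mean(obs) - mean(sim)` for `tmean`,
#' with the long-term means taken over the reference window. The method
#' assumes the bias is stationary across climates: the same factors are
#' applied unchanged outside the reference window.
#'
#' @param sim simulated climate panel.
#' @param obs observed climate panel on the same regions.
#' @param reference_period `c(start_year, end_year)`, default `c(1971, 2000)`.
#' @param pooled fit one factor per region and variable pooled across
#'   calendar months instead of the default per-month fit.
#' @return Tibble of class `scaling_factors`: `region`, `month`, `variable`,
#'   `type` (`"ratio"` or `"offset"`), `value`.
#' @export
fit_scaling <- function(sim, obs, reference_period = c(1971, 2000),
                        pooled = FALSE) {
  check_window(reference_period, "reference_period")
  vars <- intersect(c("tmean", "dtr", "pre", "pet"), names(sim))
  vars <- intersect(vars, names(obs))
  check_columns(sim, c("region", "year", "month"), "sim")
  ref_means <- function(panel) {
    panel %>%
      dplyr::filter(.data$year >= reference_period[1],
                    .data$year <= reference_period[2]) %>%
      tidyr::pivot_longer(dplyr::all_of(vars), names_to = "variable") %>%
      dplyr::group_by(.data$region,
                      month = if (pooled) 0L else .data$month,
                      .data$variable) %>%
      dplyr::summarise(mean = mean(.data$value), .groups = "drop")
  }
  ms <- ref_means(sim)
  mo <- ref_means(obs)
  if (nrow(ms) == 0 || !setequal(unique(ms$region), unique(mo$region))) {
    stop_medfire("sim and obs must cover the reference period on the same regions",
                 "medfire_mismatch")
  }
  joined <- dplyr::inner_join(ms, mo, by = c("region", "month", "variable"),
                              suffix = c("_sim", "_obs"))
  ratio_vars <- setdiff(vars, "tmean")
  if (any(joined$variable %in% ratio_vars & joined$mean_sim <= 0)) {
    stop_medfire("simulated reference mean of a ratio variable is <= 0: scaling factor undefined",
                 "medfire_undefined_factor")
  }
  out <- joined %>%
    dplyr::mutate(
      type = ifelse(.data$variable == "tmean", "offset", "ratio"),
      value = ifelse(.data$type == "offset",
                     .data$mean_obs - .data$mean_sim,
                     .data$mean_obs / .data$mean_sim)) %>%
    dplyr::select("region", "month", "variable", "type", "value")
  attr(out, "reference_period") <- reference_period
  attr(out, "pooled") <- pooled
  class(out) <- c("scaling_factors", class(out))
  out
}

#' Apply linear-scaling factors to a climate panel
#'
#' Multiplies ratio-corrected variables and offsets `tmean`, for every year in
#' the panel (inside and outside the reference window alike). By construction
#' the corrected reference-window long-term means equal the observed ones to
#' floating tolerance; additive scaling preserves the future-minus-reference
#' temperature signal exactly, and ratio scaling preserves relative
#' precipitation changes exactly.
#'
#' @param sim simulated climate panel.
#' @param factors a [fit_scaling()] result covering all (region, month,
#'   variable) combinations of `sim`.
#' @return The corrected panel, same shape as `sim`.
#' @export
apply_scaling <- function(sim, factors) {
  check_columns(factors, c("region", "month", "variable", "type", "value"),
                "scaling factors")
  vars <- unique(factors$variable)
  vars <- intersect(vars, names(sim))
  pooled <- isTRUE(attr(factors, "pooled"))
  wide <- factors %>%
    dplyr::select("region", "month", "variable", "value") %>%
    tidyr::pivot_wider(names_from = "variable", values_from = "value",
                       names_prefix = "sf_")
  by <- if (pooled) "region" else c("region", "month")
  if (pooled) wide$month <- NULL
  out <- dplyr::left_join(sim, wide, by = by)
  for (v in vars) {
    sf <- out[[paste0("sf_", v)]]
    if (anyNA(sf)) {
      stop_medfire(sprintf("missing scaling factor for variable %s", v),
                   "medfire_mismatch")
    }
    out[[v]] <- if (v == "tmean") out[[v]] + sf else out[[v]] * sf
  }
  out <- dplyr::select(out, -dplyr::starts_with("sf_"))
  attr(out, "config") <- attr(sim, "config")
  out
}
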