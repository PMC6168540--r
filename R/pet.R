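#' Monthly-mean extraterrestrial radiation (FAO-56)
#'
#' Computes the top-of-atmosphere solar radiation for the mid-point day of a
#' calendar month from solar declination and the inverse relative Earth-Sun
#' distance, following the FAO-56 daily formulation evaluated at mid-month.
#'
#' @param lat latitude in decimal degrees; must satisfy `abs(lat) < 66.5`
#'   (no polar day/night handling).
#' @param month calendar month, 1-12. `lat` and `month` are recycled to a
#'   common length.
#' @return Extraterrestrial radiation in MJ m^-2 day^-1.
#' @examples
#' extraterrestrial_radiation(40, 6) > extraterrestrial_radiation(40, 12)
#' @export
extraterrestrial_radiation <- function(lat, month) {
  n <- max(length(lat), length(month))
  lat <- rep_len(lat, n)
  month <- rep_len(as.integer(month), n)
  if (any(month < 1 | month > 12)) {
    stop_medfire("month must be in 1..12", "medfire_invalid_argument")
  }
  if (any(abs(lat) >= 66.5)) {
    stop_medfire("polar latitudes (|lat| >= 66.5) are not supported",
                 "medfire_unsupported_domain")
  }
  mid_doy <- cumsum(DAYS_IN_MONTH) - DAYS_IN_MONTH / 2
  j <- mid_doy[month]
  phi <- lat * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * j / 365)
  delta <- 0.409 * sin(2 * pi * j / 365 - 1.39)
  ws <- acos(pmin(pmax(-tan(phi) * tan(delta), -1), 1))
  gsc <- 0.0820 # MJ m^-2 min^-1
  (24 * 60 / pi) * gsc * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
}

#' Hargreaves potential evapotranspiration
#'
#' Monthly PET from mean temperature, diurnal temperature range, latitude and
#' (for the default variant) monthly precipitation. The `"modified"` variant is
#' the Droogers-Allen precipitation-aware monthly form,
#' `0.0013 * 0.408 * Ra * (tmean + 17) * max(dtr - 0.0123 * pre, 0)^0.76`
#' (mm/day, scaled by days in month); `"classic"` is the standard Hargreaves
#' equation `0.0023 * 0.408 * Ra * (tmean + 17.8) * sqrt(dtr)`. Both are
#' floored at zero.
#'
#' @param tmean monthly mean temperature, degrees C.
#' @param dtr diurnal temperature range, degrees C, non-negative.
#' @param lat latitude, decimal degrees.
#' @param month calendar month 1-12.
#' @param pre monthly precipitation, mm; required by the modified variant.
#' @param variant `"modified"` (default) or `"classic"`.
#' @return PET in mm/month.
#' @export
hargreaves_pet <- function(tmean, dtr, lat, month, pre = NULL,
                           variant = c("modified", "classic")) {
  variant <- match.arg(variant)
  n <- max(length(tmean), length(dtr), length(lat), length(month))
  tmean <- rep_len(tmean, n); dtr <- rep_len(dtr, n)
  lat <- rep_len(lat, n); month <- rep_len(as.integer(month), n)
  if (any(dtr < 0, na.rm = TRUE)) {
    stop_medfire("dtr must be non-negative", "medfire_invalid_argument")
  }
  ra <- extraterrestrial_radiation(lat, month)
  if (variant == "modified") {
    if (is.null(pre)) {
      stop_medfire("modified Hargreaves requires pre", "medfire_invalid_argument")
    }
    pre <- rep_len(pre, n)
    if (any(pre < 0, na.rm = TRUE)) {
      stop_medfire("pre must be non-negative", "medfire_invalid_argument")
    }
    td <- pmax(dtr - 0.0123 * pre, 0)
    et0 <- 0.0013 * 0.408 * ra * (tmean + 17) * td^0.76
  } else {
    et0 <- 0.0023 * 0.408 * ra * (tmean + 17.8) * sqrt(dtr)
  }
  pmax(et0, 0) * DAYS_IN_MONTH[month]
}

#' Add a PET column to a climate panel
#'
#' @param climate climate panel tibble with columns `region`, `lat`, `year`,
#'   `month`, `tmean`, `dtr`, `pre`.
#' @param variant PET variant, see [hargreaves_pet()].
#' @return The input tibble with a `pet` column (mm/month).
#' @export
compute_pet <- function(climate, variant = c("modified", "classic")) {
  variant <- match.arg(variant)
  check_columns(climate, c("region", "lat", "year", "month", "tmean", "dtr", "pre"),
                "climate panel")
  dplyr::mutate(climate,
    pet = hargreaves_pet(.data$tmean, .data$dtr, .data$lat, .data$month,
                         pre = .data$pre, variant = variant))
}
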