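#' Accumulate the climatic water balance over a time scale
#'
#' Builds the SPEI input series `D(t) = sum_{k=0..sc-1} (pre - pet)` over the
#' `sc` months ending at each anchor month, per region. Years whose window is
#' incomplete (the first `sc - 1` months of the series) are dropped.
#'
#' @param climate climate panel with a `pet` column (see [compute_pet()]), or
#'   any tibble with `region`, `year`, `month`, `pre`, `pet`.
#' @param sc accumulation scale in months, one of 3, 6, 12.
#' @param months anchor months to keep (default all 12).
#' @return Tibble with columns `region`, `year`, `month`, `d` (mm).
#' @export
accumulate_balance <- function(climate, sc, months = 1:12) {
  if (!sc %in% c(3L, 6L, 12L)) {
    stop_medfire("sc must be one of 3, 6, 12", "medfire_invalid_argument")
  }
  check_columns(climate, c("region", "year", "month", "pre", "pet"),
                "water-balance input")
  climate <- dplyr::arrange(climate, .data$region, .data$year, .data$month)
  counts <- table(climate$region)
  if (any(counts < sc)) {
    stop_medfire("series shorter than the accumulation scale",
                 "medfire_insufficient_data")
  }
  if (length(unique(counts)) == 1) {
    # regular panel: one rolling-sum pass over a months-by-regions matrix
    nt <- counts[[1]]
    wb <- matrix(climate$pre - climate$pet, nrow = nt)
    d <- stats::filter(wb, rep(1, sc), sides = 1)
    out <- tibble::tibble(region = climate$region,
                          year = climate$year, month = climate$month,
                          d = as.numeric(d))
  } else {
    out <- climate %>%
      dplyr::group_by(.data$region) %>%
      dplyr::mutate(d = as.numeric(stats::filter(.data$pre - .data$pet,
                                                 rep(1, sc), sides = 1))) %>%
      dplyr::ungroup() %>%
      dplyr::select("region", "year", "month", "d")
  }
  dplyr::filter(out, !is.na(.data$d), .data$month %in% months)
}

# Unbiased probability-weighted moments b0, b1, b2 of a sample.
pwm_unbiased <- function(x) {
  x <- sort(x)
  n <- length(x)
  j <- seq_len(n)
  b0 <- mean(x)
  b1 <- sum(x * (j - 1)) / (n * (n - 1))
  b2 <- sum(x * (j - 1) * (j - 2)) / (n * (n - 1) * (n - 2))
  c(b0 = b0, b1 = b1, b2 = b2)
}

# Generalized-logistic (three-parameter log-logistic family) fit from
# unbiased PWMs / L-moments, Hosking's parametrization:
#   kappa = -tau3, alpha = lambda2 * sin(kappa*pi) / (kappa*pi),
#   xi = lambda1 - alpha * (1/kappa - pi/sin(kappa*pi)).
# For kappa < 0 this is the lower-bounded log-logistic with exponent
# -1/kappa; kappa > 0 gives the upper-bounded mirror (negative L-skew),
# kappa = 0 the logistic.
loglogistic_pwm <- function(x) {
  if (length(unique(x)) < 4 || sd(x) < 1e-10) {
    stop_medfire("degenerate water-balance sample: cannot fit a distribution",
                 "medfire_degenerate_distribution")
  }
  b <- pwm_unbiased(x)
  l1 <- b[["b0"]]
  l2 <- 2 * b[["b1"]] - b[["b0"]]
  l3 <- 6 * b[["b2"]] - 6 * b[["b1"]] + b[["b0"]]
  if (!is.finite(l2) || l2 <= 0 || abs(l3 / l2) >= 1) {
    stop_medfire("degenerate L-moments: cannot fit a distribution",
                 "medfire_degenerate_distribution")
  }
  kappa <- -l3 / l2
  if (abs(kappa) < 1e-8) {
    alpha <- l2
    xi <- l1
  } else {
    alpha <- l2 * sin(kappa * pi) / (kappa * pi)
    xi <- l1 - alpha * (1 / kappa - pi / sin(kappa * pi))
  }
  if (!is.finite(alpha) || alpha <= 0) {
    stop_medfire("log-logistic PWM fit failed (scale out of range)",
                 "medfire_degenerate_distribution")
  }
  c(shape = unname(kappa), scale = unname(alpha), location = unname(xi))
}

# CDF of the generalized logistic; monotone increasing in x, support
# bounded below (shape < 0) or above (shape > 0) at location + scale/shape.
ploglogistic <- function(x, shape, scale, location) {
  z <- (x - location) / scale
  y <- ifelse(abs(shape) < 1e-8, z,
              -log(pmax(1 - shape * z, 0)) / shape)
  1 / (1 + exp(-y))
}

qloglogistic <- function(p, shape, scale, location) {
  if (abs(shape) < 1e-8) return(location + scale * log(p / (1 - p)))
  location + scale * (1 - ((1 - p) / p)^shape) / shape
}

#' Fit SPEI standardization parameters on a reference period
#'
#' Fits the three-parameter log-logistic family (generalized-logistic
#' parametrization, which also covers samples with negative L-skewness) by
#' unbiased probability-weighted moments to the accumulated water balance of
#' the declared reference window, separately for every (region, calendar
#' month) series. The same parameters are later applied to any period (that
#' is how future SPEI is produced).
#'
#' @param d accumulated-balance tibble from [accumulate_balance()].
#' @param reference_period `c(start_year, end_year)` of the reference window.
#' @param min_n minimum reference sample size per series (default 20).
#' @return Tibble of class `spei_params` with columns `region`, `month`,
#'   `shape`, `scale`, `location`; the reference window is stored as an
#'   attribute.
#' @export
fit_spei_params <- function(d, reference_period, min_n = 20) {
  check_columns(d, c("region", "year", "month", "d"), "accumulated balance")
  check_window(reference_period, "reference_period")
  ref <- dplyr::filter(d, .data$year >= reference_period[1],
                       .data$year <= reference_period[2])
  counts <- dplyr::count(ref, .data$region, .data$month)
  if (nrow(counts) == 0 || any(counts$n < min_n)) {
    stop_medfire(sprintf(
      "fewer than %d reference values for at least one (region, month) series",
      min_n), "medfire_insufficient_data")
  }
  key <- paste(ref$region, ref$month, sep = "\r")
  splits <- split(ref$d, key)
  est <- t(vapply(splits, loglogistic_pwm, numeric(3)))
  parts <- strsplit(names(splits), "\r", fixed = TRUE)
  params <- tibble::tibble(
    region = vapply(parts, `[`, character(1), 1),
    month = as.integer(vapply(parts, `[`, character(1), 2)),
    shape = est[, "shape"], scale = est[, "scale"], location = est[, "location"]) %>%
    dplyr::arrange(.data$region, .data$month)
  attr(params, "reference_period") <- reference_period
  class(params) <- c("spei_params", class(params))
  params
}

#' Standardize accumulated water balance into SPEI
#'
#' `SPEI = qnorm(F_loglogistic(D))` with the reference-fitted parameters.
#' Values outside the fitted support, or beyond `cap` standard deviations,
#' are clamped to `+/- cap` and flagged in the `clamped` column (future
#' projections can exceed the fitted support).
#'
#' @param d accumulated-balance tibble (`region`, `year`, `month`, `d`).
#' @param params `spei_params` object from [fit_spei_params()].
#' @param cap extreme-value cap for the standardized index (default 3).
#' @return Tibble `region`, `year`, `month`, `spei`, `clamped`.
#' @export
compute_spei <- function(d, params, cap = 3) {
  check_columns(d, c("region", "year", "month", "d"), "accumulated balance")
  check_columns(params, c("region", "month", "shape", "scale", "location"),
                "SPEI parameters")
  joined <- dplyr::inner_join(d, params, by = c("region", "month"))
  if (nrow(joined) < nrow(d)) {
    stop_medfire("SPEI parameters do not cover every (region, month) in d",
                 "medfire_mismatch")
  }
  p <- ploglogistic(joined$d, joined$shape, joined$scale, joined$location)
  spei <- qnorm(p)
  clamped <- !is.finite(spei) | abs(spei) > cap
  spei <- pmin(pmax(spei, -cap), cap)
  joined %>%
    dplyr::transmute(.data$region, .data$year, .data$month,
                     spei = spei, clamped = clamped)
}

#' One-shot SPEI panel for a (scale, month) specification
#'
#' Convenience wrapper: PET, water-balance accumulation, reference-period
#' log-logistic fit, and standardization for a single anchor month, yielding
#' one SPEI value per region and year.
#'
#' @param climate climate panel (`region`, `lat`, `year`, `month`, `tmean`,
#'   `dtr`, `pre`); a `pet` column is reused when present.
#' @param sc accumulation scale (3, 6 or 12).
#' @param m anchor calendar month.
#' @param reference_period standardization window, default `c(1971, 2000)`.
#' @param variant PET variant, see [hargreaves_pet()].
#' @param cap extreme-value cap, see [compute_spei()].
#' @return Tibble `region`, `year`, `spei`, `clamped` with attributes `sc`,
#'   `m` and `params`.
#' @export
spei_panel <- function(climate, sc, m, reference_period = c(1971, 2000),
                       variant = "modified", cap = 3) {
  if (!"pet" %in% names(climate)) climate <- compute_pet(climate, variant)
  d <- accumulate_balance(climate, sc, months = m)
  params <- fit_spei_params(d, reference_period)
  out <- compute_spei(d, params, cap = cap) %>%
    dplyr::select("region", "year", "spei", "clamped")
  attr(out, "sc") <- sc
  attr(out, "m") <- m
  attr(out, "params") <- params
  out
}
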