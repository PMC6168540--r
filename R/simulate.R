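#' Configuration for the synthetic climate generator
#'
#' Defaults emulate a Mediterranean eco-region panel: a wet-winter/dry-summer
#' precipitation cycle, a summer-peaking temperature cycle, and a cross-region
#' gradient in long-term mean annual temperature (warm south to cool north).
#' Precipitation is gamma-distributed per calendar month (non-negative,
#' realistically skewed); the diurnal range is a positive seasonal cycle plus
#' noise.
#'
#' @param t_base long-term mean annual temperature of the first (warmest)
#'   region, degrees C.
#' @param t_gradient change of that mean per region index, degrees C/region
#'   (negative: later regions are cooler/more northern).
#' @param t_seas_amp amplitude of the temperature seasonal cycle, degrees C.
#' @param tmean_sd interannual monthly temperature noise sd, degrees C.
#' @param dtr_base,dtr_seas_amp,dtr_sd diurnal-range cycle (degrees C).
#' @param pre_base,pre_seas_amp monthly precipitation cycle (mm/month; the
#'   cycle peaks in January, its minimum is in July).
#' @param pre_cv coefficient of variation of monthly precipitation (gamma
#'   shape `1/pre_cv^2`); 0 gives deterministic precipitation.
#' @param warming_trend linear warming imposed on `tmean`, degrees C/decade.
#' @param drying_trend linear multiplicative trend on mean precipitation,
#'   fraction/decade (e.g. -0.02 dries by 2 % per decade).
#' @param lat_range,lon_range region centroid coordinate spans (degrees);
#'   regions are laid out south-to-north.
#' @param weights spatial averaging weights per region (default equal).
#' @return A list of class `climate_config`.
#' @export
climate_config <- function(t_base = 17, t_gradient = -0.3, t_seas_amp = 8,
                           tmean_sd = 1.2,
                           dtr_base = 9, dtr_seas_amp = 3, dtr_sd = 0.4,
                           pre_base = 60, pre_seas_amp = 35, pre_cv = 0.55,
                           warming_trend = 0, drying_trend = 0,
                           lat_range = c(36, 46), lon_range = c(-8, 25),
                           weights = NULL) {
  structure(as.list(environment()), class = "climate_config")
}

#' Generate a synthetic monthly climate panel
#'
#' Produces a gapless monthly panel of mean temperature, diurnal temperature
#' range and precipitation for `n_regions` eco-regions sharing one time axis,
#' with the configured seasonal cycles, cross-region temperature gradient and
#' optional warming/drying trends. Fully reproducible from `seed`.
#'
#' @param n_regions number of eco-regions (>= 2).
#' @param start_year,end_year panel span; must leave room for a 30-year
#'   reference period (`end_year > start_year + 35`).
#' @param seed integer seed or `NULL`.
#' @param config a [climate_config()].
#' @return Tibble `region`, `lat`, `lon`, `year`, `month`, `tmean`, `dtr`,
#'   `pre`, with the generator config stored as attribute `config`.
#' @export
simulate_climate <- function(n_regions = 40, start_year = 1950,
                             end_year = 2099, seed = NULL,
                             config = climate_config()) {
  if (n_regions < 2) {
    stop_medfire("n_regions must be >= 2", "medfire_invalid_argument")
  }
  if (end_year <= start_year + 35) {
    stop_medfire("end_year must exceed start_year + 35 (room for a 30-yr reference period)",
                 "medfire_invalid_argument")
  }
  cfg <- config
  regions <- sprintf("R%02d", seq_len(n_regions))
  lat <- seq(cfg$lat_range[1], cfg$lat_range[2], length.out = n_regions)
  lon <- seq(cfg$lon_range[1], cfg$lon_range[2], length.out = n_regions)
  years <- start_year:end_year
  grid <- tidyr::expand_grid(
    ridx = seq_len(n_regions), year = years, month = 1:12)
  n <- nrow(grid)
  with_seed_if(seed, {
    dec <- (grid$year - start_year) / 10
    t_clim <- cfg$t_base + cfg$t_gradient * (grid$ridx - 1) +
      cfg$t_seas_amp * cos(2 * pi * (grid$month - 7) / 12) +
      cfg$warming_trend * dec
    tmean <- t_clim + (if (cfg$tmean_sd > 0) rnorm(n, 0, cfg$tmean_sd) else 0)
    dtr <- pmax(cfg$dtr_base + cfg$dtr_seas_amp * cos(2 * pi * (grid$month - 7) / 12) +
                  (if (cfg$dtr_sd > 0) rnorm(n, 0, cfg$dtr_sd) else 0), 0)
    pre_mu <- pmax((cfg$pre_base + cfg$pre_seas_amp * cos(2 * pi * (grid$month - 1) / 12)) *
                     pmax(1 + cfg$drying_trend * dec, 0.01), 0.1)
    pre <- if (cfg$pre_cv > 0) {
      shape <- 1 / cfg$pre_cv^2
      rgamma(n, shape = shape, scale = pre_mu / shape)
    } else pre_mu
    out <- tibble::tibble(
      region = regions[grid$ridx],
      lat = lat[grid$ridx],
      lon = lon[grid$ridx],
      year = grid$year,
      month = grid$month,
      tmean = tmean, dtr = dtr, pre = pre)
    attr(out, "config") <- cfg
    out
  })
}

#' Plant a synthetic ground truth for the drought-fire model
#'
#' Builds per-region regression coefficients for the generative log-linear
#' burned-area model `log BA = beta1 + beta2 * SPEI + beta3 * T + eps`.
#' Drought sensitivity is planted through the cross-region relation
#' `beta2 = gamma1 + gamma2 * Ty + scatter`, where `Ty` is each region's
#' long-term mean annual temperature over `normal_window`, so the spatial
#' model can be asked to recover `(gamma1, gamma2)`.
#'
#' @param climate climate panel from [simulate_climate()].
#' @param sc,m SPEI specification of the true predictor.
#' @param gamma1,gamma2 coefficients of the planted beta2-Ty relation
#'   (defaults: intercept -1.62, slope 0.057 per degree C).
#' @param beta2_sd spatial scatter around the planted relation.
#' @param beta1_mean,beta1_sd intercept distribution (log-area units).
#' @param beta3 linear trend coefficient per year (0 disables the trend).
#' @param noise_sd sd of the lognormal noise eps.
#' @param normal_window window for the Ty normals.
#' @param seed integer seed or `NULL`.
#' @return List of class `synthetic_truth` with elements `coefs` (tibble
#'   `region`, `ty`, `beta1`, `beta2`, `beta3`), `sc`, `m`, `noise_sd`,
#'   `gamma`, `normal_window`.
#' @export
simulate_truth <- function(climate, sc = 3, m = 8,
                           gamma1 = -1.62, gamma2 = 0.057, beta2_sd = 0.1,
                           beta1_mean = 6, beta1_sd = 0.3, beta3 = 0,
                           noise_sd = 0.3, normal_window = c(1971, 2000),
                           seed = NULL) {
  if (noise_sd < 0) {
    stop_medfire("noise_sd must be >= 0", "medfire_invalid_argument")
  }
  ty <- climate %>%
    dplyr::filter(.data$year >= normal_window[1],
                  .data$year <= normal_window[2]) %>%
    dplyr::group_by(.data$region) %>%
    dplyr::summarise(ty = mean(.data$tmean), .groups = "drop")
  coefs <- with_seed_if(seed, {
    ty %>% dplyr::mutate(
      beta1 = beta1_mean + (if (beta1_sd > 0) rnorm(dplyr::n(), 0, beta1_sd) else 0),
      beta2 = gamma1 + gamma2 * .data$ty +
        (if (beta2_sd > 0) rnorm(dplyr::n(), 0, beta2_sd) else 0),
      beta3 = beta3)
  })
  if (any(coefs$beta2 >= 0)) {
    warn("some planted beta2 are non-negative; those regions are not fire-prone")
  }
  structure(
    list(coefs = coefs, sc = sc, m = m, noise_sd = noise_sd,
         gamma = c(gamma1 = gamma1, gamma2 = gamma2),
         normal_window = normal_window),
    class = "synthetic_truth")
}

#' Generate burned area from a climate panel and a planted truth
#'
#' Computes the SPEI of the truth's `(sc, m)` specification from the panel and
#' inverts the log-linear model: `BA = exp(beta1 + beta2*SPEI + beta3*T + eps)`
#' with `eps ~ N(0, noise_sd)`. Output is strictly positive. The trend
#' covariate `T` is the year centred on the panel midpoint.
#'
#' @param climate climate panel covering the truth's regions.
#' @param truth a [simulate_truth()] object.
#' @param reference_period SPEI standardization window.
#' @param seed integer seed or `NULL`.
#' @param variant PET variant.
#' @return Tibble `region`, `year`, `ba` (hectares) with attribute `spei`
#'   (the SPEI panel used).
#' @export
simulate_burned_area <- function(climate, truth,
                                 reference_period = c(1971, 2000),
                                 seed = NULL, variant = "modified") {
  if (!inherits(truth, "synthetic_truth")) {
    stop_medfire("truth must come from simulate_truth()", "medfire_invalid_argument")
  }
  if (!setequal(unique(climate$region), truth$coefs$region)) {
    stop_medfire("truth regions do not match the climate panel",
                 "medfire_mismatch")
  }
  spei <- spei_panel(climate, truth$sc, truth$m,
                     reference_period = reference_period, variant = variant)
  year_mid <- floor(median(unique(spei$year)))
  out <- spei %>%
    dplyr::inner_join(truth$coefs, by = "region") %>%
    dplyr::arrange(.data$region, .data$year)
  eps <- with_seed_if(seed, {
    if (truth$noise_sd > 0) rnorm(nrow(out), 0, truth$noise_sd) else rep(0, nrow(out))
  })
  ba <- out %>%
    dplyr::transmute(.data$region, .data$year,
                     ba = exp(.data$beta1 + .data$beta2 * .data$spei +
                                .data$beta3 * (.data$year - year_mid) + eps))
  attr(ba, "spei") <- spei
  attr(ba, "year_center") <- year_mid
  ba
}

#' Global-mean temperature trajectory of a driving simulation
#'
#' Piecewise-linear anomaly: flat at zero until `ramp_start`, then warming at
#' `rate` degrees C/yr, optionally flattening at `plateau_year` (a moderate
#' mitigation scenario). Covers at least 1881-2099 so the warming-window
#' search has its pre-industrial baseline.
#'
#' @param rate warming rate, degrees C/yr.
#' @param start_year,end_year series span (defaults 1881-2099).
#' @param ramp_start year warming begins.
#' @param plateau_year year warming stops (NULL = never).
#' @param noise_sd interannual noise sd, degrees C.
#' @param base absolute pre-industrial global-mean temperature, degrees C.
#' @param seed integer seed or `NULL`.
#' @return Tibble `year`, `tglob`.
#' @export
simulate_global_temp <- function(rate, start_year = 1881, end_year = 2099,
                                 ramp_start = 1960, plateau_year = NULL,
                                 noise_sd = 0, base = 13.8, seed = NULL) {
  years <- start_year:end_year
  eff <- if (is.null(plateau_year)) years else pmin(years, plateau_year)
  anom <- rate * pmax(eff - ramp_start, 0)
  tglob <- with_seed_if(seed, {
    base + anom + (if (noise_sd > 0) rnorm(length(years), 0, noise_sd) else 0)
  })
  tibble::tibble(year = years, tglob = tglob)
}

#' Configuration for the pseudo-RCM ensemble generator
#'
#' Each member carries an additive temperature bias, a multiplicative
#' precipitation bias, and a prescribed global warming trajectory; the
#' regional response scales the global anomaly by `amplification` for
#' temperature and by `pre_sens` (fractional precipitation change per degree C
#' of global warming) for precipitation, the drying pathway of Mediterranean
#' projections.
#'
#' @param n_members members per scenario.
#' @param scenarios character vector; `"moderate"` members plateau
#'   mid-century (RCP4.5-like), `"high"` members warm throughout
#'   (RCP8.5-like).
#' @param tmean_bias,pre_bias explicit per-member bias vectors (recycled
#'   across scenarios), or `NULL` to draw them (`N(0, tmean_bias_sd)` and
#'   log-uniform in `pre_bias_range`).
#' @param tmean_bias_sd,pre_bias_range bias-drawing parameters.
#' @param amplification regional warming per degree of global warming.
#' @param pre_sens fractional precipitation change per degree of global
#'   warming (negative = drying).
#' @param rate_moderate,rate_high global warming-rate ranges (degrees C/yr)
#'   from which member rates are drawn uniformly.
#' @param plateau_moderate plateau year of the moderate scenario.
#' @param traj_noise_sd interannual noise of the global series.
#' @return List of class `rcm_config`.
#' @export
rcm_config <- function(n_members = 9, scenarios = c("moderate", "high"),
                       tmean_bias = NULL, pre_bias = NULL,
                       tmean_bias_sd = 1.5, pre_bias_range = c(0.8, 1.25),
                       amplification = 1.2, pre_sens = -0.04,
                       rate_moderate = c(0.02, 0.026), rate_high = c(0.028, 0.04),
                       plateau_moderate = 2070, traj_noise_sd = 0.08) {
  structure(as.list(environment()), class = "rcm_config")
}

#' Generate a pseudo-RCM ensemble from an observed panel
#'
#' Members inherit the observed panel's realised monthly values over the
#' overlapping years and extend them with newly generated variability from
#' the same climate configuration; on top of that, each member gets its
#' additive `tmean` bias, multiplicative `pre` bias, and the regional imprint
#' of its global warming trajectory. With all biases zero and a flat
#' trajectory, a member's reference-period means therefore equal the observed
#' ones exactly.
#'
#' @param obs observed climate panel from [simulate_climate()].
#' @param config an [rcm_config()].
#' @param start_year,end_year member panel span (default 1970-2099, the usual span of regional climate-model archives).
#' @param seed integer seed or `NULL`.
#' @return Tibble of class `rcm_ensemble`, one row per member, with columns
#'   `member`, `scenario`, `rate`, `tmean_bias`, `pre_bias` and list-columns
#'   `climate` (monthly panel) and `gts` (global-mean temperature series).
#' @export
simulate_rcm_ensemble <- function(obs, config = rcm_config(),
                                  start_year = 1970, end_year = 2099,
                                  seed = NULL) {
  if (config$n_members < 1) {
    stop_medfire("n_members must be >= 1", "medfire_invalid_argument")
  }
  cfg_obs <- attr(obs, "config")
  if (is.null(cfg_obs)) {
    stop_medfire("obs must carry its generator config (use simulate_climate())",
                 "medfire_invalid_argument")
  }
  nm <- config$n_members
  with_seed_if(seed, {
    tb <- if (is.null(config$tmean_bias)) rnorm(nm, 0, config$tmean_bias_sd) else
      rep_len(config$tmean_bias, nm)
    pb <- if (is.null(config$pre_bias)) {
      exp(runif(nm, log(config$pre_bias_range[1]), log(config$pre_bias_range[2])))
    } else rep_len(config$pre_bias, nm)
    members <- tidyr::expand_grid(scenario = config$scenarios,
                                  member = seq_len(nm))
    members$rate <- ifelse(
      members$scenario == "moderate",
      runif(nrow(members), config$rate_moderate[1], config$rate_moderate[2]),
      runif(nrow(members), config$rate_high[1], config$rate_high[2]))
    members$tmean_bias <- tb[members$member]
    members$pre_bias <- pb[members$member]

    obs_years <- range(obs$year)
    regions <- unique(obs$region)
    out <- purrr::pmap(members, function(scenario, member, rate, tmean_bias, pre_bias) {
      plateau <- if (scenario == "moderate") config$plateau_moderate else NULL
      gts <- simulate_global_temp(rate, plateau_year = plateau,
                                  noise_sd = config$traj_noise_sd)
      # baseline-anchored anomaly driving the regional response
      anom <- gts$tglob - mean(gts$tglob[gts$year >= 1881 & gts$year <= 1910])
      anom_by_year <- setNames(anom, gts$year)
      base <- dplyr::filter(obs, .data$year >= start_year, .data$year <= end_year)
      extra_years <- setdiff(start_year:end_year, obs_years[1]:obs_years[2])
      if (length(extra_years) > 0) {
        ext <- simulate_climate(length(regions), min(extra_years) - 40,
                                max(extra_years), seed = NULL, config = cfg_obs)
        ext <- dplyr::filter(ext, .data$year %in% extra_years)
        base <- dplyr::bind_rows(base, ext) %>%
          dplyr::arrange(.data$region, .data$year, .data$month)
      }
      a <- anom_by_year[as.character(base$year)]
      clim <- base %>% dplyr::mutate(
        tmean = .data$tmean + config$amplification * a + tmean_bias,
        pre = pmax(.data$pre * pmax(1 + config$pre_sens * a, 0.02) * pre_bias, 0))
      attr(clim, "config") <- cfg_obs
      list(climate = clim, gts = gts)
    })
    members$climate <- purrr::map(out, "climate")
    members$gts <- purrr::map(out, "gts")
    members$member <- sprintf("%s_%02d", members$scenario, members$member)
    class(members) <- c("rcm_ensemble", class(members))
    members
  })
}
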