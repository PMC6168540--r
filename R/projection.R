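#' Find the earliest warming-level window
#'
#' Earliest 30-year period whose time-averaged global-mean temperature
#' anomaly, relative to the pre-industrial baseline mean, reaches the given
#' warming level. A level that is never reached is signalled with
#' `reached = FALSE`, not an error (moderate scenarios need not reach 3
#' degrees).
#'
#' @param gts tibble `year`, `tglob` covering the baseline and candidate
#'   windows.
#' @param level warming level, degrees C (e.g. 1.5, 2, 3).
#' @param baseline pre-industrial baseline window, default `c(1881, 1910)`.
#' @param width window width in years (30).
#' @return One-row tibble `level`, `start_year`, `end_year`, `reached`.
#' @export
find_warming_window <- function(gts, level, baseline = c(1881, 1910),
                                width = 30) {
  check_columns(gts, c("year", "tglob"), "global temperature series")
  check_window(baseline, "baseline")
  gts <- dplyr::arrange(gts, .data$year)
  if (any(diff(gts$year) != 1)) {
    stop_medfire("global temperature series must be gapless",
                 "medfire_invalid_argument")
  }
  base_vals <- gts$tglob[gts$year >= baseline[1] & gts$year <= baseline[2]]
  if (length(base_vals) != baseline[2] - baseline[1] + 1) {
    stop_medfire("series does not cover the baseline window",
                 "medfire_invalid_argument")
  }
  anom <- gts$tglob - mean(base_vals)
  roll <- as.numeric(stats::filter(anom, rep(1 / width, width), sides = 1))
  starts <- gts$year - width + 1
  ok <- which(!is.na(roll) & roll >= level)
  if (length(ok) == 0) {
    return(tibble::tibble(level = level, start_year = NA_integer_,
                          end_year = NA_integer_, reached = FALSE))
  }
  s <- starts[ok[1]]
  tibble::tibble(level = level, start_year = as.integer(s),
                 end_year = as.integer(s + width - 1), reached = TRUE)
}

# shared change formula: 100 * (mean BA_future - mean BA_ref) / mean BA_ref
# with BA predicted as exp(b1 + b2 * spei); the stochastic term is excluded
# (its retransformation factor cancels in the ratio).
percent_change <- function(beta1, beta2_ref, beta2_fut, spei_ref, spei_fut) {
  ref <- mean(exp(beta1 + beta2_ref * spei_ref))
  fut <- mean(exp(beta1 + beta2_fut * spei_fut))
  100 * (fut - ref) / ref
}

#' Stationary-model burned-area change
#'
#' Percent change of mean predicted burned area between a reference and a
#' future SPEI series under the stationary model: the calibrated `beta2` is
#' used in both windows and the trend term is deliberately dropped.
#'
#' @param fits tibble with `region`, `beta1`, `beta2` (e.g. a
#'   [calibrate_fire_models()] result restricted to modelled regions).
#' @param spei_future,spei_reference tibbles `region`, `year`, `spei` from
#'   the same member/pipeline.
#' @return Tibble `region`, `change` (percent).
#' @export
project_sm <- function(fits, spei_future, spei_reference) {
  check_columns(fits, c("region", "beta1", "beta2"), "fits")
  fits <- dplyr::filter(fits, !is.na(.data$beta2))
  if (nrow(spei_future) == 0 || nrow(spei_reference) == 0) {
    stop_medfire("empty SPEI window", "medfire_invalid_argument")
  }
  sf <- split(spei_future$spei, spei_future$region)
  sr <- split(spei_reference$spei, spei_reference$region)
  purrr::pmap_dfr(fits[, c("region", "beta1", "beta2")],
    function(region, beta1, beta2) {
      tibble::tibble(region = region,
                     change = percent_change(beta1, beta2, beta2,
                                             sr[[region]], sf[[region]]))
    })
}

#' Non-stationary-model burned-area change
#'
#' As [project_sm()], but the drought sensitivity responds to the changing
#' climate normal through the cross-region relation: the future-window
#' `beta2` is `gamma1 + gamma2 * X_future`. In the default `"future_only"`
#' mode the reference window keeps the region's calibrated `beta2`; in
#' `"both_sides"` mode the relation is evaluated in both windows (requires
#' `x_reference`).
#'
#' @param fits tibble with `region`, `beta1`, `beta2`.
#' @param beta2_model a [fit_beta2_model()] object (or a list with `gamma1`,
#'   `gamma2`, `covariate`).
#' @param x_future normals tibble holding the model's covariate for the
#'   future window (or tibble `region`, `x`).
#' @param spei_future,spei_reference SPEI windows as in [project_sm()].
#' @param x_reference reference-window normals, required for `"both_sides"`.
#' @param mode `"future_only"` (default) or `"both_sides"`.
#' @return Tibble `region`, `change`, `beta2_future`.
#' @export
project_nsm <- function(fits, beta2_model, x_future, spei_future,
                        spei_reference, x_reference = NULL,
                        mode = c("future_only", "both_sides")) {
  mode <- match.arg(mode)
  check_columns(fits, c("region", "beta1", "beta2"), "fits")
  fits <- dplyr::filter(fits, !is.na(.data$beta2))
  grab_x <- function(tbl, what) {
    cols <- names(tbl)
    col <- if (beta2_model$covariate %in% cols) beta2_model$covariate
      else if ("x" %in% cols) "x"
      else stop_medfire(
        sprintf("%s does not carry the model covariate '%s'",
                what, beta2_model$covariate), "medfire_invalid_argument")
    setNames(tbl[[col]], tbl$region)
  }
  xf <- grab_x(x_future, "x_future")
  b2f <- beta2_model$gamma1 + beta2_model$gamma2 * xf
  if (mode == "both_sides") {
    if (is.null(x_reference)) {
      stop_medfire("both_sides mode requires x_reference",
                   "medfire_invalid_argument")
    }
    xr <- grab_x(x_reference, "x_reference")
    b2r <- beta2_model$gamma1 + beta2_model$gamma2 * xr
  }
  sf <- split(spei_future$spei, spei_future$region)
  sr <- split(spei_reference$spei, spei_reference$region)
  purrr::pmap_dfr(fits[, c("region", "beta1", "beta2")],
    function(region, beta1, beta2) {
      beta2_ref <- if (mode == "both_sides") b2r[[region]] else beta2
      tibble::tibble(
        region = region,
        change = percent_change(beta1, beta2_ref, b2f[[region]],
                                sr[[region]], sf[[region]]),
        beta2_future = b2f[[region]])
    })
}

#' Apply an extrapolation policy to projection inputs
#'
#' `"extrapolate"` passes inputs through; `"exclude"` drops regions whose
#' future covariate normal exceeds the historical range the cross-region
#' relation was calibrated on; `"constrain"` clips the future covariate and
#' the future SPEI to their historical extremes.
#'
#' @param x_future tibble `region` plus the covariate column (or `x`).
#' @param spei_future tibble `region`, `year`, `spei`.
#' @param hist list with `x_range = c(min, max)` (cross-region calibration
#'   range of the covariate) and `spei_range`, a tibble `region`, `spei_min`,
#'   `spei_max` of each region's historical SPEI extremes.
#' @param policy `"extrapolate"`, `"exclude"` or `"constrain"`.
#' @param covariate name of the covariate column in `x_future`.
#' @return List `x_future`, `spei_future`, `kept_regions`.
#' @export
apply_extrapolation_policy <- function(x_future, spei_future, hist,
                                       policy = c("extrapolate", "exclude",
                                                  "constrain"),
                                       covariate = NULL) {
  policy <- match.arg(policy)
  col <- if (!is.null(covariate) && covariate %in% names(x_future)) covariate
    else if ("x" %in% names(x_future)) "x"
    else setdiff(names(x_future), "region")[1]
  if (policy == "extrapolate") {
    return(list(x_future = x_future, spei_future = spei_future,
                kept_regions = unique(x_future$region)))
  }
  if (policy == "exclude") {
    keep <- x_future$region[x_future[[col]] <= hist$x_range[2] &
                              x_future[[col]] >= hist$x_range[1]]
    return(list(
      x_future = dplyr::filter(x_future, .data$region %in% keep),
      spei_future = dplyr::filter(spei_future, .data$region %in% keep),
      kept_regions = keep))
  }
  # constrain: clip covariate to the calibration range, SPEI to each
  # region's historical extremes
  x_future[[col]] <- pmin(pmax(x_future[[col]], hist$x_range[1]),
                          hist$x_range[2])
  spei_future <- spei_future %>%
    dplyr::left_join(hist$spei_range, by = "region") %>%
    dplyr::mutate(spei = pmin(pmax(.data$spei, .data$spei_min), .data$spei_max)) %>%
    dplyr::select(-"spei_min", -"spei_max")
  list(x_future = x_future, spei_future = spei_future,
       kept_regions = unique(x_future$region))
}

#' Summarise an ensemble of burned-area changes
#'
#' Spatially averages per-simulation changes over regions (equal weights by
#' default), then reports the median, interquartile and 2.5-97.5 percentile
#' range of the resulting distribution. `mode = "rcm"` keeps only the point
#' fits (`replicate == 0`), the RCM-spread-only uncertainty; `mode = "all"`
#' pools the bootstrap replicates across members.
#'
#' @param changes tibble `member`, `replicate`, `region`, `change`
#'   (`replicate` 0 marks the point fit).
#' @param weights optional named vector of region weights.
#' @param mode `"all"` (default) or `"rcm"`.
#' @return One-row tibble `mode`, `n_sim`, `median`, `q25`, `q75`, `q025`,
#'   `q975`.
#' @export
ensemble_summary <- function(changes, weights = NULL, mode = c("all", "rcm")) {
  mode <- match.arg(mode)
  if (nrow(changes) == 0) {
    stop_medfire("no changes to summarise", "medfire_invalid_argument")
  }
  if (!"replicate" %in% names(changes)) changes$replicate <- 0
  sub <- if (mode == "rcm") dplyr::filter(changes, .data$replicate == 0)
    else if (any(changes$replicate > 0)) dplyr::filter(changes, .data$replicate > 0)
    else changes
  if (nrow(sub) == 0) sub <- changes
  sub$w <- if (is.null(weights)) 1 else unname(weights[sub$region])
  pooled <- sub %>%
    dplyr::group_by(.data$member, .data$replicate) %>%
    dplyr::summarise(change = sum(.data$change * .data$w) / sum(.data$w),
                     .groups = "drop")
  q <- quantile(pooled$change, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
  tibble::tibble(mode = mode, n_sim = nrow(pooled),
                 median = q[3], q25 = q[2], q75 = q[4], q025 = q[1], q975 = q[5])
}

#' Classify regional change significance and agreement
#'
#' The map-stippling rule: a region is `significant_agreeing` when at least
#' 50 % of the simulations show a statistically significant change AND more
#' than 66 % agree on its direction; `small_change` when fewer than 50 % are
#' significant; `no_agreement` otherwise.
#'
#' @param sims tibble `region`, `significant` (logical), `change` (the sign
#'   carries the direction), one row per simulation.
#' @return Tibble `region`, `n_sim`, `frac_significant`, `agreement`,
#'   `class`.
#' @export
classify_regions <- function(sims) {
  check_columns(sims, c("region", "significant", "change"), "simulations")
  sims %>%
    dplyr::group_by(.data$region) %>%
    dplyr::summarise(
      n_sim = dplyr::n(),
      frac_significant = mean(.data$significant),
      agreement = max(mean(.data$change > 0), mean(.data$change < 0)),
      .groups = "drop") %>%
    dplyr::mutate(class = dplyr::case_when(
      .data$frac_significant >= 0.5 & .data$agreement > 2 / 3 ~ "significant_agreeing",
      .data$frac_significant < 0.5 ~ "small_change",
      TRUE ~ "no_agreement"))
}

# Wilcoxon two-sided significance of the shift between two SPEI windows.
# Rank-based, hence invariant under the strictly monotone per-replicate
# transform exp(b1 + b2 * spei) for any b2 != 0: computed once per
# member x region and broadcast across replicates.
spei_shift_significant <- function(spei_ref, spei_fut, alpha = 0.05) {
  suppressWarnings(
    wilcox.test(spei_fut, spei_ref, exact = FALSE)$p.value) < alpha
}

#' Project burned-area changes over an RCM ensemble
#'
#' Full projection chain for one or more warming levels: per member, bias
#' correction against the observed panel (optional), member-specific SPEI
#' standardization on the reference window, warming-window search on the
#' member's global temperature series, stationary and/or non-stationary
#' percent changes for the point fit and every bootstrap replicate, the
#' extrapolation policy, and per-simulation significance flags.
#'
#' @param fits a [calibrate_fire_models()] result.
#' @param ensemble a [simulate_rcm_ensemble()] tibble (columns `member`,
#'   `climate`, `gts`).
#' @param obs observed climate panel (bias-correction reference).
#' @param beta2_model a [fit_beta2_model()] object; required for the NSM
#'   variant.
#' @param levels warming levels, degrees C.
#' @param variant `"sm"`, `"nsm"` or both.
#' @param policy extrapolation policy, see [apply_extrapolation_policy()].
#' @param reference_period reference window for bias correction, SPEI
#'   standardization and the percent-change baseline.
#' @param bias_correct apply linear scaling before computing member SPEI
#'   (the raw pathway stays available with `FALSE`).
#' @param nsm_mode reference-side convention, see [project_nsm()].
#' @param max_replicates cap on bootstrap replicates used (default: all).
#' @param alpha significance level of the per-simulation Wilcoxon test.
#' @return Tibble of class `fire_projection`: `member`, `scenario`, `level`,
#'   `variant`, `policy`, `replicate` (0 = point fit), `region`, `change`,
#'   `significant`, with the warming windows in attribute `windows`.
#' @export
project_burned_area <- function(fits, ensemble, obs, beta2_model = NULL,
                                levels = c(1.5, 2, 3),
                                variant = c("sm", "nsm"),
                                policy = "extrapolate",
                                reference_period = c(1971, 2000),
                                bias_correct = TRUE,
                                nsm_mode = "future_only",
                                max_replicates = Inf,
                                alpha = 0.05) {
  variant <- match.arg(variant, c("sm", "nsm"), several.ok = TRUE)
  if ("nsm" %in% variant && is.null(beta2_model)) {
    stop_medfire("the NSM variant needs a beta2_model", "medfire_invalid_argument")
  }
  settings <- attr(fits, "settings")
  modelled <- dplyr::filter(fits, .data$modelled)
  if (nrow(modelled) == 0) {
    stop_medfire("no modelled regions to project", "medfire_invalid_argument")
  }
  reps_all <- attr(fits, "replicates")
  if (!is.null(reps_all) && is.finite(max_replicates)) {
    reps_all <- dplyr::filter(reps_all, .data$replicate <= max_replicates)
  }
  b2_reps_wide <- NULL
  if (!is.null(reps_all) && nrow(reps_all) > 0) {
    wide <- reps_all %>%
      dplyr::select("region", "replicate", "beta2") %>%
      tidyr::pivot_wider(names_from = "region", values_from = "beta2") %>%
      dplyr::arrange(.data$replicate)
    b2_reps_wide <- as.matrix(wide[, -1, drop = FALSE])
  }
  gamma_reps <- if (!is.null(beta2_model)) beta2_model$boot else NULL

  # historical extremes for the extrapolation policies
  hist_spei <- attr(fits, "spei")
  hist <- NULL
  if (!is.null(hist_spei) && !is.null(beta2_model)) {
    hist <- list(
      x_range = range(beta2_model$data[[beta2_model$covariate]]),
      spei_range = hist_spei %>%
        dplyr::group_by(.data$region) %>%
        dplyr::summarise(spei_min = min(.data$spei), spei_max = max(.data$spei),
                         .groups = "drop"))
  }

  obs_pet <- if (bias_correct) compute_pet(obs, settings$variant) else NULL
  windows <- list()
  out <- purrr::pmap_dfr(
    ensemble[, c("member", "scenario", "climate", "gts")],
    function(member, scenario, climate, gts) {
      # PET is corrected as a derived variable: computed first, then
      # ratio-scaled alongside pre (tmean gets the additive offset)
      clim <- compute_pet(climate, settings$variant)
      if (bias_correct) {
        sf <- fit_scaling(clim, obs_pet, reference_period = reference_period)
        clim <- apply_scaling(clim, sf)
      }
      # one SPEI panel per (sc, m) actually selected, member-standardized
      specs <- dplyr::distinct(modelled[, c("sc", "m")])
      spei_panels <- purrr::pmap(specs, function(sc, m) {
        spei_panel(clim, sc, m, reference_period = reference_period)
      })
      names(spei_panels) <- paste(specs$sc, specs$m)
      member_spei <- purrr::pmap_dfr(
        modelled[, c("region", "sc", "m")],
        function(region, sc, m) {
          panel <- spei_panels[[paste(sc, m)]]
          panel[panel$region == region, ]
        })
      purrr::map_dfr(levels, function(level) {
        ww <- find_warming_window(gts, level)
        windows[[length(windows) + 1]] <<-
          dplyr::mutate(ww, member = member, scenario = scenario)
        if (!ww$reached) return(tibble::tibble())
        spei_ref <- dplyr::filter(member_spei,
                                  .data$year >= reference_period[1],
                                  .data$year <= reference_period[2])
        spei_fut <- dplyr::filter(member_spei,
                                  .data$year >= ww$start_year,
                                  .data$year <= ww$end_year)
        x_fut <- if (!is.null(beta2_model)) {
          compute_normals(clim, c(ww$start_year, ww$end_year),
                          settings$variant)
        } else NULL
        x_ref <- if (!is.null(beta2_model)) {
          compute_normals(clim, reference_period, settings$variant)
        } else NULL
        kept <- modelled$region
        if (policy != "extrapolate" && !is.null(hist) && !is.null(x_fut)) {
          adj <- apply_extrapolation_policy(x_fut, spei_fut, hist,
                                            policy = policy,
                                            covariate = beta2_model$covariate)
          x_fut <- adj$x_future
          spei_fut <- adj$spei_future
          kept <- intersect(kept, adj$kept_regions)
        }
        sig <- purrr::map_lgl(kept, function(rg) {
          spei_shift_significant(spei_ref$spei[spei_ref$region == rg],
                                 spei_fut$spei[spei_fut$region == rg],
                                 alpha = alpha)
        })
        names(sig) <- kept
        fit_rows <- dplyr::filter(modelled, .data$region %in% kept)
        sr_list <- split(spei_ref$spei, spei_ref$region)
        sf_list <- split(spei_fut$spei, spei_fut$region)
        # replicate 0 = point fit; the per-region intercept cancels in the
        # percent-change ratio, so only beta2 matters here
        b2_point <- setNames(fit_rows$beta2, fit_rows$region)
        b2_hist <- rbind(b2_point,
                         if (!is.null(b2_reps_wide))
                           b2_reps_wide[, fit_rows$region, drop = FALSE])
        rep_ids <- seq_len(nrow(b2_hist)) - 1L
        xf_vec <- if (!is.null(x_fut)) {
          v <- setNames(x_fut[[beta2_model$covariate]], x_fut$region)
          v[fit_rows$region]
        } else NULL
        xr_vec <- if (!is.null(x_ref)) {
          v <- setNames(x_ref[[beta2_model$covariate]], x_ref$region)
          v[fit_rows$region]
        } else NULL
        g1 <- g2 <- NULL
        if (!is.null(beta2_model)) {
          g1 <- c(beta2_model$gamma1,
                  if (!is.null(gamma_reps)) gamma_reps$gamma1[rep_ids[-1]])
          g2 <- c(beta2_model$gamma2,
                  if (!is.null(gamma_reps)) gamma_reps$gamma2[rep_ids[-1]])
          g1 <- rep_len(g1, length(rep_ids))
          g2 <- rep_len(g2, length(rep_ids))
        }
        purrr::map_dfr(variant, function(v) {
          b2_fut <- if (v == "sm") b2_hist else outer(g2, xf_vec) + g1
          b2_ref <- if (v == "sm" || nsm_mode == "future_only") b2_hist
            else outer(g2, xr_vec) + g1
          ch <- vapply(seq_along(fit_rows$region), function(j) {
            rg <- fit_rows$region[j]
            cr <- rowMeans(exp(outer(b2_ref[, j], sr_list[[rg]])))
            cf <- rowMeans(exp(outer(b2_fut[, j], sf_list[[rg]])))
            100 * (cf - cr) / cr
          }, numeric(length(rep_ids)))
          tibble::tibble(
            member = member, scenario = scenario, level = level,
            variant = v, policy = policy,
            replicate = rep(rep_ids, times = length(fit_rows$region)),
            region = rep(fit_rows$region, each = length(rep_ids)),
            change = as.numeric(ch)) %>%
            dplyr::filter(is.finite(.data$change)) %>%
            dplyr::mutate(significant = unname(sig[.data$region]) &
                            abs(.data$change) > 1e-12)
        })
      })
    })
  attr(out, "windows") <- dplyr::bind_rows(windows)
  class(out) <- c("fire_projection", class(out))
  out
}
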