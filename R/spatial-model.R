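#' Long-term climate normals per region
#'
#' Computes the six candidate covariates of the cross-region drought-
#' sensitivity model: mean annual and summer (JJAS) temperature (`Ty`, `Ts`),
#' mean annual and summer precipitation totals (`PREy`, `PREs`), and the
#' corresponding water-balance totals (`P_PETy`, `P_PETs`), averaged over the
#' declared window, plus the region centroids.
#'
#' @param climate climate panel; a `pet` column is added when absent.
#' @param window averaging window `c(start_year, end_year)`.
#' @param variant PET variant used when `pet` must be computed.
#' @return Tibble with one row per region: `region`, `lat`, `lon`, `Ty`,
#'   `Ts`, `PREy`, `PREs`, `P_PETy`, `P_PETs`; window kept as attribute.
#' @export
compute_normals <- function(climate, window, variant = "modified") {
  check_window(window, "window")
  if (!"pet" %in% names(climate)) climate <- compute_pet(climate, variant)
  sub <- dplyr::filter(climate, .data$year >= window[1], .data$year <= window[2])
  got_years <- sub %>% dplyr::count(.data$region, .data$year)
  if (nrow(sub) == 0 ||
      !all(table(got_years$region) == window[2] - window[1] + 1) ||
      any(got_years$n != 12)) {
    stop_medfire("climate panel does not fully cover the averaging window",
                 "medfire_insufficient_data")
  }
  out <- sub %>%
    dplyr::group_by(.data$region) %>%
    dplyr::summarise(
      lat = .data$lat[1], lon = .data$lon[1],
      Ty = mean(.data$tmean),
      Ts = mean(.data$tmean[.data$month %in% SUMMER_MONTHS]),
      PREy = sum(.data$pre) / dplyr::n_distinct(.data$year),
      PREs = sum(.data$pre[.data$month %in% SUMMER_MONTHS]) /
        dplyr::n_distinct(.data$year),
      P_PETy = sum(.data$pre - .data$pet) / dplyr::n_distinct(.data$year),
      P_PETs = sum((.data$pre - .data$pet)[.data$month %in% SUMMER_MONTHS]) /
        dplyr::n_distinct(.data$year),
      .groups = "drop")
  attr(out, "window") <- window
  out
}

#' Moran's I with permutation inference
#'
#' Spatial autocorrelation statistic with inverse-distance, row-standardized
#' weights and a seeded permutation p-value (default 999 permutations,
#' upper-tailed: positive autocorrelation).
#'
#' @param values numeric vector (e.g. model residuals), one per region.
#' @param coords two-column matrix or tibble of centroid coordinates
#'   (lon, lat or any planar pair).
#' @param nperm permutations.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @param seed integer seed or `NULL`.
#' @return List with `I`, `expected` (`-1/(n-1)`), `p`, `weights`.
#' @export
morans_i <- function(values, coords, nperm = 999,
                     alternative = c("greater", "less", "two.sided"),
                     seed = NULL) {
  alternative <- match.arg(alternative)
  n <- length(values)
  if (n < 8) stop_medfire("need at least 8 regions", "medfire_invalid_argument")
  if (sd(values) < 1e-12) {
    stop_medfire("all residuals equal: Moran's I undefined",
                 "medfire_undefined_statistic")
  }
  coords <- as.matrix(coords)
  d <- as.matrix(stats::dist(coords))
  if (any(d[upper.tri(d)] < 1e-12)) {
    stop_medfire("coincident centroids: inverse-distance weights undefined",
                 "medfire_invalid_argument")
  }
  w <- 1 / d
  diag(w) <- 0
  w <- w / rowSums(w)
  moran_stat <- function(v) {
    z <- v - mean(v)
    (n / sum(w)) * sum(w * outer(z, z)) / sum(z^2)
  }
  i_obs <- moran_stat(values)
  i_perm <- with_seed_if(seed, {
    vapply(seq_len(nperm), function(k) moran_stat(sample(values)), numeric(1))
  })
  e_i <- -1 / (n - 1)
  p <- switch(alternative,
    greater = (sum(i_perm >= i_obs) + 1) / (nperm + 1),
    less = (sum(i_perm <= i_obs) + 1) / (nperm + 1),
    two.sided = (sum(abs(i_perm - e_i) >= abs(i_obs - e_i)) + 1) / (nperm + 1))
  list(I = i_obs, expected = e_i, p = p, weights = w)
}

#' Fit the cross-region drought-sensitivity model
#'
#' Ordinary least squares for `beta2(i) = gamma1 + gamma2 * X(i) + eps(i)`
#' over the modelled regions, where `X` is one long-term climate normal.
#' Reports the correlation between fitted and observed sensitivities with a
#' permutation p-value, Moran's I on the residuals (spatially uncorrelated
#' noise is an assumption to be checked post hoc), and region-resampling
#' bootstrap confidence intervals for the coefficients. Optionally
#' inverse-variance weighted when per-region `beta2` standard errors are
#' supplied.
#'
#' @param beta2 tibble with `region` and `beta2` (e.g. a
#'   [calibrate_fire_models()] result), `NA` rows dropped.
#' @param normals a [compute_normals()] tibble.
#' @param covariate one of `"Ty"`, `"Ts"`, `"PREy"`, `"PREs"`, `"P_PETy"`,
#'   `"P_PETs"`.
#' @param exclude region ids excluded before fitting (e.g. a known outlier).
#' @param weights optional per-region weights (same order as the merged
#'   data), e.g. `1/se^2`.
#' @param nboot bootstrap replicates for the coefficient CIs.
#' @param nperm permutations for the correlation significance.
#' @param moran run the Moran's I residual diagnostic (default `TRUE`).
#' @param seed integer seed or `NULL`.
#' @return Object of class `beta2_model`: coefficients, correlation and its
#'   p-value, Moran's I results, bootstrap replicates and 95 % CIs, the data
#'   used, and the covariate name.
#' @export
fit_beta2_model <- function(beta2, normals, covariate = "Ty", exclude = NULL,
                            weights = NULL, nboot = 1000, nperm = 1000,
                            moran = TRUE, seed = NULL) {
  check_columns(normals, c("region", covariate), "normals")
  df <- beta2 %>%
    dplyr::select("region", "beta2") %>%
    dplyr::filter(!is.na(.data$beta2), !.data$region %in% exclude) %>%
    dplyr::inner_join(normals, by = "region")
  if (nrow(df) < 10) {
    stop_medfire("need at least 10 modelled regions", "medfire_insufficient_data")
  }
  x <- df[[covariate]]
  y <- df$beta2
  if (sd(x) < 1e-12) {
    stop_medfire("constant covariate: rank-deficient design",
                 "medfire_rank_deficient")
  }
  fit <- if (is.null(weights)) lm(y ~ x) else lm(y ~ x, weights = weights)
  gam <- unname(coef(fit))
  fitted <- gam[1] + gam[2] * x
  r_obs <- cor(fitted, y)
  r_perm <- with_seed_if(derive_seed(seed, 1), {
    vapply(seq_len(nperm), function(k) abs(cor(x[sample(length(x))], y)),
           numeric(1))
  })
  cor_p <- (sum(r_perm >= abs(cor(x, y))) + 1) / (nperm + 1)
  # Moran's I is undefined on an exact fit; report NA rather than failing
  moran <- if (moran && all(c("lon", "lat") %in% names(df)) &&
               sd(y - fitted) > 1e-12) {
    morans_i(y - fitted, df[, c("lon", "lat")], seed = derive_seed(seed, 2))
  } else NULL
  boot <- with_seed_if(derive_seed(seed, 3), {
    purrr::map_dfr(seq_len(nboot), function(b) {
      i <- sample.int(nrow(df), replace = TRUE)
      if (sd(x[i]) < 1e-12) i <- seq_len(nrow(df)) # degenerate resample guard
      cb <- unname(coef(lm(y[i] ~ x[i])))
      tibble::tibble(replicate = b, gamma1 = cb[1], gamma2 = cb[2])
    })
  })
  ci <- tibble::tibble(
    term = c("gamma1", "gamma2"),
    estimate = gam,
    conf.low = c(quantile(boot$gamma1, 0.025), quantile(boot$gamma2, 0.025)),
    conf.high = c(quantile(boot$gamma1, 0.975), quantile(boot$gamma2, 0.975)))
  structure(list(
    covariate = covariate, gamma1 = gam[1], gamma2 = gam[2],
    correlation = r_obs, cor_p = cor_p,
    moran_I = if (is.null(moran)) NA_real_ else moran$I,
    moran_p = if (is.null(moran)) NA_real_ else moran$p,
    boot = boot, ci = ci, data = df, excluded = exclude,
    residuals = y - fitted), class = "beta2_model")
}

#' Predict drought sensitivity from a climate normal
#'
#' @param object a `beta2_model`.
#' @param newdata tibble containing the model's covariate column (or a bare
#'   numeric vector of covariate values).
#' @param ... unused.
#' @return Numeric vector of predicted `beta2`.
#' @export
predict.beta2_model <- function(object, newdata, ...) {
  x <- if (is.numeric(newdata)) newdata else {
    check_columns(newdata, object$covariate, "newdata")
    newdata[[object$covariate]]
  }
  object$gamma1 + object$gamma2 * x
}

#' @export
print.beta2_model <- function(x, ...) {
  cat(sprintf("beta2 ~ %s: gamma1 = %.3f, gamma2 = %.5f (r = %.2f, p = %.3f; Moran p = %.3f)\n",
              x$covariate, x$gamma1, x$gamma2, x$correlation, x$cor_p, x$moran_p))
  invisible(x)
}

#' Rank candidate drought-sensitivity models
#'
#' Keeps candidates whose simulated-vs-observed correlation is significant
#' and whose residuals pass the Moran's I check (no spatial autocorrelation),
#' sorted by correlation; the top row is the default non-stationary-model
#' covariate.
#'
#' @param models list of `beta2_model` objects.
#' @param alpha significance level for both filters.
#' @return Tibble `covariate`, `gamma1`, `gamma2`, `correlation`, `cor_p`,
#'   `moran_p`, `retained`, sorted by correlation among retained candidates
#'   first. Warns when every candidate is filtered out.
#' @export
rank_beta2_models <- function(models, alpha = 0.05) {
  if (length(models) < 1) {
    stop_medfire("need at least one candidate model", "medfire_invalid_argument")
  }
  tab <- purrr::map_dfr(models, function(mod) {
    tibble::tibble(covariate = mod$covariate, gamma1 = mod$gamma1,
                   gamma2 = mod$gamma2, correlation = mod$correlation,
                   cor_p = mod$cor_p, moran_p = mod$moran_p)
  })
  tab <- tab %>%
    dplyr::mutate(retained = .data$cor_p <= alpha &
                    (is.na(.data$moran_p) | .data$moran_p > alpha)) %>%
    dplyr::arrange(dplyr::desc(.data$retained), dplyr::desc(.data$correlation))
  if (!any(tab$retained)) {
    warn("no candidate model passes the correlation and Moran's I filters")
  }
  tab
}
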