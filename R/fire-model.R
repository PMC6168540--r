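#' Spatially coherent permutation test for negative correlation
#'
#' One-tailed permutation p-values for the correlation between two panels,
#' against the alternative of negative correlation. Within each of the `B`
#' iterations one permutation of the year index is drawn and applied
#' identically to every region, which preserves the cross-region dependence
#' structure of the data (the field-significance convention). P-values use the
#' add-one convention `p = (r + 1) / (B + 1)`.
#'
#' @param data long tibble with columns `region`, `year` and the two series.
#' @param x,y names of the shuffled variable (`x`) and the fixed variable
#'   (`y`).
#' @param B number of permutations (>= 100).
#' @param seed integer seed or `NULL`.
#' @param perms optional pre-drawn permutation matrix (`n_years x B`) so that
#'   several candidate predictors can share one resampling sequence.
#' @return Tibble `region`, `r` (observed correlation), `p`.
#' @export
perm_cor_test <- function(data, x, y, B = 1000, seed = NULL, perms = NULL) {
  if (is.null(perms) && B < 100) {
    stop_medfire("B must be >= 100", "medfire_invalid_argument")
  }
  X <- panel_to_matrix(data, x)
  Y <- panel_to_matrix(data, y)
  if (any(apply(X, 2, sd) < 1e-12) || any(apply(Y, 2, sd) < 1e-12)) {
    stop_medfire("constant series: correlation undefined",
                 "medfire_undefined_correlation")
  }
  n <- nrow(X)
  if (is.null(perms)) {
    perms <- with_seed_if(seed, {
      matrix(replicate(B, sample.int(n)), nrow = n)
    })
  }
  B <- ncol(perms)
  Xs <- scale(X); Ys <- scale(Y)
  r_obs <- colSums(Xs * Ys) / (n - 1)
  exceed <- cpp_perm_exceed(Xs, Ys, perms, r_obs)
  tibble::tibble(region = colnames(X), r = unname(r_obs),
                 p = (as.numeric(exceed) + 1) / (B + 1))
}

#' Benjamini-Hochberg false-discovery-rate filter
#'
#' Step-up FDR mask at level `alpha`, the standard control for field
#' significance over many regions and candidate predictors.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return Logical mask, `TRUE` where the hypothesis is rejected.
#' @export
fdr_filter <- function(p, alpha = 0.05) {
  if (length(p) == 0) {
    stop_medfire("empty p-value vector", "medfire_invalid_argument")
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop_medfire("p-values must lie in [0, 1]", "medfire_invalid_argument")
  }
  p.adjust(p, method = "BH") <= alpha
}

#' Select the best SPEI predictor per region
#'
#' Implements the predictor search: correlate log burned area with every
#' candidate `SPEI(sc, m)` panel, assess one-tailed (negative) significance
#' with the spatially coherent permutation test (one shared permutation
#' sequence reused across all candidates), control the false discovery rate
#' across all region-by-candidate tests with Benjamini-Hochberg, and per
#' region keep the significant candidate with the most negative correlation.
#' Regions with no significant candidate are flagged unmodelled.
#'
#' @param ba burned-area tibble (`region`, `year`, `ba` > 0).
#' @param candidates list of SPEI panels from [spei_panel()] (each carrying
#'   `sc`/`m` attributes), or a tibble with columns `sc`, `m`, `panel`.
#' @param B permutations.
#' @param alpha FDR level.
#' @param seed integer seed or `NULL`.
#' @param years optional calibration-year restriction.
#' @return Tibble `region`, `modelled`, `sc`, `m`, `r`, `p`, `p_adj`, with
#'   attribute `diagnostics` holding the full region-by-candidate table.
#' @export
select_spei_predictor <- function(ba, candidates, B = 1000, alpha = 0.05,
                                  seed = NULL, years = NULL) {
  check_columns(ba, c("region", "year", "ba"), "burned area")
  if (any(ba$ba <= 0)) {
    stop_medfire("burned area must be strictly positive (log is taken)",
                 "medfire_invalid_argument")
  }
  if (tibble::is_tibble(candidates) && "panel" %in% names(candidates)) {
    panels <- candidates$panel
    specs <- candidates[, c("sc", "m")]
  } else {
    panels <- candidates
    specs <- tibble::tibble(sc = purrr::map_dbl(panels, ~ attr(.x, "sc")),
                            m = purrr::map_dbl(panels, ~ attr(.x, "m")))
  }
  if (!is.null(years)) ba <- dplyr::filter(ba, .data$year %in% years)
  ba <- dplyr::mutate(ba, log_ba = log(.data$ba))
  n_years <- length(unique(ba$year))
  perms <- with_seed_if(seed, matrix(replicate(B, sample.int(n_years)), nrow = n_years))
  diag <- purrr::map2_dfr(panels, seq_len(nrow(specs)), function(panel, i) {
    joined <- dplyr::inner_join(ba, panel, by = c("region", "year"))
    if (length(unique(joined$year)) != n_years) {
      stop_medfire("candidate SPEI panel does not cover the calibration years",
                   "medfire_mismatch")
    }
    perm_cor_test(joined, x = "spei", y = "log_ba", perms = perms) %>%
      dplyr::mutate(sc = specs$sc[i], m = specs$m[i])
  })
  diag$p_adj <- p.adjust(diag$p, method = "BH")
  diag$significant <- diag$p_adj <= alpha
  chosen <- diag %>%
    dplyr::group_by(.data$region) %>%
    dplyr::group_modify(function(df, key) {
      sig <- dplyr::filter(df, .data$significant)
      if (nrow(sig) == 0) {
        tibble::tibble(modelled = FALSE, sc = NA_real_, m = NA_real_,
                       r = NA_real_, p = NA_real_, p_adj = NA_real_)
      } else {
        best <- sig[which.min(sig$r), ]
        tibble::tibble(modelled = TRUE, sc = best$sc, m = best$m,
                       r = best$r, p = best$p, p_adj = best$p_adj)
      }
    }) %>%
    dplyr::ungroup()
  attr(chosen, "diagnostics") <- diag
  chosen
}

#' Mann-Kendall trend test
#'
#' Hand-rolled S statistic with tie-corrected variance and continuity
#' correction; two-sided p-value from the normal approximation.
#'
#' @param x numeric series.
#' @return List with `S`, `var_s`, `z`, `p`.
#' @export
mann_kendall <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) stop_medfire("need at least 3 observations", "medfire_invalid_argument")
  d <- outer(x, x, "-")
  S <- sum(sign(d[lower.tri(d)])) # lower.tri holds x_i - x_j, i > j (later - earlier)
  ties <- table(x)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (var_s > 0 && S != 0) (S - sign(S)) / sqrt(var_s) else 0
  list(S = S, var_s = var_s, z = z, p = 2 * pnorm(-abs(z)))
}

#' Trend gate for the burned-area regression
#'
#' The model includes the linear time term only when either the log
#' burned-area series or the selected SPEI series shows a significant
#' Mann-Kendall trend (p < 0.05); otherwise `beta3` is fixed at zero.
#'
#' @param log_ba,spei aligned annual series.
#' @param alpha significance level of the gate.
#' @return Logical.
#' @export
mk_trend_gate <- function(log_ba, spei, alpha = 0.05) {
  if (length(log_ba) < 10) {
    stop_medfire("need at least 10 observations for the trend gate",
                 "medfire_invalid_argument")
  }
  mann_kendall(log_ba)$p < alpha || mann_kendall(spei)$p < alpha
}

#' Robust fit of the drought-fire regression for one region
#'
#' Iteratively reweighted least squares with a Tukey bisquare weighting
#' function (tuning constant 4.685, 95 % Gaussian efficiency), started from
#' OLS, on `log BA ~ SPEI (+ centred year)`. The trend covariate is the
#' calendar year minus the midpoint of the fitted years, so the intercept is
#' the expected log burned area at SPEI = 0 mid-window.
#'
#' @param data tibble with `year`, `ba` (or `log_ba`) and `spei`.
#' @param include_trend include the linear time term (else `beta3 = 0`).
#' @param c bisquare tuning constant.
#' @param maxit,tol IRLS iteration cap and coefficient-change tolerance.
#' @return List of class `fire_fit`: `coef` (beta1, beta2, beta3),
#'   `residuals`, `fitted`, `include_trend`, `year_center`, `iterations`,
#'   `converged`, `data`.
#' @export
fit_fire_model <- function(data, include_trend = FALSE, c = 4.685,
                           maxit = 300, tol = 1e-8) {
  if (!"log_ba" %in% names(data)) {
    check_columns(data, c("year", "ba", "spei"), "fit data")
    if (any(data$ba <= 0)) {
      stop_medfire("burned area must be strictly positive", "medfire_invalid_argument")
    }
    data <- dplyr::mutate(data, log_ba = log(.data$ba))
  }
  data <- dplyr::arrange(data, .data$year)
  year_center <- floor(median(data$year))
  X <- cbind(1, data$spei)
  if (include_trend) X <- cbind(X, data$year - year_center)
  res <- cpp_irls_bisquare(X, data$log_ba, c = c, maxit = maxit, tol = tol)
  if (!res$converged) {
    stop_medfire(sprintf("IRLS did not converge in %d iterations", maxit),
                 "medfire_convergence")
  }
  beta <- as.numeric(res$coef)
  if (!include_trend) beta <- c(beta, 0)
  structure(list(
    coef = setNames(beta, c("beta1", "beta2", "beta3")),
    residuals = as.numeric(res$residuals),
    fitted = data$log_ba - as.numeric(res$residuals),
    include_trend = include_trend, year_center = year_center,
    iterations = res$iterations, converged = res$converged,
    data = data), class = "fire_fit")
}

#' @export
print.fire_fit <- function(x, ...) {
  cat("Robust drought-fire fit (IRLS bisquare)\n")
  print(round(x$coef, 4))
  invisible(x)
}

# Draw an n x B matrix of shared resampled year indices; degenerate columns
# (a single year drawn n times, which would make every region's SPEI
# resample constant) are redrawn, max 10 attempts.
draw_boot_indices <- function(S, B, seed = NULL) {
  n <- nrow(S)
  with_seed_if(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
    for (attempt in 1:10) {
      bad <- which(apply(idx, 2, function(i) length(unique(i)) == 1L))
      if (length(bad) == 0) break
      idx[, bad] <- sample.int(n, n * length(bad), replace = TRUE)
    }
    idx
  })
}

#' Bootstrap the drought-fire model parameters
#'
#' Pairs (case) resampling of years, drawn with replacement `B` times with
#' the identical resampled year sequence applied to every region within an
#' iteration (preserving cross-region dependence), refitting the robust
#' regression each time.
#'
#' @param log_ba_mat,spei_mat years-by-regions matrices of aligned log burned
#'   area and selected SPEI.
#' @param include_trend logical per region.
#' @param years year vector (for the trend covariate).
#' @param B replicates (default 1000).
#' @param seed integer seed or `NULL`.
#' @param c,maxit,tol IRLS settings, see [fit_fire_model()].
#' @return Tibble `region`, `replicate`, `beta1`, `beta2`, `beta3`.
#' @export
bootstrap_fire_models <- function(log_ba_mat, spei_mat, include_trend, years,
                                  B = 1000, seed = NULL, c = 4.685,
                                  maxit = 300, tol = 1e-8) {
  stopifnot(identical(dim(log_ba_mat), dim(spei_mat)))
  idx <- draw_boot_indices(spei_mat, B, seed = seed)
  trend <- years - floor(median(years))
  cube <- cpp_bootstrap_irls(log_ba_mat, spei_mat, trend,
                             rep_len(include_trend, ncol(spei_mat)),
                             idx, c = c, maxit = maxit, tol = tol)
  regions <- colnames(log_ba_mat)
  purrr::map_dfr(seq_along(regions), function(r) {
    tibble::tibble(region = regions[r], replicate = seq_len(B),
                   beta1 = cube[, 1, r], beta2 = cube[, 2, r],
                   beta3 = cube[, 3, r])
  })
}

#' Leave-one-out cross-validated skill
#'
#' Each year's log burned area is predicted from a robust model fitted
#' without that year; the skill is the correlation between observations and
#' the out-of-sample predictions.
#'
#' @inheritParams fit_fire_model
#' @return Numeric cross-validated correlation.
#' @export
loocv_skill <- function(data, include_trend = FALSE, ...) {
  if (!"log_ba" %in% names(data)) {
    data <- dplyr::mutate(data, log_ba = log(.data$ba))
  }
  data <- dplyr::arrange(data, .data$year)
  n <- nrow(data)
  if (n < 5) stop_medfire("need at least 5 years", "medfire_insufficient_data")
  year_center <- floor(median(data$year))
  X <- cbind(1, data$spei)
  if (include_trend) X <- cbind(X, data$year - year_center)
  preds <- purrr::map_dbl(seq_len(n), function(i) {
    res <- cpp_irls_bisquare(X[-i, , drop = FALSE], data$log_ba[-i], ...)
    if (!res$converged) {
      stop_medfire("IRLS did not converge in a leave-one-out fit",
                   "medfire_convergence")
    }
    sum(as.numeric(res$coef) * X[i, ])
  })
  cor(data$log_ba, preds)
}

#' Calibrate the drought-fire model for every region
#'
#' End-to-end calibration: candidate SPEI panels over the `(sc, m)` grid,
#' spatially coherent permutation significance with FDR control, per-region
#' predictor choice, Mann-Kendall trend gating, robust IRLS fit, shared-
#' sequence bootstrap uncertainty, and leave-one-out cross-validated skill.
#'
#' @param ba burned-area tibble (`region`, `year`, `ba`).
#' @param climate climate panel covering the SPEI needs of the candidate grid
#'   and the reference window.
#' @param scales,months candidate grid (defaults 3/6/12 by March-September).
#' @param reference_period SPEI standardization window.
#' @param calibration_years years used for fitting (default: all burned-area
#'   years).
#' @param B bootstrap/permutation replicates.
#' @param alpha FDR level.
#' @param seed integer seed or `NULL`.
#' @param variant PET variant.
#' @param cv compute the leave-one-out skill per region (default `TRUE`;
#'   switch off in bulk simulations where only coefficients are needed).
#' @return Tibble of class `fire_model_set`: one row per region with the
#'   selection diagnostics, coefficients, in-sample and cross-validated
#'   correlations. Attributes: `replicates` (bootstrap tibble), `residuals`,
#'   `spei` (selected SPEI panels, long), `candidates`, `settings`.
#' @export
calibrate_fire_models <- function(ba, climate, scales = c(3, 6, 12),
                                  months = 3:9,
                                  reference_period = c(1971, 2000),
                                  calibration_years = NULL,
                                  B = 1000, alpha = 0.05, seed = NULL,
                                  variant = "modified", cv = TRUE) {
  if (is.null(calibration_years)) calibration_years <- sort(unique(ba$year))
  ba_cal <- ba %>%
    dplyr::filter(.data$year %in% calibration_years) %>%
    dplyr::mutate(log_ba = log(.data$ba))
  if (!"pet" %in% names(climate)) climate <- compute_pet(climate, variant)
  grid <- tidyr::expand_grid(sc = scales, m = months)
  candidates <- purrr::map2(grid$sc, grid$m, function(sc, m) {
    spei_panel(climate, sc, m, reference_period = reference_period)
  })
  sel <- select_spei_predictor(ba_cal, candidates, B = B, alpha = alpha,
                               seed = derive_seed(seed, 1),
                               years = calibration_years)
  spec_key <- paste(grid$sc, grid$m)
  per_region <- sel %>%
    dplyr::mutate(fit = purrr::pmap(
      list(.data$region, .data$modelled, .data$sc, .data$m),
      function(region, modelled, sc, m) {
        if (!modelled) {
          return(tibble::tibble(include_trend = NA, beta1 = NA_real_,
                                beta2 = NA_real_, beta3 = NA_real_,
                                r_insample = NA_real_, cv_cor = NA_real_))
        }
        rg <- region
        panel <- candidates[[match(paste(sc, m), spec_key)]]
        df <- ba_cal[ba_cal$region == rg, ] %>%
          dplyr::inner_join(panel[panel$region == rg, ],
                            by = c("region", "year"))
        gate <- mk_trend_gate(df$log_ba, df$spei)
        fit <- fit_fire_model(df, include_trend = gate)
        tibble::tibble(include_trend = gate,
                       beta1 = fit$coef[["beta1"]],
                       beta2 = fit$coef[["beta2"]],
                       beta3 = fit$coef[["beta3"]],
                       r_insample = cor(df$log_ba, fit$fitted),
                       cv_cor = if (cv) loocv_skill(df, include_trend = gate)
                         else NA_real_)
      })) %>%
    tidyr::unnest("fit")

  modelled <- dplyr::filter(per_region, .data$modelled)
  replicates <- NULL
  spei_long <- NULL
  residuals <- NULL
  if (nrow(modelled) > 0) {
    sel_panels <- purrr::pmap_dfr(
      modelled[, c("region", "sc", "m")],
      function(region, sc, m) {
        panel <- candidates[[match(paste(sc, m), spec_key)]]
        panel[panel$region == region, ]
      })
    spei_long <- sel_panels
    joined <- ba_cal %>%
      dplyr::inner_join(sel_panels, by = c("region", "year")) %>%
      dplyr::filter(.data$region %in% modelled$region)
    Ym <- panel_to_matrix(joined, "log_ba")
    Sm <- panel_to_matrix(joined, "spei")
    Ym <- Ym[, modelled$region, drop = FALSE]
    Sm <- Sm[, modelled$region, drop = FALSE]
    # replicate fits use a slightly looser tolerance: percentile CIs are
    # insensitive below ~1e-4 and the tight tolerance only lengthens the
    # IRLS tail
    replicates <- bootstrap_fire_models(
      Ym, Sm, include_trend = modelled$include_trend,
      years = as.numeric(rownames(Ym)), B = B, seed = derive_seed(seed, 2),
      maxit = 150, tol = 1e-6)
    residuals <- joined %>%
      dplyr::left_join(modelled[, c("region", "beta1", "beta2", "beta3")],
                       by = "region") %>%
      dplyr::mutate(residual = .data$log_ba - .data$beta1 -
                      .data$beta2 * .data$spei -
                      .data$beta3 * (.data$year - floor(median(calibration_years)))) %>%
      dplyr::select("region", "year", "residual")
  }
  out <- per_region
  attr(out, "replicates") <- replicates
  attr(out, "residuals") <- residuals
  attr(out, "spei") <- spei_long
  attr(out, "settings") <- list(scales = scales, months = months,
                                reference_period = reference_period,
                                calibration_years = calibration_years,
                                B = B, alpha = alpha, seed = seed,
                                variant = variant)
  class(out) <- c("fire_model_set", class(out))
  out
}
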