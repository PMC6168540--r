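test_that("perfect negative correlation attains the minimum permutation p-value", {
  set.seed(1)
  x <- rnorm(24)
  df <- tibble(region = "R01", year = seq_along(x), x = x, y = -x)
  res <- perm_cor_test(df, "x", "y", B = 499, seed = 2)
  expect_equal(res$r, -1)
  expect_equal(res$p, 1 / 500)
})

test_that("the permutation engine matches a plain-R oracle and shares sequences", {
  set.seed(3)
  n <- 15
  df <- bind_rows(lapply(1:4, function(i) {
    tibble(region = sprintf("R%02d", i), year = 1:n,
           x = rnorm(n), y = rnorm(n))
  }))
  perms <- matrix(replicate(60, sample.int(n)), nrow = n)
  res <- perm_cor_test(df, "x", "y", perms = perms)
  # oracle: direct R loop applying each permutation identically to all regions
  X <- matrix(df$x, nrow = n); Y <- matrix(df$y, nrow = n)
  r_obs <- sapply(1:4, function(j) cor(X[, j], Y[, j]))
  exceed <- rowSums(sapply(seq_len(ncol(perms)), function(b) {
    sapply(1:4, function(j) cor(X[perms[, b], j], Y[, j]) <= r_obs[j])
  }))
  expect_equal(res$p, (exceed + 1) / (ncol(perms) + 1))
  expect_error(perm_cor_test(tibble(region = "a", year = 1:10, x = 1, y = rnorm(10)),
                             "x", "y", B = 100),
               class = "medfire_undefined_correlation")
})

test_that("Benjamini-Hochberg filter follows the step-up rule", {
  expect_true(all(fdr_filter(rep(0.001, 7))))
  # hand case: adjusted p are (0.04, 0.04, 0.0533, 0.8) so two pass at 0.05
  expect_equal(fdr_filter(c(0.01, 0.02, 0.04, 0.8)),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_error(fdr_filter(numeric(0)), class = "medfire_invalid_argument")
  expect_error(fdr_filter(c(0.2, 1.4)), class = "medfire_invalid_argument")
  # null property: average false-discovery proportion stays at or below alpha
  set.seed(4)
  fdp <- replicate(400, mean(fdr_filter(runif(20), alpha = 0.05)))
  expect_lte(mean(fdp), 0.05 + 0.01)
})

test_that("predictor selection applies the argmin-correlation rule", {
  set.seed(5)
  n <- 27
  years <- 1985:2011
  mk_panel <- function(vals, sc, m) {
    out <- tibble(region = "R01", year = years, spei = vals, clamped = FALSE)
    attr(out, "sc") <- sc; attr(out, "m") <- m
    out
  }
  s1 <- rnorm(n)
  s2 <- 0.6 * s1 + sqrt(1 - 0.36) * rnorm(n) # weaker correlate
  y <- -s1 + rnorm(n, 0, 0.25)
  ba <- tibble(region = "R01", year = years, ba = exp(5 + y))
  sel <- select_spei_predictor(ba, list(mk_panel(s1, 3, 8), mk_panel(s2, 6, 7)),
                               B = 500, seed = 6)
  expect_true(sel$modelled)
  expect_equal(c(sel$sc, sel$m), c(3, 8))
  diag <- attr(sel, "diagnostics")
  expect_equal(nrow(diag), 2)
  expect_lt(diag$r[diag$sc == 3], diag$r[diag$sc == 6])
})

test_that("Mann-Kendall statistic and gate behave as enumerated", {
  mk <- mann_kendall(c(1, 3, 2))
  expect_equal(mk$S, 1) # pairs: (1,3)+1, (1,2)+1, (3,2)-1
  # brute-force S oracle on a random series with ties
  set.seed(7)
  x <- sample(1:10, 27, replace = TRUE)
  S_brute <- sum(sign(outer(x, x, "-")[lower.tri(matrix(0, 27, 27))]))
  expect_equal(mann_kendall(x)$S, S_brute)
  # strictly increasing series of length 27 triggers the gate
  expect_lt(mann_kendall(as.numeric(1:27))$p, 0.05)
  expect_true(mk_trend_gate(as.numeric(1:27), rnorm(27)))
  expect_error(mk_trend_gate(1:5, 1:5), class = "medfire_invalid_argument")
})

test_that("the robust fit interpolates noiseless data and resists outliers", {
  set.seed(8)
  spei <- rnorm(27)
  df <- tibble(year = 1985:2011, spei = spei, log_ba = 2 - 1 * spei)
  fit <- fit_fire_model(df)
  expect_equal(unname(fit$coef[c("beta1", "beta2")]), c(2, -1),
               tolerance = 1e-8)
  expect_identical(fit$coef[["beta3"]], 0)
  # with the trend gated off beta3 stays zero even on trending data
  df2 <- df %>% mutate(log_ba = log_ba + 0.05 * (year - 1998))
  expect_identical(fit_fire_model(df2, include_trend = FALSE)$coef[["beta3"]], 0)
  expect_false(fit_fire_model(df2, include_trend = TRUE)$coef[["beta3"]] == 0)

  # one gross outlier: the robust slope moves far less than the OLS slope
  dfn <- tibble(year = 1985:2011, spei = spei,
                log_ba = 2 - spei + rnorm(27, 0, 0.2))
  b_clean <- fit_fire_model(dfn)$coef[["beta2"]]
  ols_clean <- coef(lm(log_ba ~ spei, dfn))[["spei"]]
  dfo <- dfn; dfo$log_ba[5] <- dfo$log_ba[5] + 8
  shift_rob <- abs(fit_fire_model(dfo)$coef[["beta2"]] - b_clean)
  shift_ols <- abs(coef(lm(log_ba ~ spei, dfo))[["spei"]] - ols_clean)
  expect_lt(shift_rob, 0.2 * shift_ols)
})

test_that("the IRLS core agrees with an independent bisquare implementation", {
  skip_if_not_installed("MASS")
  set.seed(9)
  for (k in 1:5) {
    x <- rnorm(30)
    y <- 1 + 0.5 * x + rt(30, df = 3) * 0.4
    ours <- fit_fire_model(tibble(year = 1:30, spei = x, log_ba = y))
    theirs <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685,
                        maxit = 100)
    expect_equal(unname(ours$coef[c("beta1", "beta2")]),
                 unname(coef(theirs)), tolerance = 1e-3)
  }
})

test_that("bootstrap replicates are shared-sequence, deterministic and anchored", {
  set.seed(10)
  n <- 20; R <- 3
  S <- matrix(rnorm(n * R), n, dimnames = list(NULL, sprintf("R%02d", 1:R)))
  Y <- -S + matrix(rnorm(n * R, 0, 0.3), n)
  colnames(Y) <- colnames(S)
  # identity resample reproduces the point fit exactly
  idx <- matrix(seq_len(n), ncol = 1)
  cube <- medfire:::cpp_bootstrap_irls(Y, S, rep(0, n), rep(FALSE, R), idx)
  for (r in 1:R) {
    point <- fit_fire_model(tibble(year = 1:n, spei = S[, r], log_ba = Y[, r]))
    expect_equal(unname(cube[1, 1:2, r]),
                 unname(point$coef[c("beta1", "beta2")]), tolerance = 1e-7)
  }
  b1 <- bootstrap_fire_models(Y, S, include_trend = FALSE, years = 1:n,
                              B = 50, seed = 11)
  b2 <- bootstrap_fire_models(Y, S, include_trend = FALSE, years = 1:n,
                              B = 50, seed = 11)
  expect_identical(b1, b2)
  expect_equal(nrow(b1), 50 * R)
  expect_true(all(is.finite(b1$beta2)))
})

test_that("leave-one-out skill is exact for linear data and honest for noise", {
  spei <- rnorm(20)
  df <- tibble(year = 1:20, spei = spei, log_ba = 1.5 - 0.8 * spei)
  expect_equal(loocv_skill(df), 1, tolerance = 1e-8)
  # optimism: cross-validated skill does not beat in-sample skill on average
  set.seed(12)
  delta <- replicate(25, {
    d <- tibble(year = 1:20, spei = rnorm(20),
                log_ba = -0.5 * spei + rnorm(20, 0, 1))
    f <- fit_fire_model(d)
    cor(d$log_ba, f$fitted) - loocv_skill(d)
  })
  expect_gt(mean(delta), 0)
  expect_error(loocv_skill(tibble(year = 1:3, spei = 1:3, log_ba = 1:3)),
               class = "medfire_insufficient_data")
})

test_that("end-to-end calibration recovers the planted model on one world", {
  w <- small_world(n_regions = 12, seed = 120)
  fits <- calibrate_fire_models(w$ba, w$climate, B = 500, seed = 121)
  expect_s3_class(fits, "fire_model_set")
  expect_true(all(fits$modelled))
  expect_true(all(fits$sc == 3 & fits$m == 8))
  expect_true(all(fits$beta2 < 0))
  cmp <- fits %>% inner_join(w$truth$coefs, by = "region",
                             suffix = c("", "_true"))
  expect_lt(max(abs(cmp$beta2 - cmp$beta2_true)), 0.35)
  reps <- attr(fits, "replicates")
  expect_equal(sort(unique(reps$replicate)), 1:500)
  td <- tidy(fits)
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  g <- glance(fits)
  expect_gt(g$mean_cv, 0.7)
  expect_lte(g$mean_cv, g$mean_r)
  # the planted warm-regions-less-sensitive pattern survives estimation
  expect_gt(cor(cmp$beta2, cmp$ty), 0)
})
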