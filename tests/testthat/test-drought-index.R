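test_that("extraterrestrial radiation matches a day-by-day FAO-56 summation", {
  # independent oracle: average the daily formula over every day of the month
  ra_daily_mean <- function(lat, month) {
    days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
    doy0 <- cumsum(c(0, days))[month]
    phi <- lat * pi / 180
    mean(vapply(seq_len(days[month]), function(dd) {
      j <- doy0 + dd
      dr <- 1 + 0.033 * cos(2 * pi * j / 365)
      delta <- 0.409 * sin(2 * pi * j / 365 - 1.39)
      ws <- acos(pmin(pmax(-tan(phi) * tan(delta), -1), 1))
      (24 * 60 / pi) * 0.0820 * dr *
        (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
    }, numeric(1)))
  }
  for (case in list(c(0, 3), c(40, 7), c(-35, 1), c(60, 6))) {
    expect_equal(extraterrestrial_radiation(case[1], case[2]),
                 ra_daily_mean(case[1], case[2]), tolerance = 0.01)
  }
})

test_that("extraterrestrial radiation has hemispheric seasonality and symmetry", {
  expect_gt(extraterrestrial_radiation(40, 6), extraterrestrial_radiation(40, 12))
  # mirrored latitude/season agree up to the Earth-Sun distance factor
  expect_equal(extraterrestrial_radiation(-40, 6),
               extraterrestrial_radiation(40, 12), tolerance = 0.07)
  expect_error(extraterrestrial_radiation(70, 6),
               class = "medfire_unsupported_domain")
})

test_that("modified Hargreaves PET matches an independent transcription", {
  # Droogers-Allen monthly form, re-transcribed from scratch
  tm <- 20; dtr <- 10; pre <- 50; lat <- 40; mon <- 7
  ra <- extraterrestrial_radiation(lat, mon)
  expected <- 0.0013 * 0.408 * ra * (tm + 17) * (dtr - 0.0123 * pre)^0.76 * 31
  expect_equal(hargreaves_pet(tm, dtr, lat, mon, pre = pre), expected,
               tolerance = 1e-9)
  # classic variant zeroes out at the formula offset temperature
  expect_identical(hargreaves_pet(-17.8, 10, 40, 7, variant = "classic"), 0)
  # monotone in temperature
  pets <- hargreaves_pet(seq(0, 30, by = 5), 10, 40, 7, pre = 50)
  expect_true(all(diff(pets) > 0))
  expect_error(hargreaves_pet(20, 10, 40, 7, pre = -1),
               class = "medfire_invalid_argument")
})

test_that("water-balance accumulation sums the sc months ending at the anchor", {
  clim <- toy_climate(n_regions = 2, years = 2000:2003)
  clim$pre <- seq_len(nrow(clim)) # distinct values to track sums
  clim <- clim %>% mutate(pet = 0.5 * pre)
  d <- accumulate_balance(clim, 3, months = 8)
  # oracle: Jun + Jul + Aug of the same year, per region
  oracle <- clim %>%
    filter(month %in% 6:8) %>%
    group_by(region, year) %>%
    summarise(d = sum(pre - pet), .groups = "drop")
  expect_equal(d %>% arrange(region, year) %>% select(region, year, d),
               oracle %>% arrange(region, year), ignore_attr = TRUE)

  # pre == pet gives identically zero balance
  clim0 <- toy_climate() %>% mutate(pet = pre)
  expect_true(all(abs(accumulate_balance(clim0, 6)$d) < 1e-12))

  # sc = 12 equals a brute-force rolling sum crossing year boundaries
  clim2 <- toy_climate(n_regions = 1, years = 2000:2004) %>%
    mutate(pre = rnorm(n(), 60, 10), pet = rnorm(n(), 40, 5))
  d12 <- accumulate_balance(clim2, 12, months = 5)
  wb <- clim2$pre - clim2$pet
  brute <- vapply(seq_along(wb), function(i) {
    if (i < 12) NA_real_ else sum(wb[(i - 11):i])
  }, numeric(1))
  idx <- which(clim2$month == 5 & !is.na(brute))
  expect_equal(d12$d, brute[idx])

  expect_error(accumulate_balance(toy_climate(years = 2000) %>%
                                    mutate(pet = 1) %>% slice(1:2), 3),
               class = "medfire_insufficient_data")
})

test_that("log-logistic PWM fitting recovers known parameters", {
  set.seed(1)
  true <- c(shape = -0.3, scale = 40, location = -200)
  x <- r_glo(1e4, true[1], true[2], true[3])
  d <- tibble(region = "R01", year = seq_along(x), month = 8L, d = x)
  p <- fit_spei_params(d, reference_period = c(1, 1e4), min_n = 20)
  expect_equal(p$shape, true[["shape"]], tolerance = 0.05)
  expect_equal(p$scale, true[["scale"]], tolerance = 0.05)
  expect_equal(p$location, true[["location"]], tolerance = 0.05)

  # refit on identical input is identical
  p2 <- fit_spei_params(d, reference_period = c(1, 1e4))
  expect_identical(p$shape, p2$shape)

  # guards: short reference window, degenerate sample
  expect_error(fit_spei_params(d[1:10, ], reference_period = c(1, 10)),
               class = "medfire_insufficient_data")
  dd <- d[1:30, ]; dd$d <- 5
  expect_error(fit_spei_params(dd, reference_period = c(1, 30)),
               class = "medfire_degenerate_distribution")
})

test_that("SPEI standardization is centred, monotone and quantile-consistent", {
  set.seed(2)
  n <- 3000
  x <- r_glo(n, -0.2, 30, -250) # from the fitted family itself
  d <- tibble(region = "R01", year = seq_len(n), month = 8L, d = x)
  params <- fit_spei_params(d, reference_period = c(1, n))
  sp <- compute_spei(d, params)

  # the fitted median maps to SPEI = 0
  med <- medfire:::qloglogistic(0.5, params$shape, params$scale, params$location)
  d_med <- tibble(region = "R01", year = 1L, month = 8L, d = med)
  expect_equal(compute_spei(d_med, params)$spei, 0, tolerance = 1e-10)

  # strictly increasing in D wherever the cap does not bind, non-decreasing
  # overall
  grid <- tibble(region = "R01", year = seq_len(50), month = 8L,
                 d = seq(min(x), max(x), length.out = 50))
  gsp <- compute_spei(grid, params)
  expect_true(all(diff(gsp$spei) >= 0))
  expect_true(all(diff(gsp$spei[!gsp$clamped]) > 0))

  # agreement with the empirical-quantile oracle between the 5th-95th pct
  qs <- quantile(x, c(0.05, 0.95))
  inner <- x > qs[1] & x < qs[2]
  emp <- qnorm((rank(x) - 0.5) / n)
  expect_lt(max(abs(sp$spei[inner] - emp[inner])), 0.05)

  # out-of-support values clamp to the cap with a flag
  lo <- tibble(region = "R01", year = 1L, month = 8L, d = min(x) - 1e4)
  out <- compute_spei(lo, params, cap = 3)
  expect_equal(out$spei, -3)
  expect_true(out$clamped)
})

test_that("reference-fitted parameters applied to a drying future shift SPEI negative", {
  cfg <- climate_config(drying_trend = -0.04, warming_trend = 0.3)
  clim <- simulate_climate(6, 1950, 2099, seed = 31, config = cfg)
  sp <- spei_panel(clim, 3, 8, reference_period = c(1971, 2000))
  fut <- sp %>% filter(year >= 2070) %>% group_by(region) %>%
    summarise(m = mean(spei))
  expect_true(all(fut$m < 0)) # sign test across regions
})

test_that("mismatched SPEI parameters are rejected", {
  d <- tibble(region = "R01", year = 1:30, month = 8L, d = rnorm(30))
  params <- fit_spei_params(d, reference_period = c(1, 30))
  d2 <- d; d2$region <- "R99"
  expect_error(compute_spei(d2, params), class = "medfire_mismatch")
})
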