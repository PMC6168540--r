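flat_gts <- function(rate = 0, base = 13.8, noise = 0) {
  tibble(year = 1881:2099,
         tglob = base + rate * pmax(1881:2099 - 1960, 0))
}

test_that("warming-window search matches the closed form on a linear ramp", {
  rate <- 0.05
  ww <- find_warming_window(flat_gts(rate), 2)
  # 30-yr mean anomaly = rate * (start + 14.5 - 1960) >= level
  expect_true(ww$reached)
  expect_equal(ww$start_year, ceiling(1960 + 2 / rate - 14.5))
  expect_equal(ww$end_year - ww$start_year + 1, 30)
  # flat series: not reached, signalled without error
  ww0 <- find_warming_window(flat_gts(0), 1.5)
  expect_false(ww0$reached)
  expect_true(is.na(ww0$start_year))
  # earliest qualifying window wins
  gts <- flat_gts(0.1)
  w3 <- find_warming_window(gts, 1)
  expect_true(all(find_warming_window(gts, 1)$start_year <=
                    find_warming_window(gts, 2)$start_year))
  expect_equal(w3$start_year,
               min(which(sapply(1910:2070, function(s) {
                 mean(gts$tglob[gts$year %in% s:(s + 29)]) -
                   mean(gts$tglob[gts$year %in% 1881:1910] ) >= 1
               })) + 1910 - 1))
  expect_error(find_warming_window(gts[gts$year > 1900, ], 1.5),
               class = "medfire_invalid_argument")
})

test_that("stationary-model changes follow the exponential closed form", {
  set.seed(1)
  spei_ref <- tibble(region = "R01", year = 1971:2000, spei = rnorm(30))
  fits <- tibble(region = "R01", beta1 = 5, beta2 = -1)
  # identical windows: zero change
  expect_equal(project_sm(fits, spei_ref, spei_ref)$change, 0)
  # constant shift dSPEI = -0.5 with beta2 = -1: 100*(e^{0.5}-1)
  spei_fut <- spei_ref %>% mutate(spei = spei - 0.5)
  expect_equal(project_sm(fits, spei_fut, spei_ref)$change,
               100 * (exp(0.5) - 1), tolerance = 1e-6)
  # insensitive regions never change
  fits0 <- fits %>% mutate(beta2 = 0)
  expect_equal(project_sm(fits0, spei_fut, spei_ref)$change, 0)
  expect_error(project_sm(fits, spei_fut[0, ], spei_ref),
               class = "medfire_invalid_argument")
})

test_that("degenerate non-stationarity collapses onto the stationary model", {
  set.seed(2)
  regs <- sprintf("R%02d", 1:5)
  spei_ref <- expand_grid(region = regs, year = 1971:2000) %>%
    mutate(spei = rnorm(n()))
  spei_fut <- spei_ref %>% mutate(spei = spei - 0.8)
  fits <- tibble(region = regs, beta1 = 5, beta2 = runif(5, -1.5, -0.5))
  bm <- structure(list(covariate = "Ty", gamma1 = -0.9, gamma2 = 0),
                  class = "beta2_model")
  x <- tibble(region = regs, Ty = runif(5, 10, 20))
  nsm <- project_nsm(fits, bm, x, spei_fut, spei_ref,
                     x_reference = x, mode = "both_sides")
  sm_equiv <- project_sm(fits %>% mutate(beta2 = -0.9), spei_fut, spei_ref)
  expect_equal(nsm$change, sm_equiv$change, tolerance = 1e-10)
  expect_error(project_nsm(fits, bm, tibble(region = regs, Ts = 1),
                           spei_fut, spei_ref),
               class = "medfire_invalid_argument")
})

test_that("warming damps the non-stationary response relative to the stationary one", {
  set.seed(3)
  regs <- sprintf("R%02d", 1:8)
  spei_ref <- expand_grid(region = regs, year = 1971:2000) %>%
    mutate(spei = rnorm(n()))
  ty_hist <- seq(8, 17, length.out = 8)
  gamma1 <- -1.62; gamma2 <- 0.057
  fits <- tibble(region = regs, beta1 = 5, beta2 = gamma1 + gamma2 * ty_hist)
  bm <- structure(list(covariate = "Ty", gamma1 = gamma1, gamma2 = gamma2),
                  class = "beta2_model")
  for (dd in c(0.4, 0.8, 1.2)) {
    spei_fut <- spei_ref %>% mutate(spei = spei - dd)
    x_fut <- tibble(region = regs, Ty = ty_hist + 3.5)
    sm <- project_sm(fits, spei_fut, spei_ref)
    nsm <- project_nsm(fits, bm, x_fut, spei_fut, spei_ref)
    expect_true(all(nsm$change <= sm$change + 1e-9))
    # warmed covariate weakens the drought sensitivity
    expect_true(all(abs(nsm$beta2_future) < abs(fits$beta2)))
  }
})

test_that("a world generated under the non-stationary law is tracked by NSM, overshot by SM", {
  # plant the future under beta2(Ty_future); compare predicted BA ratios
  set.seed(4)
  regs <- sprintf("R%02d", 1:6)
  ty_hist <- seq(9, 16, length.out = 6); d_ty <- 4
  gamma1 <- -1.62; gamma2 <- 0.057
  b2_hist <- gamma1 + gamma2 * ty_hist
  b2_fut <- gamma1 + gamma2 * (ty_hist + d_ty)
  spei_ref <- expand_grid(region = regs, year = 1971:2000) %>%
    mutate(spei = rnorm(n()))
  spei_fut <- spei_ref %>% mutate(spei = spei - 1)
  sr <- split(spei_ref$spei, spei_ref$region)
  sf <- split(spei_fut$spei, spei_fut$region)
  true_change <- vapply(seq_along(regs), function(i) {
    100 * (mean(exp(b2_fut[i] * sf[[i]])) / mean(exp(b2_hist[i] * sr[[i]])) - 1)
  }, numeric(1))
  fits <- tibble(region = regs, beta1 = 5, beta2 = b2_hist)
  bm <- structure(list(covariate = "Ty", gamma1 = gamma1, gamma2 = gamma2),
                  class = "beta2_model")
  nsm <- project_nsm(fits, bm, tibble(region = regs, Ty = ty_hist + d_ty),
                     spei_fut, spei_ref)
  sm <- project_sm(fits, spei_fut, spei_ref)
  expect_equal(nsm$change, true_change, tolerance = 1e-10)
  expect_true(all(sm$change > true_change))
})

test_that("extrapolation policies pass through, exclude, or clip", {
  regs <- c("R01", "R02", "R03")
  x_fut <- tibble(region = regs, Ty = c(12, 15, 21))
  spei_fut <- expand_grid(region = regs, year = 2061:2090) %>%
    mutate(spei = rep(c(-3, -1, -2.5), each = 30))
  hist <- list(x_range = c(8, 18),
               spei_range = tibble(region = regs, spei_min = c(-2, -2, -2),
                                   spei_max = c(2, 2, 2)))
  # all within range: the three policies coincide
  x_in <- x_fut %>% mutate(Ty = c(12, 15, 17))
  s_in <- spei_fut %>% mutate(spei = pmax(spei, -1.5))
  for (pol in c("extrapolate", "exclude", "constrain")) {
    adj <- apply_extrapolation_policy(x_in, s_in, hist, pol, covariate = "Ty")
    expect_equal(adj$x_future$Ty, x_in$Ty)
    expect_equal(adj$spei_future$spei, s_in$spei)
  }
  # exclusion drops exactly the out-of-range region
  adj <- apply_extrapolation_policy(x_fut, spei_fut, hist, "exclude",
                                    covariate = "Ty")
  expect_setequal(adj$kept_regions, c("R01", "R02"))
  expect_false("R03" %in% adj$spei_future$region)
  # constraining clips to historical extremes (brute-force scan)
  adj2 <- apply_extrapolation_policy(x_fut, spei_fut, hist, "constrain",
                                     covariate = "Ty")
  expect_true(all(adj2$x_future$Ty <= 18 & adj2$x_future$Ty >= 8))
  expect_true(all(adj2$spei_future$spei >= -2))
  expect_equal(max(abs(adj2$spei_future$spei -
                         pmin(pmax(spei_fut$spei, -2), 2))), 0)
})

test_that("constrained projections never exceed extrapolated ones", {
  set.seed(7)
  regs <- sprintf("R%02d", 1:5)
  spei_ref <- expand_grid(region = regs, year = 1971:2000) %>%
    mutate(spei = rnorm(n()))
  spei_fut <- spei_ref %>% mutate(spei = spei - 2.5) # deep drying
  fits <- tibble(region = regs, beta1 = 5,
                 beta2 = seq(-1.2, -0.6, length.out = 5))
  hist <- list(x_range = c(8, 18),
               spei_range = spei_ref %>% group_by(region) %>%
                 summarise(spei_min = min(spei), spei_max = max(spei)))
  x_fut <- tibble(region = regs, Ty = 15)
  adj <- apply_extrapolation_policy(x_fut, spei_fut, hist, "constrain",
                                    covariate = "Ty")
  ch_con <- project_sm(fits, adj$spei_future, spei_ref)
  ch_ext <- project_sm(fits, spei_fut, spei_ref)
  expect_true(all(ch_con$change <= ch_ext$change))
})

test_that("ensemble summaries match a brute-force percentile oracle", {
  one <- tibble(member = "m1", replicate = 0L, region = "R01", change = 42)
  s <- ensemble_summary(one, mode = "rcm")
  expect_true(all(unlist(s[c("median", "q25", "q75", "q025", "q975")]) == 42))
  expect_error(ensemble_summary(one[0, ]), class = "medfire_invalid_argument")

  set.seed(5)
  ch <- expand_grid(member = sprintf("m%d", 1:4), replicate = 1:50,
                    region = c("R01", "R02")) %>%
    mutate(change = rnorm(n(), 50, 20))
  s2 <- ensemble_summary(ch, mode = "all")
  pooled <- ch %>% group_by(member, replicate) %>%
    summarise(x = mean(change), .groups = "drop") %>% pull(x)
  expect_equal(s2$median, unname(quantile(pooled, 0.5)))
  expect_equal(s2$q025, unname(quantile(pooled, 0.025)))
  expect_equal(s2$n_sim, 200)
  # weighted spatial average honoured
  w <- c(R01 = 1, R02 = 0)
  s3 <- ensemble_summary(ch, weights = w, mode = "all")
  pooled_w <- ch %>% filter(region == "R01") %>%
    group_by(member, replicate) %>% summarise(x = mean(change), .groups = "drop")
  expect_equal(s3$median, unname(quantile(pooled_w$x, 0.5)))
})

test_that("ensemble spread dominates bootstrap spread when constructed so", {
  set.seed(6)
  member_shift <- rnorm(9, 80, 40)
  ch <- expand_grid(member = sprintf("m%d", 1:9), replicate = 0:100,
                    region = "R01") %>%
    mutate(change = member_shift[as.integer(sub("m", "", member))] +
             ifelse(replicate == 0, 0, rnorm(n(), 0, 2)))
  iqr_rcm <- with(ensemble_summary(ch, mode = "rcm"), q75 - q25)
  iqr_all <- with(ensemble_summary(ch, mode = "all"), q75 - q25)
  expect_lt(abs(iqr_all - iqr_rcm) / iqr_rcm, 0.2)
})

test_that("region classification follows the stippling rule", {
  mk <- function(region, n_sig, n_pos, n = 100) {
    tibble(region = region,
           significant = c(rep(TRUE, n_sig), rep(FALSE, n - n_sig)),
           change = c(rep(1, n_pos), rep(-1, n - n_pos)))
  }
  out <- classify_regions(bind_rows(
    mk("A", 100, 100), # all significant, all increasing
    mk("B", 10, 90),   # hardly any significance
    mk("C", 60, 50)))  # significant but direction split
  expect_equal(out$class[out$region == "A"], "significant_agreeing")
  expect_equal(out$class[out$region == "B"], "small_change")
  expect_equal(out$class[out$region == "C"], "no_agreement")
})
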