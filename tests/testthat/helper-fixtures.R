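# Small programmatic fixtures shared across tests.

suppressPackageStartupMessages({
  library(dplyr)
  library(tidyr)
  library(tibble)
  library(purrr)
})

# a tiny hand-built monthly panel (one value per region/month/year)
toy_climate <- function(n_regions = 3, years = 1970:2005, tmean = 15,
                        dtr = 8, pre = 50, lat0 = 38) {
  grid <- expand_grid(ridx = seq_len(n_regions), year = years, month = 1:12)
  out <- tibble(
    region = sprintf("R%02d", grid$ridx),
    lat = lat0 + grid$ridx, lon = grid$ridx * 2,
    year = grid$year, month = grid$month,
    tmean = tmean, dtr = dtr, pre = pre)
  attr(out, "config") <- climate_config()
  out
}

# default-condition synthetic world used by several tests
small_world <- function(n_regions = 12, seed = 99, years = 1985:2011) {
  clim <- simulate_climate(n_regions, 1965, 2011, seed = seed)
  truth <- simulate_truth(clim, seed = seed + 1)
  ba <- simulate_burned_area(clim, truth, seed = seed + 2) %>%
    filter(year %in% years)
  list(climate = clim, truth = truth, ba = ba)
}

# sample from the generalized-logistic family used for SPEI standardization
r_glo <- function(n, shape, scale, location) {
  u <- runif(n)
  if (abs(shape) < 1e-8) return(location + scale * log(u / (1 - u)))
  location + scale * (1 - ((1 - u) / u)^shape) / shape
}
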