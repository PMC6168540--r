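#' @importFrom rlang .data abort warn
#' @importFrom stats qnorm quantile rnorm rgamma runif sd cor median coef
#'   lm pnorm p.adjust setNames complete.cases wilcox.test
#' @importFrom dplyr %>%
#' @useDynLib medfire, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# number of days per calendar month (fixed 365-day convention, no leap years)
DAYS_IN_MONTH <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

# summer season used throughout: June-September (JJAS)
SUMMER_MONTHS <- 6:9

stop_medfire <- function(msg, class) {
  abort(msg, class = c(class, "medfire_error"))
}

check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_medfire(
      sprintf("%s is missing required column(s): %s",
              what, paste(missing, collapse = ", ")),
      "medfire_invalid_argument"
    )
  }
  invisible(df)
}

check_window <- function(window, what = "window") {
  if (length(window) != 2 || !is.numeric(window) || window[2] < window[1]) {
    stop_medfire(sprintf("%s must be c(start_year, end_year)", what),
                 "medfire_invalid_argument")
  }
  invisible(window)
}

#' Derive a stage-specific sub-seed from a master seed
#'
#' Keeps every derived seed a valid 32-bit integer so that seeded stages stay
#' reproducible from a single master seed.
#'
#' @param seed master seed (integer) or `NULL`.
#' @param offset stage offset.
#' @return An integer seed, or `NULL` when `seed` is `NULL`.
#' @export
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483629)
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# long (region, year, value) -> years x regions matrix, common years only
panel_to_matrix <- function(df, value_col) {
  wide <- df %>%
    dplyr::select("region", "year", dplyr::all_of(value_col)) %>%
    tidyr::pivot_wider(names_from = "region",
                       values_from = dplyr::all_of(value_col)) %>%
    dplyr::arrange(.data$year)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$year
  m
}
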