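# Time-series characterisation of annual density series: log transform,
# amplitude, autocorrelation-based cycle length with a white-noise
# confidence band, and second-order autoregressive density dependence.

#' Natural-log transform of a density series
#'
#' Density series containing zeros (extinction replicates) cannot be
#' logged directly; with `zero_offset = TRUE` the series is offset by its
#' smallest positive value before the transform and the result carries a
#' `flagged` attribute.
#'
#' @param x Numeric vector of densities (>= 0).
#' @param zero_offset Handle zeros by offsetting (default errors on
#'   zeros).
#' @return `log(x)` (possibly offset); attribute `flagged` is `TRUE` when
#'   an offset was applied.
#' @export
log_density <- function(x, zero_offset = FALSE) {
  stopifnot(is.numeric(x), length(x) > 0, all(x >= 0))
  flagged <- FALSE
  if (any(x == 0)) {
    if (!zero_offset) {
      abort("Series contains zeros; use `zero_offset = TRUE` (extinction replicate).")
    }
    pos <- x[x > 0]
    if (length(pos) == 0) {
      abort("Series is all zeros; nothing to analyse.")
    }
    x <- x + min(pos)
    flagged <- TRUE
  }
  structure(log(x), flagged = flagged)
}

#' Cycle amplitude: maximum over minimum population size
#'
#' @param x Numeric density series (non-empty, >= 0).
#' @return `max(x) / min(x)` (>= 1); `Inf` when the minimum is zero (an
#'   extinction replicate, flagged downstream).
#' @examples
#' amplitude(c(10, 20, 5)) # 4
#' @export
amplitude <- function(x) {
  stopifnot(is.numeric(x), length(x) > 0, all(x >= 0))
  if (min(x) == 0) {
    return(Inf)
  }
  max(x) / min(x)
}

#' Autocorrelation function values
#'
#' Standard biased (1/n) autocovariance estimator normalised by lag 0, as
#' produced by `acf()`; returned as a plain numeric vector indexed by lag
#' 0..`max_lag`.
#'
#' @param x Numeric series.
#' @param max_lag Largest lag; default `min(floor(n/4), 25)`.
#' @return Numeric vector of length `max_lag + 1`; element 1 is lag 0
#'   (exactly 1).
#' @export
acf_values <- function(x, max_lag = NULL) {
  n <- length(x)
  if (is.null(max_lag)) max_lag <- min(floor(n / 4), 25L)
  stopifnot(n >= 2, max_lag >= 1, max_lag < n)
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)
  as.numeric(a$acf)
}

#' Half-width of the white-noise confidence band for an ACF
#'
#' `z_(1-alpha/2) / sqrt(n)`: an ACF value beyond this band differs
#' significantly from zero at level `alpha` under the white-noise null.
#'
#' @param n Sample size (series length).
#' @param alpha Significance level.
#' @return The band half-width.
#' @examples
#' ci_halfwidth(100) # 0.196
#' @export
ci_halfwidth <- function(n, alpha = 0.05) {
  stopifnot(n > 0, alpha > 0, alpha < 1)
  qnorm(1 - alpha / 2) / sqrt(n)
}

#' Cycle length from the autocorrelation function
#'
#' The cycle length is the lag of the second positive significant ACF
#' maximum, counting the lag-0 peak as the first: i.e. the smallest lag
#' `L >= 2` at which the ACF has a local maximum exceeding the
#' white-noise band. To qualify as a stable periodicity a further
#' positive significant local maximum must occur within one lag of `2L`
#' (the cycle's second harmonic); irregular fluctuations therefore return
#' 0, as does a series whose ACF never rises above the band. A local
#' maximum is strictly greater than both neighbours (plateau ties broken
#' toward the smaller lag).
#'
#' @param x Numeric series (length >= 20; annual log densities in the
#'   study design).
#' @param alpha Significance level of the band.
#' @param max_lag Largest lag examined; default `min(floor(n/4), 25)`.
#'   When `2L + 1` exceeds `max_lag` the harmonic cannot be verified and
#'   0 is returned (no stable periodicity demonstrable).
#' @return Integer cycle length in time steps (years); 0 when no stable
#'   periodicity exists.
#' @export
cycle_length <- function(x, alpha = 0.05, max_lag = NULL) {
  n <- length(x)
  if (n < 20) {
    abort("Series too short for cycle detection (need >= 20 points).")
  }
  if (is.null(max_lag)) max_lag <- min(floor(n / 4), 25L)
  r <- acf_values(x, max_lag)
  ci <- ci_halfwidth(n, alpha)
  # local maxima over lags 1..max_lag-1 (r index is lag + 1)
  is_max <- function(lag) {
    r[lag + 1] > r[lag] && r[lag + 1] >= r[lag + 2]
  }
  peaks <- integer()
  for (lag in seq_len(max_lag - 1)) {
    if (is_max(lag)) peaks <- c(peaks, lag)
  }
  sig <- peaks[peaks >= 2 & r[peaks + 1] > ci]
  if (length(sig) == 0) {
    return(0L)
  }
  L <- sig[1]
  harmonic <- any(abs(sig - 2L * L) <= 1L & sig != L)
  if (harmonic) as.integer(L) else 0L
}

#' Second-order autoregressive density dependence
#'
#' Ordinary least-squares fit of \eqn{x_t = a_0 + \phi_1 x_{t-1} +
#' \phi_2 x_{t-2} + \epsilon_t} on a log-density series. The lag-1 slope
#' measures direct density dependence (AR1) and the lag-2 slope delayed
#' density dependence (AR2); strongly negative AR2 is the signature of
#' multiannual cycles driven by lagged feedback such as specialist
#' predation. `convention = "royama"` instead reports the direct
#' coefficient on the growth-rate scale, `phi1 - 1`.
#'
#' @param x Numeric series, typically log densities (length >= 10,
#'   positive variance).
#' @param convention `"slope"` (raw regression slopes, default) or
#'   `"royama"`.
#' @return Object of class `ar2_fit`: list with `ar1`, `ar2`,
#'   `intercept`, `sigma2` (residual variance), `n_obs`, `convention`
#'   and the underlying `lm` fit. Has [tidy()] and [glance()] methods.
#' @examples
#' x <- as.numeric(arima.sim(list(ar = c(0.3, -0.5)), 200))
#' fit_ar2(x)$ar2
#' @export
fit_ar2 <- function(x, convention = c("slope", "royama")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(x))
  if (length(x) < 10) {
    abort("Series too short for an AR(2) fit (need >= 10 points).")
  }
  if (!is.finite(var(x)) || var(x) == 0) {
    abort("Series has zero variance; AR(2) coefficients are undefined.")
  }
  e <- embed(as.numeric(x), 3) # columns: x_t, x_{t-1}, x_{t-2}
  d <- data.frame(xt = e[, 1], x1 = e[, 2], x2 = e[, 3])
  fit <- lm(xt ~ x1 + x2, data = d)
  cf <- coef(fit)
  ar1 <- unname(cf["x1"])
  structure(
    list(
      ar1 = if (convention == "royama") ar1 - 1 else ar1,
      ar2 = unname(cf["x2"]),
      intercept = unname(cf["(Intercept)"]),
      sigma2 = sum(fit$residuals^2) / fit$df.residual,
      n_obs = nrow(d),
      convention = convention,
      fit = fit
    ),
    class = "ar2_fit"
  )
}

#' @export
print.ar2_fit <- function(x, ...) {
  cat(sprintf(
    "<ar2_fit> AR1 = %.3f, AR2 = %.3f (%s convention), n = %d, sigma2 = %.4f\n",
    x$ar1, x$ar2, x$convention, x$n_obs, x$sigma2
  ))
  invisible(x)
}

#' Characterise a density series: all endpoints at once
#'
#' Applies the full analysis to one replicate's annual density series:
#' mean population size (and its natural log), amplitude, ACF cycle
#' length, and the AR(2) density-dependence coefficients of the logged
#' series. Extinction replicates (zeros present) are analysed on the
#' offset series and flagged; their amplitude is reported as infinite.
#'
#' @param x Numeric vector of annual densities.
#' @param alpha Significance level for the cycle-detection band.
#' @param max_lag Passed to [cycle_length()].
#' @param mean_of_logs If `TRUE` report `mean(log(x))` instead of
#'   `log(mean(x))` as the log population size.
#' @return One-row tibble: `mean_n`, `log_mean_n`, `amplitude`,
#'   `cycle_length`, `ar1`, `ar2`, `flagged`.
#' @export
series_endpoints <- function(x, alpha = 0.05, max_lag = NULL,
                             mean_of_logs = FALSE) {
  stopifnot(is.numeric(x), length(x) > 0, all(x >= 0))
  amp <- amplitude(x)
  lx <- log_density(x, zero_offset = TRUE)
  flagged <- isTRUE(attr(lx, "flagged"))
  cl <- cycle_length(as.numeric(lx), alpha = alpha, max_lag = max_lag)
  dd <- if (var(as.numeric(lx)) > 0) {
    fit_ar2(as.numeric(lx))
  } else {
    list(ar1 = NA_real_, ar2 = NA_real_)
  }
  tibble(
    mean_n = mean(x),
    log_mean_n = if (mean_of_logs) mean(as.numeric(lx)) else log(mean(x)),
    amplitude = amp,
    cycle_length = cl,
    ar1 = dd$ar1,
    ar2 = dd$ar2,
    flagged = flagged
  )
}

#' Per-replicate endpoints from a census table
#'
#' Tidy pipeline entry: groups an annual census table and computes the
#' five endpoints for each group's density series (ordered by `year`).
#'
#' @param data Data frame with at least `year`, a density column and the
#'   grouping columns.
#' @param density Column holding the annual density (tidy-eval).
#' @param ... Grouping columns (tidy-eval), e.g. `replicate` or
#'   `scenario, replicate`.
#' @param alpha,max_lag,mean_of_logs Passed to [series_endpoints()].
#' @return Tibble with one row per group: grouping columns plus the
#'   endpoint columns.
#' @examples
#' \donttest{
#' cfg <- scenario_config("specialist", burn_in_years = 10,
#'                        sample_years = 25, replicates = 2)
#' run_scenario(cfg) |>
#'   as_tibble() |>
#'   vole_endpoints(density_optimal_ha, replicate)
#' }
#' @export
vole_endpoints <- function(data, density, ..., alpha = 0.05,
                           max_lag = NULL, mean_of_logs = FALSE) {
  dens <- enquo(density)
  data %>%
    arrange(.data$year) %>%
    group_by(...) %>%
    summarise(
      series_endpoints(!!dens,
        alpha = alpha, max_lag = max_lag,
        mean_of_logs = mean_of_logs
      ),
      .groups = "drop"
    )
}
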