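# Synthetic annual-density generators with the statistical structure the
# analysis stage assumes, so every analysis operation is testable without
# running the simulator. Latent processes are generated on the log scale
# and exponentiated, so the analysis pipeline's log transform is
# exercised end to end.

#' Generate an AR(2) density series
#'
#' Latent process \eqn{x_t = c + \phi_1 x_{t-1} + \phi_2 x_{t-2} +
#' N(0, \sigma^2)}, exponentiated to positive densities. Parameters must
#' lie inside the stationarity triangle (`phi2 > -1`, `phi2 + phi1 < 1`,
#' `phi2 - phi1 < 1`). With complex characteristic roots the process is
#' quasi-periodic with period `2*pi / acos(phi1 / (2*sqrt(-phi2)))`.
#'
#' @param n Series length (years).
#' @param ar1,ar2 Autoregressive coefficients.
#' @param sigma Innovation standard deviation (log scale).
#' @param intercept Latent intercept `c`.
#' @param seed Integer seed (deterministic output per seed).
#' @param burn Burn-in steps discarded before sampling.
#' @return Tibble with `year` and `density`; the latent log series is
#'   attached as attribute `latent`.
#' @export
gen_ar2 <- function(n, ar1 = 0, ar2 = 0, sigma = 0.3, intercept = 0,
                    seed = 1, burn = 100) {
  stopifnot(n >= 1, sigma >= 0)
  if (ar2 <= -1 || ar2 + ar1 >= 1 || ar2 - ar1 >= 1) {
    abort("(ar1, ar2) must lie inside the AR(2) stationarity triangle.")
  }
  set.seed(seed)
  total <- n + burn
  e <- rnorm(total, 0, sigma)
  x <- numeric(total)
  x[1] <- intercept + e[1]
  x[2] <- intercept + ar1 * x[1] + e[2]
  for (t in 3:total) {
    x[t] <- intercept + ar1 * x[t - 1] + ar2 * x[t - 2] + e[t]
  }
  latent <- x[(burn + 1):total]
  structure(
    tibble(year = seq_len(n), density = exp(latent)),
    latent = latent
  )
}

#' Generate a noisy periodic density series
#'
#' Latent sinusoid of the given period plus Gaussian noise at a given
#' signal-to-noise ratio (amplitude of the sinusoid over the noise
#' standard deviation), exponentiated. `snr = Inf` gives a noiseless
#' cycle; the amplitude of the noiseless density series is
#' `exp(2 * amp)` (max/min of `exp(amp * sin)`).
#'
#' @param n Series length.
#' @param period Cycle period (time steps).
#' @param snr Signal-to-noise ratio (>= 0; `Inf` = noiseless).
#' @param amp Sinusoid amplitude on the log scale.
#' @param seed Integer seed.
#' @return Tibble with `year` and `density`; latent log series attached
#'   as attribute `latent`.
#' @export
gen_periodic <- function(n, period = 4, snr = 4, amp = 1, seed = 1) {
  stopifnot(n >= 1, period > 1, snr >= 0, amp > 0)
  set.seed(seed)
  t <- seq_len(n)
  signal <- amp * sin(2 * pi * t / period)
  noise <- if (is.infinite(snr)) {
    numeric(n)
  } else if (snr == 0) {
    rnorm(n, 0, amp) # pure noise at the signal's scale
  } else {
    rnorm(n, 0, amp / snr)
  }
  latent <- if (snr == 0) noise else signal + noise
  structure(
    tibble(year = t, density = exp(latent)),
    latent = latent
  )
}

#' Generate a white-noise density series
#'
#' @param n Series length.
#' @param sigma Log-scale standard deviation.
#' @param seed Integer seed.
#' @return Tibble with `year` and `density`.
#' @export
gen_white <- function(n, sigma = 1, seed = 1) {
  gen_ar2(n, 0, 0, sigma = sigma, seed = seed)
}

#' Generate a density series with an extinction (zeros)
#'
#' A stationary AR(2) series whose final `zero_years` values are zero,
#' emulating a replicate that went extinct during sampling.
#'
#' @param n Series length.
#' @param zero_years Number of trailing zero years.
#' @param seed Integer seed.
#' @param ... Passed to [gen_ar2()].
#' @return Tibble with `year` and `density`.
#' @export
gen_extinction <- function(n, zero_years = 5, seed = 1, ...) {
  stopifnot(zero_years >= 1, zero_years < n)
  out <- gen_ar2(n, seed = seed, ...)
  out$density[(n - zero_years + 1):n] <- 0
  attr(out, "latent") <- NULL
  out
}

#' Generate a balanced factorial endpoint table
#'
#' Builds the 3 x 4 x 3 factorial layout of the simulation experiment
#' (predator assembly x fragmentation x breeding season) with a response
#' composed of user-specified main effects, an optional
#' landscape-by-predator interaction, and Gaussian noise — for validating
#' the ANOVA decomposition against known ground truth.
#'
#' @param land_effect,predator_effect,season_effect Main-effect sizes:
#'   the response gains `effect * (level index - 1)` for each factor.
#' @param lp_interaction Size of a land x predator interaction term.
#' @param sigma Noise standard deviation.
#' @param replicates Rows per cell (balanced).
#' @param seed Integer seed.
#' @return Tibble with factor columns `land`, `predators`, `season`,
#'   `replicate` and numeric `response`.
#' @export
gen_grid_fixture <- function(land_effect = 0, predator_effect = 0,
                             season_effect = 0, lp_interaction = 0,
                             sigma = 1, replicates = 20, seed = 1) {
  stopifnot(replicates >= 2, sigma >= 0)
  set.seed(seed)
  grid <- tidyr::expand_grid(
    land = factor(c(1, 9, 25, 100), levels = c(1, 9, 25, 100)),
    predators = factor(c("generalist", "specialist", "mixed"),
      levels = c("generalist", "specialist", "mixed")
    ),
    season = factor(c("short", "intermediate", "long"),
      levels = c("short", "intermediate", "long")
    ),
    replicate = seq_len(replicates)
  )
  li <- as.integer(grid$land) - 1
  pi_ <- as.integer(grid$predators) - 1
  si <- as.integer(grid$season) - 1
  grid$response <- land_effect * li + predator_effect * pi_ +
    season_effect * si + lp_interaction * li * pi_ +
    rnorm(nrow(grid), 0, sigma)
  grid
}
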