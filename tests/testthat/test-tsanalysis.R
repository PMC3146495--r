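# Analysis stack: log transform, amplitude, ACF, confidence band,
# cycle-length rule, AR(2) density dependence.

test_that("log_density transforms, rejects zeros, offsets when asked", {
  expect_equal(as.numeric(log_density(c(1, 1, 1))), c(0, 0, 0))
  expect_equal(as.numeric(log_density(exp(1))), 1)
  expect_error(log_density(c(1, 0, 2)), "zeros")
  off <- log_density(c(1, 0, 2), zero_offset = TRUE)
  expect_true(attr(off, "flagged"))
  expect_equal(as.numeric(off), log(c(1, 0, 2) + 1))
  expect_false(attr(log_density(c(1, 2)), "flagged"))
})

test_that("amplitude is max over min with extinction flagged as Inf", {
  expect_equal(amplitude(c(10, 20, 5)), 4)
  expect_equal(amplitude(rep(3, 7)), 1)
  expect_equal(amplitude(c(2, 8, 4, 16)), 8)
  expect_identical(amplitude(c(3, 0, 9)), Inf)
  # agreement with the obvious definition on random series
  set.seed(1)
  for (i in 1:20) {
    x <- exp(rnorm(50))
    expect_equal(amplitude(x), max(x) / min(x), tolerance = 1e-12)
  }
})

test_that("acf_values matches a brute-force reimplementation to 1e-12", {
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(80 + i)
    r <- acf_values(x, max_lag = 20)
    expect_equal(r, brute_acf(x, 20), tolerance = 1e-12)
    expect_equal(r[1], 1)
    expect_true(all(abs(r) <= 1 + 1e-12))
  }
})

test_that("white-noise ACF stays inside 3/sqrt(n) at all positive lags", {
  set.seed(11)
  x <- rnorm(1000)
  r <- acf_values(x, max_lag = 25)
  expect_true(all(abs(r[-1]) < 3 / sqrt(1000)))
})

test_that("periodic signals put ACF maxima at multiples of the period", {
  saw <- rep(c(0, 1, 2, 3), 25) # period-4 sawtooth
  r <- brute_acf(saw, 12)
  expect_equal(acf_values(saw, 12), r, tolerance = 1e-12)
  expect_true(r[5] > r[4] && r[5] > r[6]) # lag 4
  expect_true(r[9] > r[8] && r[9] > r[10]) # lag 8
})

test_that("ci_halfwidth is the white-noise band z/sqrt(n)", {
  expect_equal(ci_halfwidth(100, 0.05), 0.196, tolerance = 1e-3)
  expect_equal(ci_halfwidth(400, 0.05), 0.098, tolerance = 1e-3)
  expect_equal(ci_halfwidth(100, 0.05), qnorm(0.975) / 10, tolerance = 1e-12)
  expect_lt(ci_halfwidth(1e8, 0.05), 1e-3) # vanishes with n
})

test_that("cycle_length finds the period of a noisy cycle and rejects noise", {
  per <- gen_periodic(100, period = 4, snr = 4, seed = 5)
  expect_equal(cycle_length(log(per$density)), 4L)
  wn <- gen_white(100, seed = 6)
  expect_equal(cycle_length(log(wn$density)), 0L)
  # AR(1) decay has a monotone ACF: no interior maximum, no cycle
  set.seed(8)
  ar1 <- as.numeric(arima.sim(list(ar = 0.8), 100))
  expect_equal(cycle_length(ar1), 0L)
  expect_error(cycle_length(rnorm(10)), "short")
})

test_that("fit_ar2 recovers known coefficients", {
  d <- gen_ar2(1000, ar1 = 0.3, ar2 = -0.8, sigma = 0.5, seed = 3)
  f <- fit_ar2(attr(d, "latent"))
  expect_equal(f$ar1, 0.3, tolerance = 0.05)
  expect_equal(f$ar2, -0.8, tolerance = 0.05)
  expect_equal(f$n_obs, 998)
  # a process with no lag-2 term: fitted ar2 within its own 95% CI of 0
  d0 <- gen_ar2(500, ar1 = 0.5, ar2 = 0, sigma = 0.4, seed = 4)
  f0 <- fit_ar2(attr(d0, "latent"))
  se2 <- tidy(f0)$std.error[3]
  expect_lt(abs(f0$ar2), 1.96 * se2 + 0.05)
  expect_error(fit_ar2(rep(1, 50)), "variance")
  expect_error(fit_ar2(rnorm(5)), "short")
})

test_that("fit_ar2 conventions differ by 1 in the direct coefficient", {
  x <- attr(gen_ar2(200, 0.4, -0.3, seed = 9), "latent")
  a <- fit_ar2(x, convention = "slope")
  b <- fit_ar2(x, convention = "royama")
  expect_equal(a$ar1 - 1, b$ar1, tolerance = 1e-12)
  expect_equal(a$ar2, b$ar2, tolerance = 1e-12)
})

test_that("tidy and glance give the broom shape", {
  f <- fit_ar2(attr(gen_ar2(100, 0.3, -0.4, seed = 2), "latent"))
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(td$term, c("intercept", "ar1", "ar2"))
  gl <- glance(f)
  expect_equal(gl$n_obs, 98)
  expect_true(gl$r.squared >= 0 && gl$r.squared <= 1)
})

test_that("series_endpoints flags extinction replicates", {
  ext <- gen_extinction(60, zero_years = 5, seed = 10, ar1 = 0.3, ar2 = -0.3)
  ep <- series_endpoints(ext$density)
  expect_true(ep$flagged)
  expect_identical(ep$amplitude, Inf)
  ok <- series_endpoints(gen_ar2(60, 0.3, -0.3, seed = 10)$density)
  expect_false(ok$flagged)
  expect_true(is.finite(ok$ar2))
})

test_that("vole_endpoints groups and orders by year", {
  d1 <- gen_periodic(60, period = 4, snr = 8, seed = 1)
  d2 <- gen_white(60, seed = 2)
  d1$replicate <- 1L
  d2$replicate <- 2L
  both <- rbind(d1, d2)
  # shuffle rows: the pipeline must re-order by year within groups
  both <- both[sample(nrow(both)), ]
  ep <- vole_endpoints(both, density, replicate)
  expect_equal(nrow(ep), 2)
  expect_equal(ep$cycle_length[ep$replicate == 1], 4L)
  expect_equal(ep$cycle_length[ep$replicate == 2], 0L)
})
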