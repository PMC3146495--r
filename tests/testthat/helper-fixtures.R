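# Shared fixtures: a small fast landscape/config for engine unit tests.
# 600 x 600 m at 10 m cells, 4% habitat -> one 12 x 12-cell patch.

tiny_landscape <- function(n_patches = 1) {
  build_landscape(600, 600, 0.04, n_patches, cell_size_m = 10)
}

tiny_config <- function(assembly = "specialist", n_patches = 1,
                        season = "intermediate", master_seed = 42, ...) {
  scenario_config(
    assembly, n_patches, season,
    width_m = 600, height_m = 600, habitat_fraction = 0.04,
    cell_size_m = 10, burn_in_years = 2, sample_years = 5,
    replicates = 1, master_seed = master_seed, ...
  )
}

# brute-force autocorrelation: direct sum form of the biased estimator
brute_acf <- function(x, max_lag) {
  n <- length(x)
  xc <- x - mean(x)
  c0 <- sum(xc^2) / n
  vapply(0:max_lag, function(k) {
    sum(xc[seq_len(n - k)] * xc[seq_len(n - k) + k]) / n / c0
  }, numeric(1))
}
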