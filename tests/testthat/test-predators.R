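# Predator rules: hunting, dispersal, annual survival, reproduction.

test_that("hunting kills at the type's efficiency and tracks the streak", {
  land <- tiny_landscape()
  pred <- new_predator("specialist", 30, 30, cell_size_m = 10)
  # empty territory: no kills, streak increments
  empty <- data.frame(id = integer(), x = integer(), y = integer())
  h <- hunt(empty, pred)
  expect_length(h$killed, 0)
  expect_equal(h$predator$failure_streak, 1L)
  expect_equal(h$predator$kills_this_year, 0L)
  # 1000 voles in the territory for one day: kills within the binomial
  # 99% interval of the tabulated efficiencies
  set.seed(5)
  voles <- data.frame(id = 1:1000, x = rep(28:32, 200), y = rep(28:32, each = 200))
  hs <- hunt(voles, pred)
  expect_gte(length(hs$killed), qbinom(0.005, 1000, 0.095))
  expect_lte(length(hs$killed), qbinom(0.995, 1000, 0.095))
  expect_equal(hs$predator$failure_streak, 0L)
  expect_equal(nrow(hs$voles), 1000 - length(hs$killed))
  gen <- new_predator("generalist", 30, 30, cell_size_m = 10)
  hg <- hunt(voles, gen)
  expect_gte(length(hg$killed), qbinom(0.005, 1000, 0.04))
  expect_lte(length(hg$killed), qbinom(0.995, 1000, 0.04))
  # voles outside the territory are never touched
  far <- data.frame(id = 1:50, x = rep(55, 50), y = rep(55, 50))
  expect_length(hunt(far, pred)$killed, 0)
})

test_that("dispersal triggers at the failure threshold and respects range", {
  land <- tiny_landscape()
  pred <- new_predator("specialist", 30, 30, cell_size_m = 10)
  pred$failure_streak <- 4L # below threshold 5
  expect_false(maybe_disperse(pred, land)$moved)
  pred$failure_streak <- 5L
  set.seed(3)
  moved <- maybe_disperse(pred, land)
  expect_true(moved$moved)
  d_cells <- ceiling(pred$params$max_dispersal_m / land$cell_size_m)
  expect_lte(max(abs(moved$x - 30), abs(moved$y - 30)), d_cells)
  expect_equal(moved$failure_streak, 0L)
  # kills carry over across the move
  pred$kills_this_year <- 42L
  set.seed(3)
  expect_equal(maybe_disperse(pred, land)$kills_this_year, 42L)
})

test_that("a fully blocked neighbourhood keeps the predator in place", {
  # generalists packed wall to wall around the disperser
  land <- build_landscape(240, 240, 0.04, 1, 10) # 24x24 cells
  gen <- new_predator("generalist", 12, 12, cell_size_m = 10) # side 8
  gen$failure_streak <- 20L
  others <- expand.grid(x = c(4, 12, 20), y = c(4, 12, 20))
  others$side <- 8L
  others <- others[!(others$x == 12 & others$y == 12), ]
  set.seed(7)
  out <- maybe_disperse(gen, land, others = others, n_candidates = 50L)
  expect_false(out$moved)
  expect_equal(out$failure_streak, 20L) # retries the next day
})

test_that("annual survival is a hard kill-count threshold", {
  sp <- new_predator("specialist", 10, 10)
  sp$kills_this_year <- 89L
  expect_false(annual_survival(sp)$alive)
  sp$kills_this_year <- 90L
  sp2 <- annual_survival(sp)
  expect_true(sp2$alive)
  expect_equal(sp2$kills_last_year, 90L)
  expect_equal(sp2$kills_this_year, 0L)
  gn <- new_predator("generalist", 10, 10)
  gn$kills_this_year <- 10L
  expect_true(annual_survival(gn)$alive)
  gn$kills_this_year <- 9L
  expect_false(annual_survival(gn)$alive)
})

test_that("spring offspring follow floor(kills/threshold) with a ceiling", {
  land <- tiny_landscape()
  sp <- new_predator("specialist", 30, 30, cell_size_m = 10)
  sp$kills_last_year <- 23L # floor(23/5) = 4 attempts
  set.seed(11)
  off <- spring_reproduction(sp, land)
  expect_lte(length(off), 4)
  expect_gt(length(off), 0)
  # territory non-overlap among parent and recruits
  all_t <- rbind(
    data.frame(x = sp$x, y = sp$y, side = sp$side),
    do.call(rbind, lapply(off, function(p) {
      data.frame(x = p$x, y = p$y, side = p$side)
    }))
  )
  for (i in seq_len(nrow(all_t) - 1)) {
    for (j in (i + 1):nrow(all_t)) {
      expect_equal(territory_overlap(
        territory(all_t$x[i], all_t$y[i], all_t$side[i]),
        territory(all_t$x[j], all_t$y[j], all_t$side[j])
      ), 0)
    }
  }
  gn <- new_predator("generalist", 30, 30, cell_size_m = 10)
  gn$kills_last_year <- 89L # below the 90-kill threshold
  expect_length(spring_reproduction(gn, land), 0)
  # the litter ceiling caps a huge kill count
  sp$kills_last_year <- 10000L
  set.seed(12)
  expect_lte(length(spring_reproduction(sp, land)),
             sp$params$max_offspring)
})

test_that("recruitment is capped by available territory space", {
  land <- build_landscape(240, 240, 0.04, 1, 10)
  sp <- new_predator("specialist", 12, 12, cell_size_m = 10) # side 5
  sp$kills_last_year <- 1000L
  # pack the whole reachable neighbourhood with same-type territories
  others <- expand.grid(x = seq(2, 22, by = 5), y = seq(2, 22, by = 5))
  others$side <- 5L
  set.seed(13)
  off <- spring_reproduction(sp, land, others = others, n_candidates = 30L)
  expect_length(off, 0) # no recruit could be placed
})

test_that("predation diagnostics match hand computation on a 3-day trace", {
  log <- tibble::tibble(
    predator = c(1, 1, 1, 2, 2, 2),
    day = c(1, 2, 3, 1, 2, 3),
    kills = c(0, 2, 0, 1, 0, 0),
    exposure = c(4, 10, 3, 8, 2, 1)
  )
  d <- predation_diagnostics(log)
  expect_equal(d$failure_day_fraction, 4 / 6)
  expect_equal(d$predation_rate, 3 / 28)
  expect_equal(d$kills, 3L)
  expect_equal(d$predator_days, 6L)
  none <- predation_diagnostics(log[0, ])
  expect_true(is.na(none$failure_day_fraction)) # undefined without predators
  one <- predation_diagnostics(
    tibble::tibble(predator = 1, day = 1:3, kills = c(1, 2, 1),
                   exposure = c(5, 5, 5))
  )
  expect_equal(one$failure_day_fraction, 0)
})

test_that("Table-style parameter sets are validated and overridable", {
  sp <- predator_params("specialist")
  gn <- predator_params("generalist")
  # specialist needs few kills to breed, many to survive; generalist the
  # reverse: the defining asymmetry of the two response types
  expect_lt(sp$reproductive_threshold, gn$reproductive_threshold)
  expect_gt(sp$survival_threshold, gn$survival_threshold)
  expect_gt(sp$kill_efficiency, gn$kill_efficiency)
  expect_lt(sp$territory_size_m2, gn$territory_size_m2)
  expect_lt(sp$failures_before_dispersal, gn$failures_before_dispersal)
  expect_lt(sp$max_dispersal_m, gn$max_dispersal_m)
  custom <- predator_params("specialist", kill_efficiency = 0.2)
  expect_equal(custom$kill_efficiency, 0.2)
  expect_error(predator_params("specialist", kill_efficiency = 1.5))
})
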