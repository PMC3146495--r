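# Vole behavioural rules: seasons, weaning, eviction, mate choice,
# infanticide, mortality, territory search.

test_that("breeding season windows follow the design calendar", {
  int <- breeding_season("intermediate")
  expect_true(in_breeding_season(day_of_year("Apr 5"), int))
  expect_false(in_breeding_season(day_of_year("Apr 4"), int))
  expect_true(in_breeding_season(day_of_year("Oct 1"), int))
  expect_false(in_breeding_season(day_of_year("Oct 2"), int))
  expect_true(in_breeding_season(day_of_year("Oct 15"), breeding_season("long")))
  expect_false(in_breeding_season(day_of_year("Sep 2"), breeding_season("short")))
  expect_equal(breeding_season("short")$end, day_of_year("Sep 1"))
  expect_equal(breeding_season("long")$end, day_of_year("Nov 1"))
})

test_that("weanlings appear at the nest, at weaning age, sexes ~ even", {
  mother <- list(x = 10L, y = 12L, alive = TRUE)
  set.seed(1)
  young <- wean_litter(mother, 4)
  expect_equal(nrow(young), 4)
  expect_true(all(young$x == 10L & young$y == 12L))
  expect_true(all(young$age_days == 14L))
  expect_true(all(young$stage == "juvenile"))
  expect_equal(nrow(wean_litter(mother, 0)), 0)
  expect_equal(nrow(wean_litter(list(x = 1, y = 1, alive = FALSE), 5)), 0)
  # sex ratio of 10,000 weanlings within the binomial 99% interval of 1/2
  set.seed(99)
  big <- wean_litter(mother, 10000)
  nf <- sum(big$sex == "F")
  expect_gte(nf, qbinom(0.005, 10000, 0.5))
  expect_lte(nf, qbinom(0.995, 10000, 0.5))
})

test_that("eviction requires same sex, older holder and >50% overlap", {
  older <- list(sex = "F", age_days = 200,
                territory = territory(10, 10, 2))
  younger_60 <- list(sex = "F", age_days = 100,
                     territory = territory(11, 10, 2)) # 2 of 4 cells... 50%
  # 50% exactly: no eviction (strict inequality)
  expect_false(resolve_eviction(older, younger_60))
  younger_100 <- list(sex = "F", age_days = 100,
                      territory = territory(10, 10, 2)) # full overlap
  expect_true(resolve_eviction(older, younger_100))
  # opposite sexes never evict
  male <- list(sex = "M", age_days = 100, territory = territory(10, 10, 2))
  expect_false(resolve_eviction(older, male))
  # the younger cannot evict the older
  expect_false(resolve_eviction(younger_100, older))
  # equal ages: no one is "older"
  peer <- list(sex = "F", age_days = 200, territory = territory(10, 10, 2))
  expect_false(resolve_eviction(older, peer))
})

test_that("territory_overlap is measured on the second argument", {
  a <- territory(0, 0, 2) # cells [0,1]x[0,1]
  b <- territory(1, 1, 2) # cells [1,2]x[1,2]
  expect_equal(territory_overlap(a, b), 0.25)
  expect_equal(territory_overlap(b, a), 0.25)
  big <- territory(0, 0, 4)
  small <- territory(0, 0, 2)
  expect_equal(territory_overlap(big, small), 1)
  expect_lt(territory_overlap(small, big), 0.5)
})

test_that("a female chooses the closest overlapping male", {
  female <- list(x = 10, y = 10)
  males <- data.frame(
    id = c(1L, 2L, 3L),
    x = c(10, 12, 30), # 3 overlaps nothing
    y = c(11, 10, 30),
    side = c(4L, 4L, 4L)
  )
  expect_equal(select_mate(female, males), 1L) # distance 1 beats distance 2
  expect_equal(select_mate(female, males[3, , drop = FALSE]), NA_integer_)
  expect_equal(select_mate(female, males[integer(0), ]), NA_integer_)
  one <- data.frame(id = 9L, x = 11, y = 11, side = 4L)
  expect_equal(select_mate(female, one), 9L)
})

test_that("infanticide declines with litter age and needs an intruder", {
  p <- vole_params()
  expect_equal(infanticide_prob(14, p), 0)
  expect_equal(infanticide_prob(0, p), p$infanticide_p0)
  ages <- 0:14
  probs <- infanticide_prob(ages, p)
  expect_true(all(diff(probs) <= 0)) # non-increasing in age
  expect_false(attempt_infanticide(FALSE, 0, p)) # male inside own territory
  set.seed(2)
  expect_false(attempt_infanticide(TRUE, 14, p)) # weaned young immune
})

test_that("mortality: predation, starvation or lifespan, else alive", {
  p <- vole_params()
  voles <- data.frame(
    age_days = c(100, p$lifespan_days, 100, 100),
    days_in_matrix = c(0, 0, p$starvation_days + 1, p$starvation_days)
  )
  alive <- vole_mortality(voles, predated = c(FALSE, FALSE, FALSE, FALSE), p)
  expect_equal(alive, c(TRUE, FALSE, FALSE, TRUE))
  expect_false(vole_mortality(voles[1, ], predated = TRUE, p))
})

test_that("territory search grants free ground and respects the matrix", {
  land <- tiny_landscape() # one 12x12-cell patch
  p0 <- land$patches[1, ]
  cx <- (p0$x0 + p0$x1) %/% 2
  cy <- (p0$y0 + p0$y1) %/% 2
  prm <- vole_params()
  # lone female in an empty patch larger than her need
  lone <- list(x = cx, y = cy, sex = "F", age_days = 100)
  site <- find_territory(land, lone, params = prm)
  expect_false(is.null(site))
  expect_equal(habitat_at(land, site$x, site$y), "optimal")
  # a vole deep in matrix finds nothing
  stranded <- list(x = 0, y = 0, sex = "F", age_days = 100)
  expect_null(find_territory(land, stranded, params = prm))
  # sequential settlement in a minimal patch: both females fit with
  # zero overlap (patch of 2x2 cells = 4 single-cell female slots)
  land4 <- build_landscape(600, 600, 4 * 100 / 600^2, 1, 10)
  origin <- list(
    x = land4$patches$x0[1], y = land4$patches$y0[1],
    sex = "F", age_days = 120
  )
  s1 <- find_territory(land4, origin, params = prm)
  expect_false(is.null(s1))
  residents <- data.frame(
    id = 1L, sex = "F", age_days = 120, x = s1$x, y = s1$y, side = 1L
  )
  second <- list(x = origin$x, y = origin$y, sex = "F", age_days = 90)
  s2 <- find_territory(land4, second, residents = residents, params = prm)
  expect_false(is.null(s2))
  expect_length(s2$evict, 0)
  expect_false(s1$x == s2$x && s1$y == s2$y) # zero overlap: distinct cells
})

test_that("males in season prefer sites holding mature females", {
  land <- tiny_landscape()
  p0 <- land$patches[1, ]
  prm <- vole_params()
  male <- list(x = p0$x0 + 6, y = p0$y0 + 6, sex = "M", age_days = 120)
  females <- data.frame(x = p0$x0 + 2, y = p0$y0 + 2)
  site <- find_territory(land, male,
    females = females, params = prm, season = TRUE
  )
  expect_false(is.null(site))
  off <- (site$side - 1) %/% 2
  expect_true(
    females$x >= site$x - off && females$x < site$x - off + site$side &&
      females$y >= site$y - off && females$y < site$y - off + site$side
  )
})
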