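# Landscape construction: area conservation, patch layout, queries.

test_that("full-scale landscapes hold 1.5% habitat at every fragmentation", {
  for (n in c(1, 9, 25, 100)) {
    land <- build_landscape(10000, 10000, 0.015, n, cell_size_m = 1)
    expect_equal(land$habitat_fraction, 0.015, tolerance = 0.01)
    expect_equal(land$n_patches, as.integer(n))
    # congruent square patches
    expect_equal(nrow(land$patches), n)
    expect_true(all(land$patches$x1 - land$patches$x0 + 1 ==
                      land$patch_side_cells))
  }
  one <- build_landscape(10000, 10000, 0.015, 1, 1)
  area <- one$patch_side_cells^2 # m^2 at 1 m cells
  expect_equal(area, 1.5e6, tolerance = 0.01 * 1.5e6)
  hundred <- build_landscape(10000, 10000, 0.015, 100, 1)
  expect_equal(hundred$patch_side_cells^2, 1.5e4, tolerance = 0.01 * 1.5e4)
})

test_that("habitat area is conserved across fragmentation levels", {
  areas <- vapply(c(1, 9, 25, 100), function(n) {
    land <- build_landscape(2450, 2450, 0.015, n, 10)
    land$n_patches * land$patch_side_cells^2
  }, numeric(1))
  expect_true(all(areas == areas[1])) # exact at the desk-scale geometry
})

test_that("a tiny exact case: 100 x 100 m, 1% habitat, one 10 x 10 patch", {
  land <- build_landscape(100, 100, 0.01, 1, 1)
  expect_equal(land$patch_side_cells, 10L)
  expect_equal(sum(land$patch >= 0), 100)
  expect_equal(land$habitat_fraction, 0.01)
})

test_that("scaling landscape and patch count together keeps the fraction", {
  a <- build_landscape(1000, 1000, 0.02, 4, 10)
  b <- build_landscape(2000, 2000, 0.02, 16, 10)
  expect_equal(a$habitat_fraction, b$habitat_fraction, tolerance = 0.01)
})

test_that("invalid geometries are rejected", {
  expect_error(build_landscape(1000, 1000, 0.015, 7, 10), "perfect square")
  expect_error(build_landscape(1000, 1000, 1.5, 1, 10), "habitat_fraction")
  expect_error(build_landscape(200, 200, 0.001, 100, 10), "side")
})

test_that("habitat_at is consistent with the patch grid", {
  land <- build_landscape(100, 100, 0.01, 1, 1)
  centre <- land$patches[1, ]
  cx <- (centre$x0 + centre$x1) %/% 2
  cy <- (centre$y0 + centre$y1) %/% 2
  expect_equal(habitat_at(land, cx, cy), "optimal")
  expect_equal(habitat_at(land, 0, 0), "matrix") # centred patch -> corner free
  expect_error(habitat_at(land, -1, 0), "bounds")
  expect_error(habitat_at(land, 0, 100), "bounds")
  # any cell with a patch id is optimal
  cells <- as_tibble(land)
  expect_identical(
    cells$habitat == "optimal", cells$patch >= 0L
  )
})

test_that("patch_occupancy counts distinct occupied patches", {
  land <- build_landscape(2450, 2450, 0.015, 100, 10)
  expect_equal(patch_occupancy(land, NULL), 0)
  expect_equal(
    patch_occupancy(land, data.frame(x = integer(), y = integer())), 0
  )
  # one vole at each patch centre -> occupancy 1
  centres <- data.frame(
    x = (land$patches$x0 + land$patches$x1) %/% 2,
    y = (land$patches$y0 + land$patches$y1) %/% 2
  )
  expect_equal(patch_occupancy(land, centres), 1)
  # voles in 35 distinct patches (several voles in some) -> 0.35
  sub <- centres[1:35, ]
  sub <- rbind(sub, sub[1:10, ])
  expect_equal(patch_occupancy(land, sub), 0.35)
  # matrix voles do not count
  expect_equal(patch_occupancy(land, data.frame(x = 0, y = 0)), 0)
})

test_that("landscape JSON round-trips exactly", {
  land <- build_landscape(2450, 2450, 0.015, 9, 10)
  path <- tempfile(fileext = ".json")
  write_landscape(land, path)
  back <- read_landscape(path)
  expect_identical(back$patch, land$patch)
  expect_equal(back$habitat_fraction, land$habitat_fraction)
  unlink(path)
})
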