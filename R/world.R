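# Bridge between scenario_config and the compiled daily-tick world.

# Flatten a scenario_config into the list the C++ engine consumes.
# Distances are converted to cells here, so the engine is unit-free.
engine_config <- function(config, landscape = NULL, record_daily = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(landscape)) {
    landscape <- build_landscape(
      config$width_m, config$height_m, config$habitat_fraction,
      config$n_patches, config$cell_size_m
    )
  }
  cell <- landscape$cell_size_m
  vp <- config$vole
  to_cells <- function(m) max(1L, as.integer(round(m / cell)))
  habitat_cells <- landscape$n_patches * landscape$patch_side_cells^2
  habitat_m2 <- habitat_cells * cell^2

  pred_cfg <- function(pp, active) {
    cap <- habitat_m2 / pp$territory_size_m2
    list(
      active = active,
      repro_thr = pp$reproductive_threshold,
      surv_thr = pp$survival_threshold,
      kill_eff = pp$kill_efficiency,
      side = to_cells(sqrt(pp$territory_size_m2)),
      fail_disp = as.integer(pp$failures_before_dispersal),
      max_disp = to_cells(pp$max_dispersal_m),
      max_off = as.integer(pp$max_offspring),
      sense_thr = as.integer(pp$prey_sign_threshold),
      init_n = max(2L, as.integer(round(cap * config$init_predator_density))),
      immigrants = config$immigrants_per_year
    )
  }
  spec_on <- config$predator_assembly %in% c("specialist", "mixed")
  gen_on <- config$predator_assembly %in% c("generalist", "mixed")

  list(
    W = landscape$width, H = landscape$height,
    n_patches = landscape$n_patches,
    cell_m = cell,
    pid = as.integer(as.vector(t(landscape$patch))), # cell = y*W + x
    vole = list(
      gestation = vp$gestation_days, weaning = vp$weaning_days,
      maturity = vp$maturity_days, lifespan = vp$lifespan_days,
      starvation = vp$starvation_days,
      litter_min = vp$litter_min, litter_max = vp$litter_max,
      f_side = to_cells(vp$female_territory_m),
      m_side = to_cells(vp$male_territory_m),
      search_radius = to_cells(vp$search_radius_m),
      move_radius = to_cells(vp$move_m),
      infant_p0 = vp$infanticide_p0,
      excursion_p = vp$excursion_p,
      excursion_radius = to_cells(vp$excursion_radius_m)
    ),
    specialist = pred_cfg(config$specialist, spec_on),
    generalist = pred_cfg(config$generalist, gen_on),
    season_start = config$season$start,
    season_end = config$season$end,
    census_day = config$census_day,
    init_voles_per_sex = max(
      1L,
      as.integer(round(habitat_cells * config$init_vole_density))
    ),
    vole_immigrants = as.integer(config$vole_immigrants_per_year),
    record_daily = record_daily
  )
}

#' Create a simulation world
#'
#' Instantiates the daily-tick individual-based world for a scenario. The
#' world is a stateful handle: advance it with [world_step()], inspect it
#' with [world_counts()], [world_voles()] and [world_predators()]. Useful
#' for constructing small fixtures and probing single behavioural rules;
#' whole-scenario runs should use [run_scenario()].
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed for the world's own random stream.
#' @param empty If `TRUE`, start with no voles and no predators (agents
#'   can then be injected with [world_add_vole()] / [world_add_predator()]).
#' @return An object of class `vole_world`.
#' @export
vole_world <- function(config, seed = 1, empty = FALSE) {
  cfg <- engine_config(config)
  if (empty) {
    cfg$init_voles_per_sex <- 0L
    cfg$specialist$init_n <- 0L
    cfg$generalist$init_n <- 0L
    cfg$specialist$immigrants <- 0L
    cfg$generalist$immigrants <- 0L
    cfg$vole_immigrants <- 0L
  }
  ptr <- cpp_world_new(cfg, as.numeric(seed))
  structure(
    list(ptr = ptr, config = config),
    class = "vole_world"
  )
}

#' @export
print.vole_world <- function(x, ...) {
  ct <- world_counts(x)
  cat(sprintf(
    "<vole_world> day %d of year %d: %d voles, %d specialists, %d generalists\n",
    ct$doy, ct$year, ct$n_voles, ct$n_specialists, ct$n_generalists
  ))
  invisible(x)
}

#' Advance a world day by day
#'
#' One daily step applies, in order: vole behaviours (territory
#' assessment/acquisition with eviction, dispersal movement, mating,
#' gestation, weaning, infanticide excursions), predator hunts, predator
#' dispersal checks, then mortality. The agent schedule is reshuffled
#' every day. Annual events (predator spring reproduction on 1 April,
#' year-end survival evaluation) fire on their calendar days.
#'
#' @param world A [vole_world()].
#' @param n_days Number of days to advance.
#' @return The world, invisibly (state is advanced in place).
#' @export
world_step <- function(world, n_days = 1L) {
  stopifnot(inherits(world, "vole_world"))
  cpp_world_step(world$ptr, as.integer(n_days))
  invisible(world)
}

#' Set the calendar position of a world (fixture helper)
#' @param world A [vole_world()].
#' @param doy Day of year (1-365).
#' @param year Simulation year.
#' @return The world, invisibly.
#' @export
world_set_day <- function(world, doy, year = 1L) {
  cpp_world_set_day(world$ptr, as.integer(doy), as.integer(year))
  invisible(world)
}

#' Snapshot counts and cumulative event tallies of a world
#'
#' @param world A [vole_world()].
#' @return One-row tibble: calendar position, population composition,
#'   predator counts, occupied patches, and the cumulative birth and
#'   per-cause death tallies (every vole death is attributed to exactly
#'   one of predation, starvation or lifespan).
#' @export
world_counts <- function(world) {
  stopifnot(inherits(world, "vole_world"))
  as_tibble(cpp_world_counts(world$ptr))
}

#' @describeIn world_counts All living voles as a tibble.
#' @export
world_voles <- function(world) {
  stopifnot(inherits(world, "vole_world"))
  out <- as_tibble(cpp_world_voles(world$ptr))
  out$sex <- ifelse(out$sex == 1, "M", "F")
  out
}

#' @describeIn world_counts All living predators as a tibble.
#' @export
world_predators <- function(world) {
  stopifnot(inherits(world, "vole_world"))
  out <- as_tibble(cpp_world_preds(world$ptr))
  out$type <- ifelse(out$type == 1, "generalist", "specialist")
  out
}

#' Inject a vole into a world (fixture helper)
#'
#' @param world A [vole_world()].
#' @param sex `"F"` or `"M"`.
#' @param age Age in days.
#' @param x,y Cell position.
#' @param settle Attempt to grant a territory centred at `(x, y)`
#'   immediately (subject to the usual habitat/overlap rules).
#' @return The vole's id.
#' @export
world_add_vole <- function(world, sex = "F", age = 60L, x, y,
                           settle = TRUE) {
  stopifnot(inherits(world, "vole_world"), sex %in% c("F", "M"))
  cpp_world_add_vole(
    world$ptr, as.integer(sex == "M"), as.integer(age),
    as.integer(x), as.integer(y), settle
  )
}

#' Inject a predator into a world (fixture helper)
#'
#' @param world A [vole_world()].
#' @param type `"specialist"` or `"generalist"`.
#' @param x,y Territory centre cell.
#' @return `TRUE` if the site was free (same-type non-overlap) and the
#'   predator was placed.
#' @export
world_add_predator <- function(world, type = "specialist", x, y) {
  stopifnot(inherits(world, "vole_world"))
  cpp_world_add_pred(
    world$ptr, as.integer(type == "generalist"),
    as.integer(x), as.integer(y)
  )
}
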