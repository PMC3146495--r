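#' Vole life-history and behaviour constants
#'
#' Demographic and movement constants for the field-vole agents. The core
#' behavioural rules (territoriality, eviction, closest-male mating,
#' season-limited breeding, weaning at day 14, even sex ratio) are fixed;
#' the quantitative constants below are calibration constants with
#' field-plausible defaults, documented in the methods vignette.
#'
#' @param gestation_days Gestation length (days).
#' @param weaning_days Age at weaning; weanlings enter the simulation at
#'   this age, at the mother's nest.
#' @param maturity_days Age of sexual maturity (days).
#' @param lifespan_days Physiological lifespan limit (days).
#' @param starvation_days Number of consecutive days in matrix habitat a
#'   vole survives; death occurs when the count exceeds this.
#' @param litter_min,litter_max Litter size drawn uniformly on this range.
#' @param female_territory_m,male_territory_m Territory side length (m);
#'   territories are squares of optimal habitat.
#' @param search_radius_m Daily radius scanned for a free territory site.
#' @param move_m Daily displacement of itinerant (non-territorial) voles;
#'   in matrix habitat movement is directionally persistent (dispersal),
#'   on optimal habitat it is a local random jump.
#' @param infanticide_p0 Success probability of an infanticide attempt on
#'   a newborn litter; declines linearly to 0 at weaning age.
#' @param excursion_p Daily probability that a resident mature male makes
#'   an excursion beyond his territory during the breeding season
#'   (encounters with nursing females then trigger infanticide attempts).
#' @param excursion_radius_m Excursion radius (m).
#' @return A named list of class `vole_params`.
#' @export
vole_params <- function(gestation_days = 21L,
                        weaning_days = 14L,
                        maturity_days = 60L,
                        lifespan_days = 550L,
                        starvation_days = 10L,
                        litter_min = 4L,
                        litter_max = 6L,
                        female_territory_m = 10,
                        male_territory_m = 20,
                        search_radius_m = 50,
                        move_m = 80,
                        infanticide_p0 = 0.5,
                        excursion_p = 0.05,
                        excursion_radius_m = 30) {
  out <- as.list(environment())
  stopifnot(
    out$weaning_days > 0, out$gestation_days > 0,
    out$litter_min >= 0, out$litter_max >= out$litter_min,
    out$lifespan_days > out$maturity_days,
    out$infanticide_p0 >= 0, out$infanticide_p0 <= 1
  )
  structure(out, class = "vole_params")
}

#' Predator parameter sets
#'
#' Returns the six behavioural parameters for a predator type. The
#' defaults encode the two archetypes of the study design: a small
#' mustelid-like specialist with a strong delayed numerical response (few
#' kills needed per offspring, many needed to survive, small territory,
#' high kill efficiency, quick to disperse, short dispersal range) and a
#' fox-like generalist with a weakly coupled response (the reverse).
#'
#' @param type `"specialist"` or `"generalist"`.
#' @param reproductive_threshold Voles killed per offspring produced.
#' @param survival_threshold Voles killed per year required to survive the
#'   year-end evaluation.
#' @param territory_size_m2 Hunting territory area (m^2); territories are
#'   squares and never overlap within a predator type.
#' @param kill_efficiency Daily probability of killing each vole inside
#'   the territory.
#' @param failures_before_dispersal Consecutive days without a kill that
#'   trigger dispersal.
#' @param max_dispersal_m Maximum dispersal distance per move (m).
#' @param max_offspring Ceiling on spring offspring per adult (a
#'   litter-size calibration constant; the kill-count threshold sets how
#'   many of these are realised).
#' @param prey_sign_threshold Minimum number of voles a candidate
#'   dispersal site must hold to register as prey sign; sparser pockets
#'   are effectively invisible to a searching predator (a giving-up
#'   density, and the voles' low-density refuge).
#' @return A named list of class `predator_params`.
#' @examples
#' predator_params("specialist")$kill_efficiency # 0.095
#' @export
predator_params <- function(type = c("specialist", "generalist"),
                            reproductive_threshold = NULL,
                            survival_threshold = NULL,
                            territory_size_m2 = NULL,
                            kill_efficiency = NULL,
                            failures_before_dispersal = NULL,
                            max_dispersal_m = NULL,
                            max_offspring = NULL,
                            prey_sign_threshold = NULL) {
  type <- match.arg(type)
  def <- if (type == "specialist") {
    list(
      reproductive_threshold = 5, survival_threshold = 90,
      territory_size_m2 = 2500, kill_efficiency = 0.095,
      failures_before_dispersal = 5L, max_dispersal_m = 500,
      max_offspring = 6L, prey_sign_threshold = 6L
    )
  } else {
    list(
      reproductive_threshold = 90, survival_threshold = 10,
      territory_size_m2 = 6400, kill_efficiency = 0.04,
      failures_before_dispersal = 20L, max_dispersal_m = 1000,
      max_offspring = 6L, prey_sign_threshold = 6L
    )
  }
  supplied <- list(
    reproductive_threshold = reproductive_threshold,
    survival_threshold = survival_threshold,
    territory_size_m2 = territory_size_m2,
    kill_efficiency = kill_efficiency,
    failures_before_dispersal = failures_before_dispersal,
    max_dispersal_m = max_dispersal_m,
    max_offspring = max_offspring,
    prey_sign_threshold = prey_sign_threshold
  )
  for (nm in names(supplied)) {
    if (!is.null(supplied[[nm]])) def[[nm]] <- supplied[[nm]]
  }
  stopifnot(
    def$kill_efficiency > 0, def$kill_efficiency < 1,
    def$reproductive_threshold > 0, def$survival_threshold > 0,
    def$territory_size_m2 > 0, def$failures_before_dispersal > 0,
    def$max_dispersal_m > 0
  )
  structure(c(list(type = type), def), class = "predator_params")
}

#' Breeding-season calendar window
#'
#' The season starts 5 April (day 95 of a 365-day year). The study design
#' varies its end date: 1 September (short), 1 October (intermediate) or
#' 1 November (long).
#'
#' @param length `"short"`, `"intermediate"` or `"long"`.
#' @return List of class `breeding_season` with integer `start` and `end`
#'   days of year (both inclusive).
#' @examples
#' breeding_season("long")$end # 305 (1 November)
#' @export
breeding_season <- function(length = c("intermediate", "short", "long")) {
  length <- match.arg(length)
  end <- switch(length, short = 244L, intermediate = 274L, long = 305L)
  structure(
    list(length = length, start = 95L, end = end),
    class = "breeding_season"
  )
}

#' Is a day of year inside the breeding season?
#'
#' @param day Integer day of year (1-365), vectorised.
#' @param season A [breeding_season()] object.
#' @return Logical vector.
#' @examples
#' in_breeding_season(95, breeding_season("intermediate")) # TRUE (5 April)
#' in_breeding_season(275, breeding_season("intermediate")) # FALSE (2 October)
#' @export
in_breeding_season <- function(day, season) {
  stopifnot(inherits(season, "breeding_season"))
  day >= season$start & day <= season$end
}

#' Convert a calendar date string to day of year (365-day calendar)
#'
#' Convenience for tests and configs; `"Apr 5"` -> 95. No leap days.
#' @param text Strings like `"Oct 1"`.
#' @return Integer day(s) of year.
#' @export
day_of_year <- function(text) {
  months <- c(
    Jan = 0L, Feb = 31L, Mar = 59L, Apr = 90L, May = 120L, Jun = 151L,
    Jul = 181L, Aug = 212L, Sep = 243L, Oct = 273L, Nov = 304L, Dec = 334L
  )
  vapply(strsplit(text, "[ ]+"), function(p) {
    months[[p[1]]] + as.integer(p[2])
  }, integer(1))
}
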