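# Vole behavioural rules, expressed on tibbles of agents. These are the
# reference semantics of the rules the compiled engine applies at scale;
# they operate at cell resolution (territories are axis-aligned squares
# described by centre cell and side length in cells).

#' Square territory geometry helpers
#'
#' A territory with centre `(x, y)` and side `s` covers cells
#' `[x - floor((s-1)/2), x - floor((s-1)/2) + s)` on each axis (so a
#' side-1 territory is exactly its centre cell).
#'
#' @param x,y Centre cell coordinates.
#' @param side Side length in cells.
#' @return A list with `x0`, `y0` (inclusive lower corners) and `side`.
#' @export
territory <- function(x, y, side = 1L) {
  off <- (side - 1L) %/% 2L
  list(x0 = as.integer(x) - off, y0 = as.integer(y) - off,
       side = as.integer(side), x = as.integer(x), y = as.integer(y))
}

#' Overlap between two territories as a fraction of the second one
#'
#' @param a,b Territories from [territory()].
#' @return `area(a intersect b) / area(b)`.
#' @export
territory_overlap <- function(a, b) {
  ox <- max(0L, min(a$x0 + a$side, b$x0 + b$side) - max(a$x0, b$x0))
  oy <- max(0L, min(a$y0 + a$side, b$y0 + b$side) - max(a$y0, b$y0))
  (ox * oy) / (b$side^2)
}

#' Wean a litter into juvenile agents
#'
#' Weanlings enter the population at the mother's nest location at weaning
#' age, with sex assigned independently with probability 1/2 (even sex
#' ratio), and immediately join the pool of territory-searching
#' itinerants. If the mother is dead the litter is lost.
#'
#' @param mother One-row data frame (or list) with `x`, `y` and `alive`.
#' @param n_young Number of young in the litter.
#' @param params [vole_params()].
#' @return Tibble of weanlings with columns `sex` (`"F"`/`"M"`), `stage`
#'   (`"juvenile"`), `age_days`, `x`, `y`; zero rows if `n_young` is 0 or
#'   the mother is dead.
#' @export
wean_litter <- function(mother, n_young, params = vole_params()) {
  if (n_young <= 0 || isFALSE(mother$alive)) {
    return(tibble(
      sex = character(), stage = character(), age_days = integer(),
      x = integer(), y = integer()
    ))
  }
  tibble(
    sex = ifelse(runif(n_young) < 0.5, "F", "M"),
    stage = "juvenile",
    age_days = as.integer(params$weaning_days),
    x = as.integer(mother$x),
    y = as.integer(mother$y)
  )
}

#' Should a younger vole be evicted by an older same-sex territory holder?
#'
#' A younger vole whose territory overlaps an older, same-sex resident's
#' territory by strictly more than 50% of its own area is forced to move
#' (loses its territory and re-enters dispersal).
#'
#' @param older,younger Lists with `sex`, `age_days` and `territory` (a
#'   [territory()]).
#' @return `TRUE` if the younger vole is evicted.
#' @export
resolve_eviction <- function(older, younger) {
  if (!identical(older$sex, younger$sex)) {
    return(FALSE)
  }
  if (older$age_days <= younger$age_days) {
    return(FALSE)
  }
  territory_overlap(older$territory, younger$territory) > 0.5
}

#' Choose a mate for a receptive female
#'
#' Candidate males are those whose territory overlaps the female's
#' position; among them she chooses the closest by Euclidean distance
#' (ties broken toward the first listed).
#'
#' @param female List/row with position `x`, `y`.
#' @param males Data frame with columns `id`, `x`, `y` (territory centre)
#'   and `side` (territory side, cells).
#' @return The chosen male's `id`, or `NA` if no territory overlaps her.
#' @export
select_mate <- function(female, males) {
  if (is.null(males) || nrow(males) == 0L) {
    return(NA_integer_)
  }
  covers <- vapply(seq_len(nrow(males)), function(i) {
    t <- territory(males$x[i], males$y[i], males$side[i])
    female$x >= t$x0 && female$x < t$x0 + t$side &&
      female$y >= t$y0 && female$y < t$y0 + t$side
  }, logical(1))
  if (!any(covers)) {
    return(NA_integer_)
  }
  cand <- males[covers, , drop = FALSE]
  d2 <- (cand$x - female$x)^2 + (cand$y - female$y)^2
  cand$id[which.min(d2)]
}

#' Infanticide success probability
#'
#' Success declines linearly with litter age from `p0` at birth to 0 at
#' weaning age, so weaned young are immune.
#'
#' @param litter_age Litter age in days (vectorised).
#' @param params [vole_params()].
#' @return Probability in \[0, 1\].
#' @export
infanticide_prob <- function(litter_age, params = vole_params()) {
  pmax(0, params$infanticide_p0 *
    (1 - litter_age / params$weaning_days))
}

#' Attempt infanticide on a female's unweaned litter
#'
#' Only mature males that have moved beyond the bounds of their original
#' territory attempt infanticide.
#'
#' @param male_outside_territory Is the male beyond his own territory?
#' @param litter_age Age of the litter (days).
#' @param params [vole_params()].
#' @return `TRUE` if the litter is killed.
#' @export
attempt_infanticide <- function(male_outside_territory, litter_age,
                                params = vole_params()) {
  if (!isTRUE(male_outside_territory)) {
    return(FALSE)
  }
  runif(1) < infanticide_prob(litter_age, params)
}

#' Daily vole mortality rule
#'
#' A vole dies the day it is predated, when it has spent more than the
#' starvation threshold of consecutive days in matrix habitat, or upon
#' reaching its physiological lifespan limit. Vectorised over rows.
#'
#' @param voles Data frame with `age_days` and `days_in_matrix`.
#' @param predated Logical (recycled): killed by a predator today.
#' @param params [vole_params()].
#' @return Logical vector: `TRUE` when the vole survives the day.
#' @export
vole_mortality <- function(voles, predated = FALSE, params = vole_params()) {
  n <- nrow(voles)
  predated <- rep_len(predated, n)
  !(predated |
    voles$days_in_matrix > params$starvation_days |
    voles$age_days >= params$lifespan_days)
}

#' Search for a free territory site near a vole
#'
#' Scans candidate centre cells in rings of increasing Chebyshev radius
#' (nearest first, deterministic order) around the vole's position. A site
#' is valid when every cell of the would-be territory is optimal habitat
#' and no same-sex resident that is at least as old retains >50% of the
#' candidate's area; younger same-sex residents overlapped by more than
#' half of *their* area would be evicted. During the breeding season
#' mature males prefer sites containing at least one mature female, and
#' fall back on the nearest valid site otherwise.
#'
#' @param landscape [build_landscape()] object.
#' @param vole List/row with `x`, `y`, `sex` (`"F"`/`"M"`), `age_days`.
#' @param residents Data frame of territory holders with columns `id`,
#'   `sex`, `age_days`, `x`, `y` (territory centre), `side`; may be empty.
#' @param females Optional data frame of mature female positions (`x`,
#'   `y`) used for the male preference rule.
#' @param params [vole_params()].
#' @param season Is it the breeding season (enables the male preference)?
#' @return `NULL` if no site exists within the search radius, else a list
#'   with the territory (`x`, `y`, `side`) and `evict`, the ids of younger
#'   residents displaced by settling.
#' @export
find_territory <- function(landscape, vole, residents = NULL,
                           females = NULL, params = vole_params(),
                           season = FALSE) {
  stopifnot(inherits(landscape, "vole_landscape"))
  cell <- landscape$cell_size_m
  side <- max(1L, as.integer(round(
    (if (vole$sex == "F") params$female_territory_m else
      params$male_territory_m) / cell
  )))
  radius <- max(1L, as.integer(round(params$search_radius_m / cell)))
  W <- landscape$width
  H <- landscape$height
  off <- (side - 1L) %/% 2L
  prefer_female <- vole$sex == "M" && season &&
    vole$age_days >= params$maturity_days && !is.null(females) &&
    nrow(females) > 0L

  site_ok <- function(cx, cy) {
    x0 <- cx - off
    y0 <- cy - off
    if (x0 < 0L || y0 < 0L || x0 + side > W || y0 + side > H) {
      return(NULL)
    }
    block <- landscape$patch[(y0 + 1):(y0 + side), (x0 + 1):(x0 + side)]
    if (any(block < 0L)) {
      return(NULL)
    }
    cand <- territory(cx, cy, side)
    evict <- integer()
    if (!is.null(residents) && nrow(residents) > 0L) {
      same <- residents[residents$sex == vole$sex, , drop = FALSE]
      for (i in seq_len(nrow(same))) {
        rt <- territory(same$x[i], same$y[i], same$side[i])
        if (territory_overlap(rt, cand) > 0.5 &&
            same$age_days[i] >= vole$age_days) {
          return(NULL) # an older (or equal-age) holder keeps the ground
        }
        if (territory_overlap(cand, rt) > 0.5 &&
            same$age_days[i] < vole$age_days) {
          evict <- c(evict, same$id[i])
        }
      }
    }
    list(x = cx, y = cy, side = side, evict = evict)
  }

  has_female <- function(site) {
    any(females$x >= site$x - off & females$x < site$x - off + side &
          females$y >= site$y - off & females$y < site$y - off + side)
  }

  fallback <- NULL
  for (r in 0:radius) {
    ring <- ring_cells(vole$x, vole$y, r)
    for (k in seq_len(nrow(ring))) {
      site <- site_ok(ring$x[k], ring$y[k])
      if (is.null(site)) next
      if (!prefer_female) {
        return(site)
      }
      if (has_female(site)) {
        return(site)
      }
      if (is.null(fallback)) fallback <- site
    }
  }
  fallback
}

# cells at exact Chebyshev distance r from (x, y), deterministic order
ring_cells <- function(x, y, r) {
  if (r == 0L) {
    return(tibble(x = as.integer(x), y = as.integer(y)))
  }
  xs <- (x - r):(x + r)
  ys <- (y - r):(y + r)
  top <- tibble(x = xs, y = y + r)
  bottom <- tibble(x = xs, y = y - r)
  left <- tibble(x = x - r, y = (y - r + 1L):(y + r - 1L))
  right <- tibble(x = x + r, y = (y - r + 1L):(y + r - 1L))
  out <- bind_rows(top, bottom, left, right)
  out[order(pmax(abs(out$x - x), abs(out$y - y)), out$y, out$x), ]
}
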