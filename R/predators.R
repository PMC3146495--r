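# Predator behavioural rules on tibbles. As with the vole rules these are
# the reference semantics; the compiled engine applies the same rules at
# scale. Predator territories are squares (side = sqrt(territory area)),
# never overlapping within a type; hunting is confined to the territory.

#' Create a predator agent
#'
#' @param type `"specialist"` or `"generalist"`.
#' @param x,y Territory centre (cell coordinates).
#' @param params [predator_params()]; defaults to the type's standard set.
#' @param cell_size_m Cell edge (m), used to convert territory area to a
#'   side length in cells.
#' @return List of class `predator` with territory geometry and the
#'   per-year kill count and failure streak initialised to zero.
#' @export
new_predator <- function(type, x, y, params = predator_params(type),
                         cell_size_m = 10) {
  side <- max(1L, as.integer(round(sqrt(params$territory_size_m2) /
                                     cell_size_m)))
  structure(
    list(
      type = type, x = as.integer(x), y = as.integer(y), side = side,
      params = params, kills_this_year = 0L, kills_last_year = 0L,
      failure_streak = 0L, alive = TRUE
    ),
    class = "predator"
  )
}

#' Hunt: daily predation within the territory
#'
#' Every vole inside the territory is killed independently with the
#' type's daily kill efficiency. The annual kill counter increases by the
#' number of kills; the failure streak resets on any kill and increments
#' on a day with none (including days with an empty territory).
#'
#' @param voles Data frame of voles with `id`, `x`, `y`.
#' @param predator A [new_predator()] object.
#' @return List: `predator` (updated counters), `killed` (ids), and
#'   `voles` (input minus the killed).
#' @export
hunt <- function(voles, predator) {
  t <- territory(predator$x, predator$y, predator$side)
  inside <- voles$x >= t$x0 & voles$x < t$x0 + t$side &
    voles$y >= t$y0 & voles$y < t$y0 + t$side
  idx <- which(inside)
  killed <- idx[runif(length(idx)) < predator$params$kill_efficiency]
  predator$kills_this_year <- predator$kills_this_year + length(killed)
  predator$failure_streak <-
    if (length(killed) > 0L) 0L else predator$failure_streak + 1L
  list(
    predator = predator,
    killed = voles$id[killed],
    voles = if (length(killed)) voles[-killed, , drop = FALSE] else voles
  )
}

#' Dispersal check after repeated hunting failure
#'
#' When the failure streak reaches the type's threshold the predator
#' relocates its territory centre to a random non-overlapping site within
#' the maximum dispersal distance (square neighbourhood); if every
#' candidate is blocked by same-type territories it stays and retries the
#' next day. The streak resets after a successful move; the kill counter
#' carries over.
#'
#' @param predator A [new_predator()] object.
#' @param landscape [build_landscape()] object (bounds).
#' @param others Data frame of same-type territory centres `x`, `y`,
#'   `side`; may be empty.
#' @param n_candidates Number of random candidate centres examined.
#' @return The (possibly moved) predator; `$moved` reports the outcome.
#' @export
maybe_disperse <- function(predator, landscape, others = NULL,
                           n_candidates = 12L) {
  predator$moved <- FALSE
  if (predator$failure_streak < predator$params$failures_before_dispersal) {
    return(predator)
  }
  d <- max(1L, as.integer(round(predator$params$max_dispersal_m /
                                  landscape$cell_size_m)))
  off <- (predator$side - 1L) %/% 2L
  for (k in seq_len(n_candidates)) {
    cx <- predator$x + sample.int(2L * d + 1L, 1L) - d - 1L
    cy <- predator$y + sample.int(2L * d + 1L, 1L) - d - 1L
    x0 <- cx - off
    y0 <- cy - off
    if (x0 < 0L || y0 < 0L || x0 + predator$side > landscape$width ||
        y0 + predator$side > landscape$height) {
      next
    }
    if (!is.null(others) && nrow(others) > 0L) {
      cand <- territory(cx, cy, predator$side)
      blocked <- any(vapply(seq_len(nrow(others)), function(i) {
        territory_overlap(
          territory(others$x[i], others$y[i], others$side[i]), cand
        ) > 0
      }, logical(1)))
      if (blocked) next
    }
    predator$x <- cx
    predator$y <- cy
    predator$failure_streak <- 0L
    predator$moved <- TRUE
    break
  }
  predator
}

#' Year-end survival evaluation
#'
#' A predator survives the year if it consumed at least its survival
#' threshold of voles; the annual counter then resets (its value is kept
#' as last year's kills, which drives spring reproduction).
#'
#' @param predator A [new_predator()] object.
#' @return The updated predator with `$alive` set.
#' @export
annual_survival <- function(predator) {
  predator$alive <- predator$kills_this_year >= predator$params$survival_threshold
  if (predator$alive) {
    predator$kills_last_year <- predator$kills_this_year
  }
  predator$kills_this_year <- 0L
  predator
}

#' Spring reproduction
#'
#' Offspring number is `floor(last year's kills / reproductive
#' threshold)`, capped at the type's litter-size ceiling
#' (`max_offspring`). Each offspring is recruited into a non-overlapping
#' territory within the parent's dispersal range, or discarded when no
#' site fits, so recruitment is also capped by territory space.
#'
#' @param predator A surviving [new_predator()] object.
#' @param landscape [build_landscape()] object.
#' @param others Data frame of same-type territories (`x`, `y`, `side`)
#'   already in place, including the parent's.
#' @param n_candidates Placement attempts per offspring.
#' @return List of recruited `predator` objects (possibly empty).
#' @export
spring_reproduction <- function(predator, landscape, others = NULL,
                                n_candidates = 12L) {
  n_off <- min(
    floor(predator$kills_last_year /
            predator$params$reproductive_threshold),
    predator$params$max_offspring
  )
  recruits <- list()
  if (n_off <= 0 || !predator$alive) {
    return(recruits)
  }
  occupied <- if (is.null(others)) {
    tibble(x = integer(), y = integer(), side = integer())
  } else {
    tibble(x = others$x, y = others$y, side = others$side)
  }
  d <- max(1L, as.integer(round(predator$params$max_dispersal_m /
                                  landscape$cell_size_m)))
  off <- (predator$side - 1L) %/% 2L
  for (i in seq_len(n_off)) {
    for (k in seq_len(n_candidates)) {
      cx <- predator$x + sample.int(2L * d + 1L, 1L) - d - 1L
      cy <- predator$y + sample.int(2L * d + 1L, 1L) - d - 1L
      x0 <- cx - off
      y0 <- cy - off
      if (x0 < 0L || y0 < 0L || x0 + predator$side > landscape$width ||
          y0 + predator$side > landscape$height) {
        next
      }
      cand <- territory(cx, cy, predator$side)
      blocked <- nrow(occupied) > 0L && any(vapply(
        seq_len(nrow(occupied)),
        function(j) {
          territory_overlap(
            territory(occupied$x[j], occupied$y[j], occupied$side[j]), cand
          ) > 0
        }, logical(1)
      ))
      if (!blocked) {
        recruits[[length(recruits) + 1L]] <-
          new_predator(predator$type, cx, cy, predator$params,
                       landscape$cell_size_m)
        occupied <- bind_rows(
          occupied,
          tibble(x = cx, y = cy, side = predator$side)
        )
        break
      }
    }
  }
  recruits
}

#' Predation diagnostics from a per-predator daily log
#'
#' Computes the two fragmentation diagnostics: the fraction of predator
#' days without a successful kill, and the predation rate (kills per
#' vole-exposure day, where exposure counts each vole present in a
#' predator's territory on a given day).
#'
#' @param log A data frame with one row per predator-day: columns
#'   `predator`, `day`, `kills`, `exposure`.
#' @return One-row tibble: `failure_day_fraction`, `predation_rate`,
#'   `kills`, `exposure`, `predator_days`. With an empty log the
#'   fractions are `NA` (no predators -> undefined).
#' @export
predation_diagnostics <- function(log) {
  if (is.null(log) || nrow(log) == 0L) {
    return(tibble(
      failure_day_fraction = NA_real_, predation_rate = NA_real_,
      kills = 0L, exposure = 0, predator_days = 0L
    ))
  }
  tibble(
    failure_day_fraction = mean(log$kills == 0),
    predation_rate = ifelse(sum(log$exposure) > 0,
      sum(log$kills) / sum(log$exposure), NA_real_
    ),
    kills = sum(log$kills),
    exposure = sum(log$exposure),
    predator_days = nrow(log)
  )
}
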