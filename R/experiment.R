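# Factorial experiment driver: run the 36-scenario grid, collect
# per-replicate endpoints, and decompose endpoint variance by source.

#' Run a scenario grid and collect per-replicate endpoints
#'
#' Runs every scenario in `grid` (by default the full 3 x 4 x 3
#' factorial) and computes the five endpoints per replicate from the
#' annual census series: log mean population size, amplitude, cycle
#' length, and the AR(2) direct and delayed density-dependence
#' coefficients. The result is a balanced endpoint table ready for
#' [anova_decompose()].
#'
#' @param grid A [scenario_grid()] tibble (or a filtered subset of one).
#' @param density Which density column to analyse:
#'   `"density_optimal_ha"` (voles per ha of optimal habitat, default) or
#'   `"density_total_ha"`.
#' @param mean_of_logs Passed to [vole_endpoints()].
#' @param progress Print a line per scenario.
#' @return Tibble, one row per scenario x replicate: factors `land`
#'   (fragmentation level, factor), `predators`, `season`, `replicate`,
#'   the endpoints, and the extinction flag.
#' @export
run_grid <- function(grid = scenario_grid(), density = "density_optimal_ha",
                     mean_of_logs = FALSE, progress = FALSE) {
  stopifnot(all(c("scenario", "config") %in% names(grid)))
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    cfg <- grid$config[[i]]
    if (progress) {
      message(sprintf(
        "scenario %d/%d: %s, %d patches, %s season",
        i, nrow(grid), cfg$predator_assembly, cfg$n_patches,
        cfg$season$length
      ))
    }
    sim <- run_scenario(cfg)
    ep <- vole_endpoints(
      sim$census, .data[[density]], .data$replicate,
      mean_of_logs = mean_of_logs
    )
    ep <- left_join(
      ep, sim$replicates[, c("replicate", "extinct")],
      by = "replicate"
    )
    mutate(ep,
      scenario = grid$scenario[i],
      land = cfg$n_patches,
      predators = cfg$predator_assembly,
      season = cfg$season$length,
      .before = 1
    )
  })
  out <- bind_rows(rows)
  out$land <- factor(out$land, levels = sort(unique(out$land)))
  out$predators <- factor(out$predators,
    levels = c("generalist", "specialist", "mixed")
  )
  out$season <- factor(out$season,
    levels = c("short", "intermediate", "long")
  )
  out
}

#' Three-way factorial ANOVA variance decomposition
#'
#' Decomposes an endpoint's variance over the three design factors and
#' all their interactions, reporting for each source its degrees of
#' freedom, sum of squares, percentage of variation accounted for
#' (adjusted R-squared contribution, `(SS - df * MSE) / SS_total * 100`,
#' floored at 0) and the F-test p-value. The design must be balanced
#' (equal replicates per cell), which makes the decomposition independent
#' of factor order and of relabelling.
#'
#' @param data Endpoint table (e.g. from [run_grid()] or
#'   [gen_grid_fixture()]).
#' @param response Response column (tidy-eval).
#' @param factors Names of the three factor columns.
#' @return Tibble of class `vc_anova`: one row per source (main effects,
#'   two-way and three-way interactions) plus a `Residual` row; columns
#'   `source`, `df`, `sumsq`, `adj_r2_pct`, `p_value`.
#' @examples
#' tab <- gen_grid_fixture(land_effect = 2, sigma = 1, seed = 7)
#' anova_decompose(tab, response)
#' @export
anova_decompose <- function(data, response,
                            factors = c("land", "predators", "season")) {
  stopifnot(length(factors) == 3, all(factors %in% names(data)))
  resp <- enquo(response)
  y <- eval_tidy(resp, data)
  if (!is.numeric(y)) {
    abort("`response` must be numeric.")
  }
  d <- data.frame(
    y = y,
    f1 = factor(data[[factors[1]]]),
    f2 = factor(data[[factors[2]]]),
    f3 = factor(data[[factors[3]]])
  )
  keep <- is.finite(d$y)
  if (!all(keep)) d <- d[keep, , drop = FALSE]
  cells <- table(d$f1, d$f2, d$f3)
  if (length(unique(as.vector(cells))) != 1L || any(cells == 0)) {
    abort("Design is unbalanced: equal replicates per factorial cell required.")
  }
  fit <- aov(y ~ f1 * f2 * f3, data = d)
  tab <- anova(fit)
  src <- rownames(tab)
  nice <- c(
    f1 = factors[1], f2 = factors[2], f3 = factors[3]
  )
  rename_src <- function(s) {
    s <- trimws(s)
    if (s == "Residuals") {
      return("Residual")
    }
    parts <- strsplit(s, ":")[[1]]
    paste(nice[parts], collapse = ":")
  }
  ss_total <- sum(tab[["Sum Sq"]])
  mse <- tab["Residuals", "Mean Sq"]
  out <- tibble(
    source = unname(vapply(src, rename_src, character(1))),
    df = as.integer(tab[["Df"]]),
    sumsq = tab[["Sum Sq"]],
    adj_r2_pct = pmax(
      0, (tab[["Sum Sq"]] - tab[["Df"]] * mse) / ss_total * 100
    ),
    p_value = tab[["Pr(>F)"]]
  )
  out$adj_r2_pct[out$source == "Residual"] <- NA_real_
  attr(out, "ss_total") <- ss_total
  attr(out, "mse") <- mse
  attr(out, "response") <- rlang::as_label(resp)
  class(out) <- c("vc_anova", class(out))
  out
}
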