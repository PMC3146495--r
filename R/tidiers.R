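# broom-style tidiers

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an AR(2) density-dependence fit
#'
#' @param x An [fit_ar2()] object.
#' @param ... Unused.
#' @return Tibble with one row per term (`intercept`, `ar1`, `ar2`):
#'   `estimate`, `std.error`, `statistic`, `p.value`. `ar1` is on the
#'   scale chosen by the fit's `convention`.
#' @export
tidy.ar2_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  out <- tibble(
    term = c("intercept", "ar1", "ar2"),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
  if (x$convention == "royama") {
    out$estimate[out$term == "ar1"] <-
      out$estimate[out$term == "ar1"] - 1
  }
  out
}

#' @rdname tidy.ar2_fit
#' @return `glance()`: one-row tibble with `n_obs`, `sigma2`,
#'   `r.squared`, `convention`.
#' @export
glance.ar2_fit <- function(x, ...) {
  tibble(
    n_obs = x$n_obs,
    sigma2 = x$sigma2,
    r.squared = summary(x$fit)$r.squared,
    convention = x$convention
  )
}

#' Tidy / summarise an ANOVA variance decomposition
#'
#' @param x An [anova_decompose()] table.
#' @param ... Unused.
#' @return `tidy()` returns the table itself (it is already tidy);
#'   `glance()` a one-row tibble with the total SS, residual mean square
#'   and the response name.
#' @export
tidy.vc_anova <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.vc_anova
#' @export
glance.vc_anova <- function(x, ...) {
  tibble(
    ss_total = attr(x, "ss_total"),
    mse = attr(x, "mse"),
    response = attr(x, "response"),
    explained_pct = sum(x$adj_r2_pct, na.rm = TRUE)
  )
}
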