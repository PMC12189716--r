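.check_age_domain <- function(t, t0) {
  if (any(t < t0)) {
    stop("age t must be >= t0 (", signif(t0, 6), ")", call. = FALSE)
  }
}

#' Mean body length at age under the VBGF
#'
#' @param vbgf a `"vbgf_fit"`.
#' @param t age in years, `t >= t0` (vectorised).
#' @return body length, mm.
#' @export
length_at_age <- function(vbgf, t) {
  stopifnot(inherits(vbgf, "vbgf_fit"))
  .check_age_domain(t, vbgf$t0)
  vbgf$linf * (1 - exp(-vbgf$k * (t - vbgf$t0)))
}

#' Mean body weight at age under the derived weight growth curve
#'
#' @param wg a `"weight_growth"`.
#' @param t age in years, `t >= t0` (vectorised).
#' @return body weight, g.
#' @export
weight_at_age <- function(wg, t) {
  stopifnot(inherits(wg, "weight_growth"))
  .check_age_domain(t, wg$t0)
  wg$winf * (1 - exp(-wg$k * (t - wg$t0)))^wg$b
}

#' Growth rate and acceleration curves
#'
#' First and second derivatives of the length and weight growth curves:
#' \itemize{
#'   \item `growth_rate_length`: dL/dt = L_inf k exp(-k (t - t0)), mm/yr.
#'   \item `growth_accel_length`: d2L/dt2 = -L_inf k^2 exp(-k (t - t0)),
#'     mm/yr^2 (always negative: length growth only decelerates).
#'   \item `growth_rate_weight`: dW/dt = b W_inf k exp(-k tau)
#'     (1 - exp(-k tau))^(b-1) with tau = t - t0, g/yr; maximal at the
#'     inflection-point age.
#'   \item `growth_accel_weight`: d2W/dt2 = b W_inf k^2 exp(-k tau)
#'     (1 - exp(-k tau))^(b-2) (b exp(-k tau) - 1), g/yr^2; changes sign
#'     exactly once, at the inflection-point age.
#' }
#'
#' @param vbgf a `"vbgf_fit"`.
#' @param wg a `"weight_growth"`.
#' @param t age in years, `t >= t0` (vectorised).
#' @return rate or acceleration at `t`, in the units above.
#' @name growth_derivatives
NULL

#' @rdname growth_derivatives
#' @export
growth_rate_length <- function(vbgf, t) {
  stopifnot(inherits(vbgf, "vbgf_fit"))
  .check_age_domain(t, vbgf$t0)
  vbgf$linf * vbgf$k * exp(-vbgf$k * (t - vbgf$t0))
}

#' @rdname growth_derivatives
#' @export
growth_accel_length <- function(vbgf, t) {
  stopifnot(inherits(vbgf, "vbgf_fit"))
  .check_age_domain(t, vbgf$t0)
  -vbgf$linf * vbgf$k^2 * exp(-vbgf$k * (t - vbgf$t0))
}

#' @rdname growth_derivatives
#' @export
growth_rate_weight <- function(wg, t) {
  stopifnot(inherits(wg, "weight_growth"))
  .check_age_domain(t, wg$t0)
  u <- exp(-wg$k * (t - wg$t0))
  wg$b * wg$winf * wg$k * u * (1 - u)^(wg$b - 1)
}

#' @rdname growth_derivatives
#' @export
growth_accel_weight <- function(wg, t) {
  stopifnot(inherits(wg, "weight_growth"))
  .check_age_domain(t, wg$t0)
  u <- exp(-wg$k * (t - wg$t0))
  wg$b * wg$winf * wg$k^2 * u * (1 - u)^(wg$b - 2) * (wg$b * u - 1)
}

#' Inflection-point age of the weight growth curve
#'
#' Age at which the weight growth rate dW/dt is maximal:
#' t_i = ln(b)/k + t0. Requires b > 1 (otherwise the weight curve has no
#' inflection).
#'
#' @param b allometry exponent (> 1).
#' @param k growth coefficient, 1/yr.
#' @param t0 theoretical age at zero length, yr.
#' @return inflection-point age, years.
#' @export
inflection_age <- function(b, k, t0) {
  stopifnot(is.finite(b), is.finite(k), is.finite(t0), k > 0)
  if (b <= 1) {
    stop("weight growth curve has no inflection point for b <= 1",
         call. = FALSE)
  }
  log(b) / k + t0
}

#' Critical age of an unfished cohort
#'
#' Age at which the total biomass of an unfished cohort peaks (growth in
#' individual weight exactly offsets natural mortality):
#' t_c = \[k t0 - ln(M) + ln(b k + M)\] / k. Harvesting well after t_c wastes
#' growth potential; harvesting well before wastes recruits.
#'
#' @param k growth coefficient, 1/yr.
#' @param t0 theoretical age at zero length, yr.
#' @param b allometry exponent.
#' @param M natural mortality coefficient, 1/yr (> 0).
#' @return critical age, years.
#' @export
critical_age <- function(k, t0, b, M) {
  stopifnot(is.finite(k), k > 0, is.finite(t0), is.finite(b))
  if (!is.finite(M) || M <= 0) {
    stop("natural mortality M must be strictly positive", call. = FALSE)
  }
  (k * t0 - log(M) + log(b * k + M)) / k
}

#' Growth performance index phi-prime
#'
#' phi = log10(k) + 2 log10(L_inf), with L_inf in millimetres. phi combines
#' the growth coefficient and asymptotic length into a single index that is
#' comparable across populations and species; note that quoting L_inf in cm
#' instead of mm shifts phi by exactly -2.
#'
#' @param k growth coefficient, 1/yr.
#' @param linf asymptotic body length, mm.
#' @return dimensionless index (log10 scale, mm-based).
#' @export
growth_performance_index <- function(k, linf) {
  stopifnot(is.finite(k), k > 0, is.finite(linf), linf > 0)
  log10(k) + 2 * log10(linf)
}

#' Summary growth quantities for one population
#'
#' Bundles the inflection-point age, critical age and growth performance
#' index derived from a fitted (or injected) growth parameter set.
#'
#' @param vbgf a `"vbgf_fit"`.
#' @param b allometry exponent (from the length-weight fit).
#' @param M natural mortality, 1/yr; needed for the critical age (may be `NA`
#'   to skip it).
#' @return object of class `"growth_summary"`: list with `t_i`, `t_c`, `phi`.
#' @export
growth_summary <- function(vbgf, b, M = NA_real_) {
  stopifnot(inherits(vbgf, "vbgf_fit"))
  t_c <- if (is.na(M)) NA_real_ else critical_age(vbgf$k, vbgf$t0, b, M)
  structure(list(t_i = inflection_age(b, vbgf$k, vbgf$t0),
                 t_c = t_c,
                 phi = growth_performance_index(vbgf$k, vbgf$linf)),
            class = "growth_summary")
}

#' @export
print.growth_summary <- function(x, ...) {
  cat(sprintf("Growth summary: t_i = %.2f yr, t_c = %.2f yr, phi = %.2f\n",
              x$t_i, x$t_c, x$phi))
  invisible(x)
}
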