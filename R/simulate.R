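#' Configuration of a synthetic exploited population
#'
#' Describes the generative model the assessment estimators assume: an
#' equilibrium population with constant recruitment, ages distributed as a
#' truncated exponential with total mortality rate `Z` above the recruitment
#' age, lengths on a von Bertalanffy mean curve with multiplicative normal
#' noise, weights on the allometric curve with multiplicative lognormal
#' noise, a fixed sex ratio, and (optionally, for catches) gear selectivity.
#'
#' Supply either `Z` directly or both `M` and `F_` (then Z = M + F).
#'
#' @param linf,k,t0 true VBGF parameters (mm, 1/yr, yr).
#' @param lw_a,lw_b true length-weight coefficients (W in g, L in mm).
#' @param Z total mortality, 1/yr; alternative to `M` + `F_`.
#' @param M,F_ natural and fishing mortality, 1/yr.
#' @param recruitment_age age at which fish enter the modelled population, yr.
#' @param max_age truncation age of the age distribution, yr (may be `Inf`).
#' @param length_cv coefficient of variation of length about the mean curve
#'   (normal, truncated at 3 sigma to preserve positivity).
#' @param weight_cv coefficient of variation of weight about the allometric
#'   curve (lognormal, mean 1).
#' @param sex_ratio_female probability a fish is female.
#' @param n number of fish.
#' @param seed integer seed; identical config + seed gives identical records.
#' @param group_id label stamped on the generated records.
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(linf, k, t0, lw_a, lw_b,
                       Z = NULL, M = NULL, F_ = NULL,
                       recruitment_age = 0, max_age = 50,
                       length_cv = 0.08, weight_cv = 0.1,
                       sex_ratio_female = 0.5, n = 1000L, seed = 1L,
                       group_id = "SIM") {
  if (is.null(Z)) {
    if (is.null(M) || is.null(F_)) {
      stop("supply either Z or both M and F_", call. = FALSE)
    }
    Z <- M + F_
  }
  stopifnot(is.finite(linf), linf > 0, is.finite(k), k > 0, is.finite(t0),
            is.finite(lw_a), lw_a > 0, is.finite(lw_b), lw_b > 0,
            is.finite(Z), Z > 0,
            recruitment_age >= 0, max_age > recruitment_age,
            length_cv >= 0, length_cv < 1 / 3,
            weight_cv >= 0,
            sex_ratio_female >= 0, sex_ratio_female <= 1,
            n >= 1, is.finite(seed))
  structure(list(linf = linf, k = k, t0 = t0, lw_a = lw_a, lw_b = lw_b,
                 Z = Z, M = M, F_ = F_,
                 recruitment_age = recruitment_age, max_age = max_age,
                 length_cv = length_cv, weight_cv = weight_cv,
                 sex_ratio_female = sex_ratio_female,
                 n = as.integer(n), seed = as.integer(seed),
                 group_id = group_id),
            class = "sim_config")
}

#' Simulate an individual-based fish population
#'
#' Draws `n` fish from the equilibrium model described by a [sim_config()].
#' Continuous ages come from the exponential survival curve truncated to
#' \[recruitment_age, max_age\] (inverse-CDF sampling); the reported `age`
#' column is the integer annulus count (floor of the continuous age), while
#' the continuous age is retained in `age_true` for oracle computations.
#' Length noise is multiplicative normal with the configured CV, clamped at
#' three standard deviations; weight noise is mean-one lognormal.
#'
#' @param config a `"sim_config"`.
#' @return data.frame of fish records (`group_id`, `sex`, `age`, `length_mm`,
#'   `weight_g`) plus the bookkeeping column `age_true`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n

  # truncated exponential ages via inverse CDF
  u <- stats::runif(n)
  span_mass <- if (is.finite(config$max_age)) {
    1 - exp(-config$Z * (config$max_age - config$recruitment_age))
  } else 1
  age_true <- config$recruitment_age - log(1 - u * span_mass) / config$Z

  mean_len <- config$linf * (1 - exp(-config$k * (age_true - config$t0)))
  eps <- stats::rnorm(n)
  eps <- pmin(pmax(eps, -3), 3)
  length_mm <- mean_len * (1 + config$length_cv * eps)

  mean_wt <- config$lw_a * length_mm^config$lw_b
  if (config$weight_cv > 0) {
    sdlog <- sqrt(log(1 + config$weight_cv^2))
    weight_g <- mean_wt * stats::rlnorm(n, meanlog = -sdlog^2 / 2,
                                        sdlog = sdlog)
  } else {
    weight_g <- mean_wt
  }

  sex <- ifelse(stats::runif(n) < config$sex_ratio_female, "female", "male")

  data.frame(group_id = config$group_id,
             sex = sex,
             age = as.integer(floor(age_true)),
             length_mm = length_mm,
             weight_g = weight_g,
             age_true = age_true,
             stringsAsFactors = FALSE)
}

#' Apply gear selectivity to a simulated population
#'
#' Knife-edge selectivity retains every fish with `length_mm >= lc`;
#' logistic selectivity retains each fish independently with probability
#' 1/(1 + exp(-ln(19) (L - L50)/(L95 - L50))), converging to the knife edge
#' as L95 approaches L50.
#'
#' @param population data.frame of fish records (e.g. from
#'   [simulate_population()]).
#' @param selectivity list: either `list(type = "knife_edge", lc = <mm>)` or
#'   `list(type = "logistic", l50 = <mm>, l95 = <mm>)`.
#' @return the retained subset of `population`.
#' @export
simulate_catch <- function(population, selectivity) {
  stopifnot(is.list(selectivity), !is.null(selectivity$type))
  L <- population$length_mm
  keep <- switch(
    selectivity$type,
    knife_edge = L >= selectivity$lc,
    logistic = {
      stopifnot(selectivity$l95 > selectivity$l50)
      p <- 1 / (1 + exp(-log(19) * (L - selectivity$l50) /
                          (selectivity$l95 - selectivity$l50)))
      stats::runif(length(L)) < p
    },
    stop("unknown selectivity type: ", selectivity$type, call. = FALSE))
  population[keep, , drop = FALSE]
}
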