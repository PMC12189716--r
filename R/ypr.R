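#' Beverton-Holt relative yield per recruit
#'
#' Evaluates the knife-edge relative yield-per-recruit
#' Y'/R = E U^(M/k) \[1 - 3U/(1 + m) + 3U^2/(1 + 2m) - U^3/(1 + 3m)\]
#' with U = 1 - L_c/L_inf and m = k/Z = (1 - E) / (M/k). Writing the model
#' as a function of the exploitation rate E alone uses Z = M/(1 - E), the
#' standard relative-yield substitution. The expression assumes cubic
#' length-weight allometry (b = 3).
#'
#' @param E exploitation rate, in \[0, 1) (vectorised).
#' @param U fraction of growth remaining at first capture, 1 - L_c/L_inf,
#'   in (0, 1\].
#' @param M_over_k ratio of natural mortality to the growth coefficient.
#' @return dimensionless Y'/R.
#' @export
relative_yield_per_recruit <- function(E, U, M_over_k) {
  stopifnot(all(E >= 0), all(U > 0), all(U <= 1), M_over_k > 0)
  if (any(E >= 1)) {
    stop("exploitation rate E must be below 1", call. = FALSE)
  }
  m <- (1 - E) / M_over_k
  E * U^M_over_k *
    (1 - 3 * U / (1 + m) + 3 * U^2 / (1 + 2 * m) - U^3 / (1 + 3 * m))
}

#' Beverton-Holt relative biomass per recruit
#'
#' B'/R = (Y'/R)/F with F = Z - M = M E/(1 - E). The quotient is 0/0 at
#' E = 0, so the implementation uses the algebraically equivalent form
#' B'/R = (1/k) U^(M/k) sum_n Omega_n U^n / (M/k/(1 - E) + n),
#' Omega = (1, -3, 3, -1), which is finite everywhere on \[0, 1) and equals
#' the analytic limit at E = 0. Units are relative (1/yr^-1 scaled by the
#' recruit weight normalisation).
#'
#' @inheritParams relative_yield_per_recruit
#' @param M natural mortality, 1/yr.
#' @param k growth coefficient, 1/yr.
#' @return relative B'/R.
#' @export
relative_biomass_per_recruit <- function(E, U, M, k) {
  stopifnot(all(E >= 0), all(U > 0), all(U <= 1), M > 0, k > 0)
  if (any(E >= 1)) {
    stop("exploitation rate E must be below 1", call. = FALSE)
  }
  M_over_k <- M / k
  zk <- M_over_k / (1 - E)  # Z/k
  (1 / k) * U^M_over_k *
    (1 / zk - 3 * U / (zk + 1) + 3 * U^2 / (zk + 2) - U^3 / (zk + 3))
}

#' Configuration for a per-recruit analysis
#'
#' @param linf asymptotic body length, mm.
#' @param k growth coefficient, 1/yr.
#' @param M natural mortality, 1/yr.
#' @param lc length at first capture, mm (0 < lc < linf).
#' @param E_step resolution of the exploitation-rate grid on \[0, 0.999\].
#' @param lc_ratio_range range of L_c/L_inf spanned by the isopleth grid.
#' @param lc_steps number of L_c grid points for the isopleth.
#' @return object of class `"ypr_config"`.
#' @export
ypr_config <- function(linf, k, M, lc, E_step = 0.001,
                       lc_ratio_range = c(0.1, 0.6), lc_steps = 51) {
  stopifnot(is.finite(linf), linf > 0, is.finite(k), k > 0,
            is.finite(M), M > 0, is.finite(lc), lc > 0, lc < linf,
            E_step > 0, E_step <= 0.05,
            length(lc_ratio_range) == 2L, all(lc_ratio_range > 0),
            all(lc_ratio_range < 1), lc_steps >= 2)
  structure(list(linf = linf, k = k, M = M, lc = lc, E_step = E_step,
                 lc_ratio_range = sort(lc_ratio_range), lc_steps = lc_steps),
            class = "ypr_config")
}

#' Reference exploitation rates of the per-recruit curves
#'
#' Computes the three standard reference points:
#' \itemize{
#'   \item `E_max`: the exploitation rate maximising Y'/R (grid scan followed
#'     by golden-section refinement, tolerance 1e-5).
#'   \item `E_10`: where the marginal yield dY'/R / dE falls to one tenth of
#'     its value at E = 0 (central differences, step 1e-5), the conventional
#'     "optimal" rate.
#'   \item `E_50`: where B'/R falls to half its unexploited value (root
#'     bracketing, tolerance 1e-6).
#' }
#'
#' @param config a `"ypr_config"`.
#' @return named list with `E_max`, `E_10`, `E_50`.
#' @export
reference_points <- function(config) {
  stopifnot(inherits(config, "ypr_config"))
  U <- 1 - config$lc / config$linf
  mk <- config$M / config$k
  yield <- function(E) relative_yield_per_recruit(E, U, mk)
  biomass <- function(E) relative_biomass_per_recruit(E, U, config$M, config$k)

  E_grid <- seq(0, 0.999, by = config$E_step)
  y_grid <- yield(E_grid)
  # unimodality check: interior local maxima beyond the global one
  d <- diff(y_grid)
  n_peaks <- sum(d[-length(d)] > 0 & d[-1L] < 0)
  if (n_peaks > 1L) {
    warning("Y'/R grid scan is not unimodal; using the global grid argmax",
            call. = FALSE)
    E_max <- E_grid[which.max(y_grid)]
  } else {
    i <- which.max(y_grid)
    lo <- E_grid[max(i - 1L, 1L)]
    hi <- E_grid[min(i + 1L, length(E_grid))]
    E_max <- stats::optimize(yield, c(lo, hi), maximum = TRUE,
                             tol = 1e-5)$maximum
  }

  h <- 1e-5
  slope <- function(E) (yield(E + h) - yield(E - h)) / (2 * h)
  slope0 <- (yield(2 * h) - yield(0)) / (2 * h)
  g <- function(E) slope(E) - 0.1 * slope0
  E_10 <- stats::uniroot(g, lower = h, upper = E_max, tol = 1e-6)$root

  b0 <- biomass(0)
  E_50 <- stats::uniroot(function(E) biomass(E) - 0.5 * b0,
                         lower = 0, upper = 0.9999, tol = 1e-6)$root

  list(E_max = E_max, E_10 = E_10, E_50 = E_50)
}

#' Relative yield- and biomass-per-recruit analysis
#'
#' Evaluates the Y'/R and B'/R curves over the exploitation-rate grid and
#' locates the three reference points.
#'
#' @param config a `"ypr_config"`.
#' @return object of class `"ypr_result"`: list with `curve` (data.frame
#'   `E`, `YpR`, `BpR`), `ref` (list `E_max`, `E_10`, `E_50`) and `config`.
#' @export
ypr_analysis <- function(config) {
  stopifnot(inherits(config, "ypr_config"))
  U <- 1 - config$lc / config$linf
  mk <- config$M / config$k
  E <- seq(0, 0.999, by = config$E_step)
  curve <- data.frame(
    E = E,
    YpR = relative_yield_per_recruit(E, U, mk),
    BpR = relative_biomass_per_recruit(E, U, config$M, config$k))
  structure(list(curve = curve, ref = reference_points(config),
                 config = config),
            class = "ypr_result")
}

#' @export
print.ypr_result <- function(x, ...) {
  cat("Relative yield/biomass per recruit\n")
  cat(sprintf("  L_c/L_inf = %.3f, M/k = %.3f\n",
              x$config$lc / x$config$linf, x$config$M / x$config$k))
  cat(sprintf("  E_max = %.3f, E_10 = %.3f, E_50 = %.3f\n",
              x$ref$E_max, x$ref$E_10, x$ref$E_50))
  invisible(x)
}

#' Yield isopleth grid over exploitation rate and capture length
#'
#' Full factorial evaluation of Y'/R over a grid of exploitation rates and
#' lengths at first capture, for isopleth (contour) diagrams.
#'
#' @param linf asymptotic body length, mm.
#' @param M natural mortality, 1/yr.
#' @param k growth coefficient, 1/yr.
#' @param E_grid exploitation-rate grid (default step 0.01 on \[0, 0.99\]).
#' @param lc_ratio_grid grid of L_c/L_inf ratios (default 0.1-0.6).
#' @return object of class `"ypr_isopleth"`: list with `YpR` (matrix, rows =
#'   E, columns = L_c), `E`, `lc_mm`, `lc_ratio`.
#' @export
isopleth_grid <- function(linf, M, k,
                          E_grid = seq(0, 0.99, by = 0.01),
                          lc_ratio_grid = seq(0.1, 0.6, length.out = 51)) {
  stopifnot(all(E_grid >= 0), all(E_grid < 1),
            all(lc_ratio_grid > 0), all(lc_ratio_grid < 1))
  mk <- M / k
  Y <- outer(E_grid, lc_ratio_grid,
             function(E, r) relative_yield_per_recruit(E, 1 - r, mk))
  dimnames(Y) <- list(E = formatC(E_grid, format = "g"),
                      lc = formatC(lc_ratio_grid * linf, format = "g"))
  structure(list(YpR = Y, E = E_grid, lc_mm = lc_ratio_grid * linf,
                 lc_ratio = lc_ratio_grid),
            class = "ypr_isopleth")
}

#' Serialise an isopleth grid to long format
#'
#' @param x a `"ypr_isopleth"`.
#' @return data.frame with columns `E`, `lc_mm`, `lc_ratio`, `YpR`.
#' @export
as.data.frame.ypr_isopleth <- function(x, ...) {
  data.frame(E = rep(x$E, times = length(x$lc_mm)),
             lc_mm = rep(x$lc_mm, each = length(x$E)),
             lc_ratio = rep(x$lc_ratio, each = length(x$E)),
             YpR = as.vector(x$YpR))
}

#' Capture length maximising yield at a fixed L_c/L_inf ratio
#'
#' Reports the L_c corresponding to a chosen ratio of the asymptotic length
#' (the yield-isopleth optimum is conventionally quoted at L_c/L_inf = 0.6),
#' rounded to the nearest millimetre.
#'
#' @param linf asymptotic body length, mm.
#' @param ratio L_c/L_inf ratio.
#' @return L_c in whole mm.
#' @export
optimal_lc_at_ratio <- function(linf, ratio = 0.6) {
  stopifnot(is.finite(linf), linf > 0, ratio >= 0, ratio < 1)
  round(ratio * linf)
}

#' Recommended minimum catchable length
#'
#' Averages three management-relevant lengths: the yield-maximising capture
#' length (from the isopleth analysis), the body length at the
#' inflection-point age, and the body length at the critical age. The mean
#' of the three indices, rounded to the nearest millimetre, is the advised
#' minimum catchable length.
#'
#' @param vbgf a `"vbgf_fit"`.
#' @param summary a `"growth_summary"` carrying `t_i` and `t_c`.
#' @param lc_star yield-maximising capture length, mm (e.g. from
#'   [optimal_lc_at_ratio()]).
#' @return recommended minimum catchable length, whole mm, with attribute
#'   `"components"` holding the three indices.
#' @export
recommend_min_catch_length <- function(vbgf, summary, lc_star) {
  stopifnot(inherits(vbgf, "vbgf_fit"), inherits(summary, "growth_summary"),
            is.finite(lc_star), lc_star > 0)
  comps <- c(lc_star = lc_star,
             length_at_ti = length_at_age(vbgf, summary$t_i),
             length_at_tc = length_at_age(vbgf, summary$t_c))
  out <- round(mean(comps))
  attr(out, "components") <- comps
  out
}
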