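#' Beverton-Holt mean-length total mortality estimator
#'
#' Z = k (L_inf - L_mean) / (L_mean - L_c), where L_mean is the mean body
#' length of the catch above the length at first capture L_c. The estimator
#' is exact for an equilibrium population with constant recruitment, von
#' Bertalanffy growth and constant total mortality Z above the age at first
#' capture.
#'
#' @param k growth coefficient, 1/yr.
#' @param linf asymptotic body length, mm.
#' @param l_mean mean body length of the retained catch, mm.
#' @param l_c length at first capture, mm.
#' @return total mortality coefficient Z, 1/yr.
#' @export
beverton_holt_Z <- function(k, linf, l_mean, l_c) {
  stopifnot(is.finite(k), k > 0)
  if (!(l_c < l_mean)) {
    stop("mean length must exceed the length at first capture (L_c < L_mean)",
         call. = FALSE)
  }
  if (!(l_mean < linf)) {
    stop("mean length must lie below the asymptotic length (L_mean < L_inf)",
         call. = FALSE)
  }
  k * (linf - l_mean) / (l_mean - l_c)
}

#' Pauly empirical natural mortality
#'
#' Pauly's regression of natural mortality M on growth parameters and water
#' temperature. The default `"base10_cm"` variant is the standard published
#' form: log10 M = -0.0066 - 0.279 log10(L_inf\[cm\]) + 0.6543 log10(k) +
#' 0.4634 log10(T), with L_inf converted from mm to cm. The
#' `"natural_log_printed"` variant evaluates the same coefficients as natural
#' logarithms with L_inf in mm; it is provided because the formula circulates
#' in that form, but it yields markedly different (usually implausible)
#' values. The variant used is recorded on the result.
#'
#' @param linf asymptotic body length, mm.
#' @param k growth coefficient, 1/yr.
#' @param temperature mean annual water temperature, degrees C.
#' @param variant `"base10_cm"` (default) or `"natural_log_printed"`.
#' @return natural mortality M, 1/yr, with attribute `"variant"`.
#' @export
pauly_M <- function(linf, k, temperature, variant = c("base10_cm",
                                                      "natural_log_printed")) {
  variant <- match.arg(variant)
  stopifnot(is.finite(linf), linf > 0, is.finite(k), k > 0,
            is.finite(temperature), temperature > 0)
  M <- if (variant == "base10_cm") {
    10^(-0.0066 - 0.279 * log10(linf / 10) + 0.6543 * log10(k) +
          0.4634 * log10(temperature))
  } else {
    exp(-0.0066 - 0.279 * log(linf) + 0.6543 * log(k) +
          0.4634 * log(temperature))
  }
  attr(M, "variant") <- variant
  M
}

#' Fishing mortality and exploitation rate
#'
#' F = Z - M and E = F/Z. A negative F (Z below the assumed natural
#' mortality) signals inconsistent inputs; it is reported with a warning,
#' never silently clamped.
#'
#' @param Z total mortality, 1/yr (> 0).
#' @param M natural mortality, 1/yr.
#' @param F_ fishing mortality, 1/yr.
#' @return `fishing_mortality()`: F in 1/yr; `exploitation_rate()`: E,
#'   dimensionless.
#' @export
fishing_mortality <- function(Z, M) {
  if (!is.finite(Z) || Z <= 0) {
    stop("total mortality Z must be strictly positive", call. = FALSE)
  }
  F_ <- Z - M
  if (any(F_ < 0)) {
    warning("negative fishing mortality (Z < M): inputs are inconsistent",
            call. = FALSE)
  }
  F_
}

#' @rdname fishing_mortality
#' @export
exploitation_rate <- function(F_, Z) {
  if (any(!is.finite(Z) | Z <= 0)) {
    stop("total mortality Z must be strictly positive", call. = FALSE)
  }
  F_ / Z
}

#' Reliability diagnostics for mortality estimates
#'
#' Three standard screening ratios:
#' \itemize{
#'   \item `exp_neg_k` = exp(-k), the annual fraction of the remaining growth
#'     gap retained; the growth equation is considered reliable when < 1.
#'   \item `M_over_K` = M/k; empirically credible natural mortality falls in
#'     1-2.5.
#'   \item `Z_over_K` = Z/k; below 3 the death process is dominated by
#'     natural causes, above 3 by fishing.
#' }
#'
#' @param k growth coefficient, 1/yr.
#' @param M natural mortality, 1/yr.
#' @param Z total mortality, 1/yr.
#' @return object of class `"mortality_diagnostics"`: list of the three
#'   ratios, the logical flags `growth_reliable`, `m_reliable`, and `regime`
#'   (`"natural"`, `"fishing"` or `"balanced"`).
#' @export
mortality_diagnostics <- function(k, M, Z) {
  stopifnot(is.finite(k), k > 0, is.finite(M), M > 0, is.finite(Z), Z > 0)
  exp_neg_k <- exp(-k)
  m_over_k <- M / k
  z_over_k <- Z / k
  regime <- if (z_over_k < 3) "natural" else if (z_over_k > 3) "fishing" else
    "balanced"
  structure(list(exp_neg_k = exp_neg_k, M_over_K = m_over_k,
                 Z_over_K = z_over_k,
                 growth_reliable = exp_neg_k < 1,
                 m_reliable = m_over_k >= 1 && m_over_k <= 2.5,
                 regime = regime),
            class = "mortality_diagnostics")
}

#' @export
print.mortality_diagnostics <- function(x, ...) {
  cat(sprintf("exp(-k) = %.3f (%s), M/K = %.2f (%s), Z/K = %.2f (%s regime)\n",
              x$exp_neg_k, if (x$growth_reliable) "reliable" else "unreliable",
              x$M_over_K, if (x$m_reliable) "reliable" else "outside 1-2.5",
              x$Z_over_K, x$regime))
  invisible(x)
}

#' Estimate the length at first capture from catch lengths
#'
#' The default rule takes a low quantile of the retained lengths (5th
#' percentile) as a knife-edge L_c. The `"logistic"` option fits a logistic
#' retention curve to the ascending limb of the length-frequency
#' distribution (bin counts below the modal bin scaled by the modal count,
#' treated as retention probabilities in a binomial GLM) and returns the
#' 50%-retention length.
#'
#' @param lengths numeric vector of retained body lengths, mm.
#' @param method `"percentile"` (default) or `"logistic"`.
#' @param prob quantile used by the percentile rule.
#' @param bins number of histogram bins for the logistic rule.
#' @return estimated L_c, mm.
#' @export
estimate_lc <- function(lengths, method = c("percentile", "logistic"),
                        prob = 0.05, bins = 25) {
  method <- match.arg(method)
  stopifnot(length(lengths) >= 10, all(lengths > 0))
  if (method == "percentile") {
    return(unname(stats::quantile(lengths, probs = prob)))
  }
  h <- graphics::hist(lengths, breaks = bins, plot = FALSE)
  mode_bin <- which.max(h$counts)
  if (mode_bin < 3L) {
    stop("too few bins below the modal length for the logistic L_c estimator",
         call. = FALSE)
  }
  asc <- seq_len(mode_bin)
  p <- h$counts[asc] / h$counts[mode_bin]
  p <- pmin(p, 1)
  fit <- stats::glm(cbind(round(p * 100), 100 - round(p * 100)) ~ h$mids[asc],
                    family = stats::binomial())
  unname(-coef(fit)[1L] / coef(fit)[2L])
}

#' Full mortality assessment from catch records
#'
#' Convenience wrapper: given the retained catch of one group and its fitted
#' growth parameters, estimates L_c (unless supplied), computes the mean
#' length over fish at or above L_c (the mean-length estimator's derivation
#' requires the truncated mean), and assembles Z, M, F, E and the
#' diagnostics.
#'
#' @param records fish records of the group's catch.
#' @param vbgf a `"vbgf_fit"`.
#' @param temperature mean annual water temperature, degrees C.
#' @param lc length at first capture, mm; estimated via [estimate_lc()] when
#'   `NULL`.
#' @param pauly_variant passed to [pauly_M()].
#' @return object of class `"mortality_estimates"`: list with `Z`, `M`, `F`,
#'   `E`, `l_mean`, `l_c`, `temperature`, `pauly_variant`, `diagnostics`.
#' @export
estimate_mortality <- function(records, vbgf, temperature, lc = NULL,
                               pauly_variant = "base10_cm") {
  records <- validate_fish_records(records)
  stopifnot(inherits(vbgf, "vbgf_fit"))
  lengths <- records$length_mm
  if (is.null(lc)) lc <- estimate_lc(lengths)
  retained <- lengths[lengths >= lc]
  if (length(retained) < 2L) {
    stop("no retained lengths at or above L_c = ", signif(lc, 4),
         call. = FALSE)
  }
  l_mean <- mean(retained)
  Z <- beverton_holt_Z(vbgf$k, vbgf$linf, l_mean, lc)
  M <- pauly_M(vbgf$linf, vbgf$k, temperature, variant = pauly_variant)
  F_ <- fishing_mortality(Z, as.numeric(M))
  E <- exploitation_rate(F_, Z)
  structure(list(Z = Z, M = as.numeric(M), F = F_, E = E, l_mean = l_mean,
                 l_c = lc, temperature = temperature,
                 pauly_variant = attr(M, "variant"),
                 diagnostics = mortality_diagnostics(vbgf$k, as.numeric(M), Z)),
            class = "mortality_estimates")
}

#' @export
print.mortality_estimates <- function(x, ...) {
  cat(sprintf(
    "Mortality: Z = %.3f, M = %.3f (Pauly %s), F = %.3f, E = %.3f /yr\n",
    x$Z, x$M, x$pauly_variant, x$F, x$E))
  cat(sprintf("  L_mean = %.1f mm over L_c = %.1f mm, T = %.1f C\n",
              x$l_mean, x$l_c, x$temperature))
  print(x$diagnostics)
  invisible(x)
}
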