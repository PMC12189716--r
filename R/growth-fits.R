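#' Fit the length-weight allometry W = a L^b
#'
#' Fits the power relation between body weight (g) and body length (mm).
#' The default fit is ordinary least squares of log10(W) on log10(L), the
#' standard choice in the length-weight literature and the scale on which
#' the allometry exponent `b` is usually tested against isometry (b = 3).
#' A direct nonlinear least-squares fit on the raw scale is available via
#' `method = "nls"`.
#'
#' @param records data.frame of fish records (see [validate_fish_records()]);
#'   only `length_mm` and `weight_g` are used, sexes pooled.
#' @param method `"log10"` (default) or `"nls"`.
#' @param isometry_alpha significance level of the t-test of b = 3 used to set
#'   the isometry flag.
#' @return an object of class `"lw_fit"`: list with elements `a`, `b`, `n`,
#'   `r_squared`, `se_b`, `isometric` (logical), `p_isometry`, `method`.
#' @export
fit_length_weight <- function(records, method = c("log10", "nls"),
                              isometry_alpha = 0.05) {
  method <- match.arg(method)
  records <- validate_fish_records(records)
  L <- records$length_mm
  W <- records$weight_g
  if (length(unique(L)) < 3L) {
    stop("length-weight fit needs at least 3 records with distinct lengths",
         call. = FALSE)
  }

  if (method == "log10") {
    fit <- stats::lm(log10(W) ~ log10(L))
    b <- unname(coef(fit)[2L])
    a <- 10^unname(coef(fit)[1L])
    sm <- suppressWarnings(summary(fit))  # silence the perfect-fit notice
    se_b <- sm$coefficients[2L, 2L]
    r2 <- sm$r.squared
  } else {
    # log-scale fit seeds the raw-scale optimisation
    seed_fit <- stats::lm(log10(W) ~ log10(L))
    start <- list(a = 10^unname(coef(seed_fit)[1L]),
                  b = unname(coef(seed_fit)[2L]))
    fit <- minpack.lm::nlsLM(W ~ a * L^b, start = start,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(fit)
    a <- unname(cf["a"])
    b <- unname(cf["b"])
    se_b <- summary(fit)$coefficients["b", 2L]
    r2 <- 1 - sum(resid(fit)^2) / sum((W - mean(W))^2)
  }

  t_stat <- (b - 3) / se_b
  df <- length(L) - 2L
  p_iso <- 2 * stats::pt(abs(t_stat), df = df, lower.tail = FALSE)

  structure(list(a = a, b = b, n = length(L), r_squared = r2, se_b = se_b,
                 isometric = p_iso >= isometry_alpha, p_isometry = p_iso,
                 method = method),
            class = "lw_fit")
}

#' @export
print.lw_fit <- function(x, ...) {
  cat("Length-weight fit: W = a * L^b  (", x$method, " scale)\n", sep = "")
  cat(sprintf("  a = %.4e g/mm^b, b = %.4f (SE %.4f), n = %d, R^2 = %.4f\n",
              x$a, x$b, x$se_b, x$n, x$r_squared))
  cat(sprintf("  growth %s (p[b = 3] = %.3g)\n",
              if (x$isometric) "isometric" else "allometric", x$p_isometry))
  invisible(x)
}

# fixed multi-start table for the VBGF fit; the L_inf column is a multiplier
# of the maximum observed length
.vbgf_starts <- function(lmax) {
  data.frame(linf = lmax * c(1.05, 1.05, 1.05, 1.20, 1.05),
             k = c(0.2, 0.1, 0.4, 0.2, 0.3),
             t0 = c(-0.5, -0.5, -0.5, -1.0, 0.0))
}

#' Fit the von Bertalanffy growth function to length-at-age data
#'
#' Fits L_t = L_inf (1 - exp(-k (t - t0))) by Levenberg-Marquardt nonlinear
#' least squares with five fixed starting points (initial L_inf just above
#' the largest observed fish, initial k spanning 0.1-0.4/yr). The multi-start
#' guards against the well-known L_inf-k ridge in the VBGF likelihood
#' surface. The best residual sum of squares wins; near-ties are broken by
#' the smallest |t0|.
#'
#' @param records data.frame of fish records spanning at least 4 distinct
#'   ages; sexes pooled.
#' @param use_means fit age-class mean lengths instead of individual records.
#' @return object of class `"vbgf_fit"`: list with `linf` (mm), `k` (1/yr),
#'   `t0` (yr), `n`, `rss`, `linf_exceeds_lmax` (sanity flag: the asymptote
#'   should normally exceed the largest observed fish), `converged`,
#'   `n_starts_converged`.
#' @export
fit_vbgf <- function(records, use_means = FALSE) {
  records <- validate_fish_records(records)
  age <- records$age
  len <- records$length_mm
  if (length(unique(age)) < 4L) {
    stop("VBGF fit needs records spanning at least 4 distinct ages",
         call. = FALSE)
  }
  if (use_means) {
    len <- tapply(len, age, mean)
    age <- as.numeric(names(len))
    len <- as.numeric(len)
  }

  starts <- .vbgf_starts(max(len))
  fits <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    fits[[i]] <- tryCatch(
      minpack.lm::nlsLM(
        len ~ linf * (1 - exp(-k * (age - t0))),
        start = list(linf = starts$linf[i], k = starts$k[i], t0 = starts$t0[i]),
        lower = c(linf = 0.3 * max(len), k = 1e-4, t0 = -20),
        upper = c(linf = 20 * max(len), k = 5, t0 = min(age)),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                             ptol = 1e-12)),
      error = function(e) NULL)
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    stop("VBGF fit failed to converge from any starting point", call. = FALSE)
  }
  fits <- fits[ok]
  rss <- vapply(fits, function(f) sum(resid(f)^2), numeric(1))
  t0s <- vapply(fits, function(f) unname(coef(f)["t0"]), numeric(1))
  # near-ties on the residual broken by smallest |t0|
  best_rss <- min(rss)
  tied <- rss <= best_rss * (1 + 1e-8) + 1e-12
  best <- which(tied)[which.min(abs(t0s[tied]))]
  cf <- coef(fits[[best]])

  linf_hat <- unname(cf["linf"])
  structure(list(linf = linf_hat, k = unname(cf["k"]),
                 t0 = unname(cf["t0"]), n = length(len), rss = rss[best],
                 linf_exceeds_lmax = linf_hat > max(len),
                 converged = TRUE, n_starts_converged = sum(ok)),
            class = "vbgf_fit")
}

#' Construct a VBGF parameter set directly
#'
#' Wraps externally obtained parameters (for example published values) in the
#' same object the fitter returns, so downstream operations can be run in
#' parameters-injected mode.
#'
#' @param linf asymptotic body length, mm.
#' @param k growth coefficient, 1/yr.
#' @param t0 theoretical age at zero length, yr.
#' @return object of class `"vbgf_fit"`.
#' @export
vbgf_params <- function(linf, k, t0) {
  stopifnot(is.finite(linf), linf > 0, is.finite(k), k > 0, is.finite(t0))
  structure(list(linf = linf, k = k, t0 = t0, n = NA_integer_, rss = NA_real_,
                 linf_exceeds_lmax = NA, converged = NA,
                 n_starts_converged = NA_integer_),
            class = "vbgf_fit")
}

#' @export
print.vbgf_fit <- function(x, ...) {
  cat("von Bertalanffy growth fit: L_t = L_inf (1 - exp(-k (t - t0)))\n")
  cat(sprintf("  L_inf = %.1f mm, k = %.4f /yr, t0 = %.3f yr",
              x$linf, x$k, x$t0))
  if (!is.na(x$n)) cat(sprintf("  (n = %d, RSS = %.4g)", x$n, x$rss))
  cat("\n")
  invisible(x)
}

#' Derive the weight growth curve from length growth and allometry
#'
#' The weight growth curve W_t = W_inf (1 - exp(-k (t - t0)))^b is not refit:
#' W_inf = a L_inf^b is computed from the fitted allometry, and k, t0, b are
#' carried over unchanged.
#'
#' @param vbgf a `"vbgf_fit"`.
#' @param lw a `"lw_fit"`.
#' @return object of class `"weight_growth"`: list with `winf` (g), `k`, `t0`,
#'   `b`, `a`.
#' @export
derive_weight_growth <- function(vbgf, lw) {
  stopifnot(inherits(vbgf, "vbgf_fit"), inherits(lw, "lw_fit"))
  structure(list(winf = lw$a * vbgf$linf^lw$b, k = vbgf$k, t0 = vbgf$t0,
                 b = lw$b, a = lw$a),
            class = "weight_growth")
}

#' @export
print.weight_growth <- function(x, ...) {
  cat("Derived weight growth: W_t = W_inf (1 - exp(-k (t - t0)))^b\n")
  cat(sprintf("  W_inf = %.1f g, k = %.4f /yr, t0 = %.3f yr, b = %.4f\n",
              x$winf, x$k, x$t0, x$b))
  invisible(x)
}
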