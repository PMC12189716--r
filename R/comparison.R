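#' ANCOVA homogeneity-of-slopes test across groups
#'
#' Tests whether a bivariate relationship (length-weight, length-age or
#' weight-age) differs among groups by comparing the full-interaction linear
#' model `y ~ x * group` against the common-slope model `y ~ x + group`.
#' The interaction F statistic with its exact degrees of freedom is the
#' standard ANCOVA test of parallel slopes. For length-weight comparisons
#' both variables are log10-transformed (so the slopes are the allometry
#' exponents b); age relationships are compared on the identity scale.
#'
#' @param records data.frame of fish records from 2 or more groups, each with
#'   at least 3 points.
#' @param response one of `"weight_g"`, `"length_mm"`.
#' @param covariate one of `"length_mm"`, `"age"`.
#' @param transform `"log10"` (log10 both axes) or `"identity"`.
#' @return object of class `"ancova_result"`: list with `F_stat`, `df_num`,
#'   `df_den`, `p_value`, `slopes` (named per-group vector), `transform`.
#' @export
ancova_slopes <- function(records,
                          response = "weight_g",
                          covariate = "length_mm",
                          transform = c("log10", "identity")) {
  transform <- match.arg(transform)
  records <- validate_fish_records(records)
  stopifnot(response %in% names(records), covariate %in% names(records))

  y <- records[[response]]
  x <- records[[covariate]]
  if (transform == "log10") {
    if (any(x <= 0) || any(y <= 0)) {
      stop("log10 transform requires strictly positive response and covariate",
           call. = FALSE)
    }
    y <- log10(y)
    x <- log10(x)
  }
  g <- factor(records$group_id)
  if (nlevels(g) < 2L) {
    stop("ANCOVA needs at least 2 groups", call. = FALSE)
  }
  counts <- table(g)
  if (any(counts < 3L)) {
    stop("every group needs at least 3 records; too few in: ",
         paste(names(counts)[counts < 3L], collapse = ", "), call. = FALSE)
  }
  for (lev in levels(g)) {
    if (length(unique(x[g == lev])) < 2L) {
      stop("covariate is constant within group ", lev,
           ": design is rank deficient", call. = FALSE)
    }
  }

  full <- stats::lm(y ~ x * g)
  reduced <- stats::lm(y ~ x + g)
  tab <- stats::anova(reduced, full)
  F_stat <- tab$F[2L]
  df_num <- as.integer(tab$Df[2L])
  df_den <- as.integer(tab$Res.Df[2L])
  p <- stats::pf(F_stat, df_num, df_den, lower.tail = FALSE)

  slopes <- vapply(levels(g), function(lev) {
    unname(coef(stats::lm(y[g == lev] ~ x[g == lev]))[2L])
  }, numeric(1))

  structure(list(F_stat = F_stat, df_num = df_num, df_den = df_den,
                 p_value = p, slopes = slopes, transform = transform,
                 response = response, covariate = covariate),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA slope homogeneity: %s ~ %s (%s scale)\n",
              x$response, x$covariate, x$transform))
  cat(sprintf("  F(%d, %d) = %.3f, p = %.4g\n",
              x$df_num, x$df_den, x$F_stat, x$p_value))
  cat("  per-group slopes: ",
      paste(sprintf("%s = %.4f", names(x$slopes), x$slopes), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
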