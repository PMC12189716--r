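#' Read a run configuration from YAML
#'
#' The configuration describes the groups to assess and the per-group
#' quantities the data cannot supply: mean annual water temperature
#' (`temperature_celsius`, required unless natural mortality is injected),
#' an optional knife-edge length at first capture (`lc_mm`; estimated from
#' the catch when absent) and the Pauly variant (`pauly_variant`). Top-level
#' keys: `groups` (named list), `seed`, `E_step`, `lc_ratio` (the isopleth
#' optimum ratio, default 0.6). Unknown keys are rejected.
#'
#' @param path path to a YAML file.
#' @return validated configuration list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a configuration list (as parsed from YAML/JSON).
#' @export
as_run_config <- function(cfg) {
  allowed_top <- c("groups", "seed", "E_step", "lc_ratio")
  unknown <- setdiff(names(cfg), allowed_top)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$groups) || length(cfg$groups) == 0L ||
      is.null(names(cfg$groups))) {
    stop("configuration must define a named `groups` list", call. = FALSE)
  }
  allowed_group <- c("temperature_celsius", "lc_mm", "pauly_variant")
  for (g in names(cfg$groups)) {
    unknown <- setdiff(names(cfg$groups[[g]]), allowed_group)
    if (length(unknown) > 0L) {
      stop("unknown key(s) in group ", g, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (is.null(cfg$groups[[g]]$pauly_variant)) {
      cfg$groups[[g]]$pauly_variant <- "base10_cm"
    }
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$E_step)) cfg$E_step <- 0.001
  if (is.null(cfg$lc_ratio)) cfg$lc_ratio <- 0.6
  class(cfg) <- "run_config"
  cfg
}

.stage <- function(stage, group, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s | group %s] %s", stage, group,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full length-based assessment
#'
#' Orchestrates the whole pipeline per group: length-weight and VBGF fits,
#' derived weight growth and growth-rate/acceleration coefficient sets,
#' growth summary (inflection age, critical age, phi), mortality and
#' exploitation estimates with diagnostics, the per-recruit analysis with
#' reference points and isopleth grid, and the minimum-catchable-length
#' recommendation.
#'
#' A parameters-injected mode (`params`) accepts already-fitted or published
#' values per group — any of `linf`, `k`, `t0`, `a`, `b`, `Z`, `M` — and
#' skips the corresponding fitting or estimation stage, so published
#' parameter tables can be pushed through the downstream analysis without
#' raw records.
#'
#' @param config a `"run_config"` (see [read_run_config()]) or a plain list
#'   accepted by [as_run_config()].
#' @param records data.frame of fish records covering the configured groups;
#'   may be `NULL` when every stage is parameter-injected.
#' @param params optional named list (by group) of injected parameters.
#' @return object of class `"assessment_report"`: per-group results plus a
#'   machine-readable `manifest` (package version, seed, config hash).
#' @export
run_full_assessment <- function(config, records = NULL, params = NULL) {
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  groups <- names(config$groups)
  if (!is.null(records)) {
    records <- validate_fish_records(records, groups = groups)
  }

  results <- list()
  for (g in groups) {
    gcfg <- config$groups[[g]]
    inj <- if (is.null(params)) list() else params[[g]]
    grecs <- if (is.null(records)) NULL else
      records[records$group_id == g, , drop = FALSE]
    needs_fit <- is.null(inj$linf) || is.null(inj$k) || is.null(inj$t0) ||
      is.null(inj$a) || is.null(inj$b)
    if ((needs_fit || is.null(inj$Z)) &&
        (is.null(grecs) || nrow(grecs) == 0L)) {
      stop("group ", g, ": no records and insufficient injected parameters",
           call. = FALSE)
    }

    lw <- .stage("length_weight", g, {
      if (!is.null(inj$a) && !is.null(inj$b)) {
        structure(list(a = inj$a, b = inj$b, n = NA_integer_,
                       r_squared = NA_real_, se_b = NA_real_,
                       isometric = NA, p_isometry = NA_real_,
                       method = "injected"),
                  class = "lw_fit")
      } else fit_length_weight(grecs)
    })
    vbgf <- .stage("vbgf", g, {
      if (!is.null(inj$linf) && !is.null(inj$k) && !is.null(inj$t0)) {
        vbgf_params(inj$linf, inj$k, inj$t0)
      } else fit_vbgf(grecs)
    })
    wg <- .stage("weight_growth", g, derive_weight_growth(vbgf, lw))

    mort <- .stage("mortality", g, {
      if (!is.null(inj$Z) && !is.null(inj$M)) {
        F_ <- fishing_mortality(inj$Z, inj$M)
        structure(list(Z = inj$Z, M = inj$M, F = F_,
                       E = exploitation_rate(F_, inj$Z),
                       l_mean = NA_real_, l_c = gcfg$lc_mm %||% NA_real_,
                       temperature = gcfg$temperature_celsius %||% NA_real_,
                       pauly_variant = "injected",
                       diagnostics = mortality_diagnostics(vbgf$k, inj$M,
                                                           inj$Z)),
                  class = "mortality_estimates")
      } else {
        if (is.null(gcfg$temperature_celsius)) {
          stop("temperature_celsius missing and M not injected")
        }
        estimate_mortality(grecs, vbgf,
                           temperature = gcfg$temperature_celsius,
                           lc = gcfg$lc_mm,
                           pauly_variant = gcfg$pauly_variant)
      }
    })

    summ <- .stage("growth_summary", g, growth_summary(vbgf, lw$b, mort$M))

    # capture length for the per-recruit curves: configured value, else the
    # data-derived L_c, else a quarter of L_inf (representative of the small
    # capture sizes of unregulated gillnet fisheries)
    lc_for_ypr <- gcfg$lc_mm %||% mort$l_c
    if (is.null(lc_for_ypr) || is.na(lc_for_ypr)) {
      lc_for_ypr <- 0.25 * vbgf$linf
    }
    ypr <- .stage("ypr", g, {
      ypr_analysis(ypr_config(vbgf$linf, vbgf$k, mort$M, lc_for_ypr,
                              E_step = config$E_step))
    })
    iso <- .stage("isopleth", g, isopleth_grid(vbgf$linf, mort$M, vbgf$k))
    lc_star <- optimal_lc_at_ratio(vbgf$linf, config$lc_ratio)
    advice <- .stage("advice", g,
                     recommend_min_catch_length(vbgf, summ, lc_star))

    results[[g]] <- list(
      lw = lw, vbgf = vbgf, weight_growth = wg,
      rate_coefficients = data.frame(
        length_rate = vbgf$linf * vbgf$k,
        length_accel = -vbgf$linf * vbgf$k^2,
        weight_rate = wg$winf * wg$k * wg$b,
        weight_accel = wg$winf * wg$k^2 * wg$b),
      summary = summ, mortality = mort, ypr = ypr, isopleth = iso,
      lc_star = lc_star, recommended_min_length = advice)
  }

  structure(list(groups = results,
                 manifest = list(package = "lenstock",
                                 version = as.character(
                                   utils::packageVersion("lenstock")),
                                 seed = config$seed,
                                 config_hash = config_hash(config))),
            class = "assessment_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hash a run configuration
#'
#' MD5 of the canonical JSON serialisation, used in the report manifest so
#' any output table can be traced to the exact configuration that produced
#' it.
#'
#' @param config a configuration list.
#' @return character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Tabular summary of an assessment report
#'
#' @param object an `"assessment_report"`.
#' @param ... unused.
#' @return data.frame with one row per group: growth parameters, derived
#'   ages, phi, mortality, exploitation, reference points and the
#'   recommended minimum catchable length. Full precision; round for
#'   display.
#' @export
summary.assessment_report <- function(object, ...) {
  rows <- lapply(names(object$groups), function(g) {
    r <- object$groups[[g]]
    data.frame(group = g, linf = r$vbgf$linf, k = r$vbgf$k, t0 = r$vbgf$t0,
               a = r$lw$a, b = r$lw$b, winf = r$weight_growth$winf,
               t_i = r$summary$t_i, t_c = r$summary$t_c, phi = r$summary$phi,
               Z = r$mortality$Z, M = r$mortality$M, F = r$mortality$F,
               E = r$mortality$E,
               E_max = r$ypr$ref$E_max, E_10 = r$ypr$ref$E_10,
               E_50 = r$ypr$ref$E_50,
               lc_star = r$lc_star,
               min_catch_length = as.numeric(r$recommended_min_length))
  })
  do.call(rbind, rows)
}

#' @export
print.assessment_report <- function(x, ...) {
  cat("Length-based stock assessment (", length(x$groups), " group",
      if (length(x$groups) != 1) "s", ")\n", sep = "")
  s <- summary(x)
  num <- vapply(s, is.numeric, logical(1))
  s[num] <- lapply(s[num], signif, digits = 4)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Write an assessment report bundle to disk
#'
#' Emits machine-readable outputs at full precision: `summary.csv` (the
#' per-group table), per-group `ypr_curve_<group>.csv` and
#' `isopleth_<group>.csv` (long format), and `manifest.json`.
#'
#' @param report an `"assessment_report"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_assessment <- function(report, dir) {
  stopifnot(inherits(report, "assessment_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(summary(report), file.path(dir, "summary.csv"),
                   row.names = FALSE)
  for (g in names(report$groups)) {
    r <- report$groups[[g]]
    utils::write.csv(r$ypr$curve,
                     file.path(dir, paste0("ypr_curve_", g, ".csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(r$isopleth),
                     file.path(dir, paste0("isopleth_", g, ".csv")),
                     row.names = FALSE)
  }
  writeLines(jsonlite::toJSON(report$manifest, auto_unbox = TRUE, digits = NA),
             file.path(dir, "manifest.json"))
  invisible(dir)
}
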