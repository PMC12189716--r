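test_that("noiseless power-law data recover length-weight coefficients exactly", {
  L <- seq(50, 400, by = 50)
  rec <- make_records(L, 1e-5 * L^3)
  for (m in c("log10", "nls")) {
    fit <- fit_length_weight(rec, method = m)
    expect_equal(fit$a, 1e-5, tolerance = 1e-8)
    expect_equal(fit$b, 3, tolerance = 1e-8)
    expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  }
})

test_that("length-weight fit under noise matches a grid-search oracle and truth", {
  set.seed(42)
  n <- 2000
  L <- runif(n, 40, 400)
  sdlog <- sqrt(log(1 + 0.1^2))
  W <- 2e-5 * L^2.97 * rlnorm(n, -sdlog^2 / 2, sdlog)
  fit <- fit_length_weight(make_records(L, W))
  expect_lt(abs(fit$b - 2.97), 0.05)
  oracle <- oracle_lw_grid(L, W)
  expect_lt(abs(fit$b - oracle$b), 5e-4)  # grid resolution
  expect_lt(abs(log10(fit$a) - oracle$log10_a), 5e-3)
})

test_that("length-weight fit refuses degenerate or invalid inputs", {
  expect_error(fit_length_weight(make_records(c(100, 100, 100), c(9, 10, 11))),
               "distinct lengths")
  expect_error(fit_length_weight(make_records(c(100, 200), c(10, 80))),
               "distinct lengths")
})

test_that("published allometry exponents are near-isometric", {
  expect_true(all(abs(tributary_params()$b - 3) < 0.08))
})

test_that("noiseless VBGF data are recovered to numerical precision", {
  ages <- 0:13
  len <- 414.5 * (1 - exp(-0.154 * (ages + 0.556)))
  fit <- fit_vbgf(make_records(len, 1e-5 * len^3, age = ages))
  expect_equal(fit$linf, 414.5, tolerance = 1e-6)
  expect_equal(fit$k, 0.154, tolerance = 1e-6)
  expect_equal(fit$t0, -0.556, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
})

test_that("VBGF fit recovers simulated truth within stated tolerance", {
  cfg <- sim_config(linf = 400, k = 0.16, t0 = -0.5, lw_a = 2e-5, lw_b = 3,
                    Z = 0.35, max_age = 20, length_cv = 0.08, n = 3000,
                    seed = 7)
  pop <- simulate_population(cfg)
  fit <- fit_vbgf(pop)
  expect_lt(abs(fit$linf - 400) / 400, 0.03)
  expect_lt(abs(fit$k - 0.16) / 0.16, 0.10)
})

test_that("VBGF fit requires at least four distinct ages", {
  ages <- rep(c(1L, 2L, 3L), each = 3)
  len <- 100 + 10 * ages + rep(c(-1, 0, 1), 3)
  expect_error(fit_vbgf(make_records(len, 1e-5 * len^3, age = ages)),
               "4 distinct ages")
})

test_that("derived weight growth is exact arithmetic, never a refit", {
  lw <- structure(list(a = 1e-5, b = 3, n = 10L, r_squared = 1,
                       se_b = 0, isometric = TRUE, p_isometry = 1,
                       method = "log10"), class = "lw_fit")
  wg <- derive_weight_growth(vbgf_params(100, 0.2, -0.5), lw)
  expect_identical(wg$winf, 10)
  expect_identical(wg$k, 0.2)
  expect_identical(wg$b, 3)
})

test_that("published weight-rate coefficients recombine as W_inf * k * b", {
  tp <- tributary_params()
  for (i in seq_len(nrow(tp))) {
    winf <- tp$weight_rate_coef[i] / (tp$k[i] * tp$b[i])
    lw <- structure(list(a = winf / tp$linf[i]^tp$b[i], b = tp$b[i],
                         n = NA_integer_, r_squared = NA_real_,
                         se_b = NA_real_, isometric = NA,
                         p_isometry = NA_real_, method = "injected"),
                    class = "lw_fit")
    wg <- derive_weight_growth(vbgf_params(tp$linf[i], tp$k[i], tp$t0[i]), lw)
    expect_equal(wg$winf * wg$k * wg$b, tp$weight_rate_coef[i],
                 tolerance = 1e-3)
  }
})

test_that("growth curves respect their boundaries and asymptote", {
  v <- vbgf_params(414.532467532468, 0.154, -0.556)
  expect_equal(length_at_age(v, v$t0), 0)
  t <- seq(v$t0, 60, length.out = 500)
  L <- length_at_age(v, t)
  expect_true(all(diff(L) > 0))
  expect_true(all(L < v$linf))
  expect_equal(length_at_age(v, 1e4), v$linf, tolerance = 1e-6)
  expect_error(length_at_age(v, -1), "t0")
  # length at the inflection age, frozen from high-precision arithmetic
  expect_equal(length_at_age(v, 6.51017866129995), 274.907533202,
               tolerance = 1e-9)
})

test_that("derivative curves have the shapes the model implies", {
  v <- vbgf_params(400, 0.18, -0.4)
  lw <- structure(list(a = 2e-5, b = 2.95, n = 10L, r_squared = 1,
                       se_b = 0, isometric = TRUE, p_isometry = 1,
                       method = "log10"), class = "lw_fit")
  wg <- derive_weight_growth(v, lw)
  t <- seq(v$t0 + 1e-6, 40, length.out = 2000)

  rate_L <- growth_rate_length(v, t)
  expect_true(all(rate_L > 0))
  expect_true(all(diff(rate_L) < 0))
  expect_true(all(growth_accel_length(v, t) < 0))

  # weight rate peaks at the inflection age (grid oracle, 1e-3 yr steps)
  t_i <- inflection_age(wg$b, wg$k, wg$t0)
  grid <- seq(v$t0 + 1e-3, 40, by = 1e-3)
  rate_W <- growth_rate_weight(wg, grid)
  expect_lt(abs(grid[which.max(rate_W)] - t_i), 1e-3 + 1e-9)
  expect_lte(max(rate_W), growth_rate_weight(wg, t_i))

  # weight acceleration changes sign exactly once, at t_i
  acc <- growth_accel_weight(wg, grid)
  sign_changes <- sum(diff(sign(acc)) != 0)
  expect_identical(sign_changes, 1L)
  expect_lt(abs(grid[which(diff(sign(acc)) != 0)] - t_i), 1e-3 + 1e-9)
})

test_that("closed-form ages and phi match 50-digit reference values", {
  tp <- tributary_params()
  ref <- frozen_growth_reference()
  for (i in seq_len(nrow(tp))) {
    j <- match(tp$code[i], ref$code)
    expect_equal(tp$linf[i], ref$linf[j], tolerance = 1e-12)
    expect_equal(inflection_age(tp$b[i], tp$k[i], tp$t0[i]), ref$t_i[j],
                 tolerance = 1e-12)
    expect_equal(critical_age(tp$k[i], tp$t0[i], tp$b[i], tp$M[i]),
                 ref$t_c[j], tolerance = 1e-12)
    expect_equal(growth_performance_index(tp$k[i], tp$linf[i]), ref$phi[j],
                 tolerance = 1e-12)
  }
})

test_that("closed-form identities hold", {
  expect_equal(inflection_age(exp(1), 1, 0), 1, tolerance = 1e-14)
  # M = b k, t0 = 0 collapses the critical age to ln(2)/k
  for (k in c(0.1, 0.2, 0.5)) {
    expect_equal(critical_age(k, 0, 2.9, 2.9 * k), log(2) / k,
                 tolerance = 1e-12)
  }
  expect_equal(growth_performance_index(1, 1), 0)
  # rescaling L_inf by c shifts phi by exactly 2 log10(c)
  set.seed(3)
  for (i in 1:20) {
    k <- runif(1, 0.05, 1); linf <- runif(1, 100, 800); cc <- runif(1, 0.1, 10)
    expect_equal(growth_performance_index(k, linf * cc) -
                   growth_performance_index(k, linf),
                 2 * log10(cc), tolerance = 1e-10)
  }
})

test_that("closed forms reject their degenerate domains", {
  expect_error(inflection_age(1, 0.2, 0), "no inflection")
  expect_error(inflection_age(0.8, 0.2, 0), "no inflection")
  expect_error(critical_age(0.2, 0, 3, 0), "positive")
  expect_error(critical_age(0.2, 0, 3, -0.1), "positive")
})
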