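test_that("relative yield vanishes at its boundaries", {
  expect_identical(relative_yield_per_recruit(0, 0.4, 2), 0)
  # L_c -> L_inf: nothing recruits to the fishery
  expect_lt(relative_yield_per_recruit(0.5, 1e-9, 2), 1e-17)
  expect_error(relative_yield_per_recruit(1, 0.4, 2), "below 1")
})

test_that("analytic yield and biomass match the age-structured integral", {
  # spot value quoted as the oracle anchor
  y <- relative_yield_per_recruit(0.5, 0.4, 2)
  expect_equal(y, oracle_yield_integral(0.5, 0.4, 2), tolerance = 1e-4)

  k <- 0.2
  for (E in c(0.1, 0.4, 0.7, 0.9)) {
    for (U in c(0.3, 0.5, 0.8)) {
      for (mk in c(1, 1.8, 2.5)) {
        expect_equal(relative_yield_per_recruit(E, U, mk),
                     oracle_yield_integral(E, U, mk, k), tolerance = 1e-8)
        expect_equal(relative_biomass_per_recruit(E, U, mk * k, k),
                     oracle_biomass_integral(E, U, mk, k), tolerance = 1e-8)
      }
    }
  }
})

test_that("biomass per recruit is continuous at E = 0 and strictly decreasing", {
  M <- 0.4; k <- 0.2; U <- 0.5
  b0 <- relative_biomass_per_recruit(0, U, M, k)
  expect_true(is.finite(b0))
  expect_equal(relative_biomass_per_recruit(1e-6, U, M, k), b0,
               tolerance = 1e-5)
  # matches the independent integral at E = 0 too
  expect_equal(b0, oracle_biomass_integral(0, U, M / k, k), tolerance = 1e-8)

  E <- seq(0, 0.998, by = 0.002)
  B <- relative_biomass_per_recruit(E, U, M, k)
  expect_true(all(diff(B) < 0))
  # depletion ratio falls from 1 towards 0
  expect_equal(B[1] / b0, 1)
  expect_lt(B[length(B)] / b0, 0.01)
})

test_that("reference points are definitional and match brute-force scans", {
  cfg <- ypr_config(400, 0.2, 0.4, 200)  # L_c/L_inf = 0.5, M/k = 2
  rp <- reference_points(cfg)

  expect_true(rp$E_10 > 0 && rp$E_10 < rp$E_max && rp$E_max < 1)

  E <- seq(0, 0.999, by = 0.001)
  Y <- relative_yield_per_recruit(E, 0.5, 2)
  expect_gte(relative_yield_per_recruit(rp$E_max, 0.5, 2), max(Y))

  # B'/R at E_50 is exactly half the unexploited level
  expect_equal(relative_biomass_per_recruit(rp$E_50, 0.5, 0.4, 0.2) /
                 relative_biomass_per_recruit(0, 0.5, 0.4, 0.2),
               0.5, tolerance = 1e-5)

  orp <- oracle_reference_points(0.5, 0.4, 0.2)
  expect_equal(rp$E_max, orp$E_max, tolerance = 1e-3)
  expect_equal(rp$E_10, orp$E_10, tolerance = 1e-3)
  expect_equal(rp$E_50, orp$E_50, tolerance = 1e-3)
})

test_that("reference points are invariant to grid resolution", {
  rp1 <- reference_points(ypr_config(400, 0.2, 0.4, 220, E_step = 0.001))
  rp2 <- reference_points(ypr_config(400, 0.2, 0.4, 220, E_step = 0.005))
  expect_equal(rp1$E_max, rp2$E_max, tolerance = 1e-4)
  expect_equal(rp1$E_10, rp2$E_10, tolerance = 1e-4)
  expect_equal(rp1$E_50, rp2$E_50, tolerance = 1e-4)
})

test_that("raising the capture length raises E_max", {
  e_max <- vapply(c(0.3, 0.4, 0.5, 0.6), function(r) {
    reference_points(ypr_config(400, 0.2, 0.4, r * 400))$E_max
  }, numeric(1))
  expect_true(all(diff(e_max) > 0))
})

test_that("isopleth grid is consistent with pointwise evaluation", {
  iso <- isopleth_grid(400, 0.4, 0.2,
                       E_grid = seq(0, 0.9, by = 0.05),
                       lc_ratio_grid = seq(0.1, 0.6, by = 0.05))
  expect_identical(dim(iso$YpR), c(length(iso$E), length(iso$lc_mm)))
  expect_true(all(iso$YpR[1, ] == 0))  # E = 0 row
  expect_true(all(iso$YpR >= 0))

  # spot check against single-point evaluation
  i <- which(abs(iso$E - 0.4) < 1e-9)
  j <- which(abs(iso$lc_ratio - 0.55) < 1e-9)
  expect_equal(iso$YpR[i, j],
               relative_yield_per_recruit(0.4, 1 - 0.55, 0.4 / 0.2))

  # each fixed-E row has a single yield ridge in L_c, and the ridge moves to
  # larger capture lengths as exploitation intensifies
  fine <- isopleth_grid(400, 0.4, 0.2,
                        E_grid = seq(0.05, 0.95, by = 0.05),
                        lc_ratio_grid = seq(0.1, 0.6, by = 0.005))
  ridge <- numeric(length(fine$E))
  for (i in seq_along(fine$E)) {
    d <- diff(fine$YpR[i, ])
    turns <- sum(d[-length(d)] > 0 & d[-1] < 0) +
      sum(d[-length(d)] < 0 & d[-1] > 0)
    expect_lte(turns, 1)
    ridge[i] <- fine$lc_ratio[which.max(fine$YpR[i, ])]
  }
  expect_true(all(diff(ridge) >= 0))

  long <- as.data.frame(iso)
  expect_identical(nrow(long), length(iso$E) * length(iso$lc_mm))
  expect_equal(long$YpR, as.vector(iso$YpR))
})

test_that("raising the capture length pays off at the overexploited rates", {
  # at each overexploited tributary's published E and M/k, yield per recruit
  # at the L_c/L_inf = 0.6 target clearly exceeds yield at the small capture
  # sizes the fisheries currently use
  tp <- tributary_params()
  for (g in c("NC", "LS", "NY")) {
    r <- tp[tp$code == g, ]
    E <- (r$Z - r$M) / r$Z
    mk <- r$M / r$k
    expect_gt(relative_yield_per_recruit(E, 1 - 0.6, mk),
              relative_yield_per_recruit(E, 1 - 0.15, mk))
  }
})

test_that("capture-length advice reproduces the published figures", {
  tp <- tributary_params()
  expect_identical(optimal_lc_at_ratio(tp$linf[tp$code == "NC"]), 240)
  expect_identical(optimal_lc_at_ratio(tp$linf[tp$code == "NY"]), 236)
  expect_identical(optimal_lc_at_ratio(400, 0), 0)

  dx <- tp[tp$code == "DX", ]
  v <- vbgf_params(dx$linf, dx$k, dx$t0)
  s <- growth_summary(v, dx$b, dx$M)
  rec <- recommend_min_catch_length(v, s, optimal_lc_at_ratio(dx$linf))
  expect_identical(as.numeric(rec), 257)
  expect_named(attr(rec, "components"),
               c("lc_star", "length_at_ti", "length_at_tc"))

  # degenerate: all three indices equal
  comps <- attr(rec, "components")
  v2 <- vbgf_params(200, 0.2, 0)
  s2 <- growth_summary(v2, 3, 0.3)
  l_eq <- length_at_age(v2, s2$t_i)
  # feed the same length as lc_star and check the mean collapses onto it
  rec2 <- recommend_min_catch_length(v2, structure(
    list(t_i = s2$t_i, t_c = s2$t_i, phi = s2$phi), class = "growth_summary"),
    l_eq)
  expect_identical(as.numeric(rec2), round(l_eq))
})
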