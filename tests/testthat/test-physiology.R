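test_that("Steele basal EGP: closed forms and ODE-oracle recovery", {
  # no dilution: all circulating glucose is tracer-supplied
  expect_equal(basal_egp_steele(clamp_record(1, 99, 99)), 0)
  expect_equal(basal_egp_steele(clamp_record(1, 99, 1)), 98)
  # mass-balance oracle: known endogenous Ra = 12
  ep <- ode_clamp_oracle(F = 0.8, Ra = 12, E_inf = 99)
  rec <- clamp_record(0.8, 99, ep)
  expect_lt(abs(basal_egp_steele(rec) - 12) / 12, 0.005)
  # Steele identity: EGP strictly decreasing in plasma enrichment
  eps <- seq(0.5, 5, by = 0.5)
  egps <- vapply(eps, function(e) basal_egp_steele(clamp_record(0.8, 99, e)),
                 numeric(1))
  expect_true(all(diff(egps) < 0))
  expect_error(clamp_record(1, 99, 0), "positive")
})

test_that("clamp suppression and Rd recover configured rates from the oracle", {
  F <- 0.6; Ra <- 10; E_inf <- 99
  ep_basal <- ode_clamp_oracle(F, Ra, E_inf)
  # clamp phase: 60% suppression, exogenous glucose infusion running
  gir <- 7
  ep_clamp <- ode_clamp_oracle(F, Ra * 0.4, E_inf, gir = gir)
  rec <- clamp_record(F, E_inf, ep_basal, enrich_clamp = ep_clamp, gir = gir)
  sup <- clamp_egp_suppressed(rec)
  expect_lt(abs(sup$suppression_pct - 60), 2)
  expect_lt(abs(rd_clamp(rec) - (gir + Ra * 0.4)), 0.1)
  # boundary conventions
  full <- clamp_record(F, E_inf, ep_basal,
                       enrich_clamp = E_inf * F / (F + 1e-9 + 20), gir = 20)
  expect_equal(clamp_egp_suppressed(full)$suppression_pct, 100,
               tolerance = 1e-3)
  none <- clamp_record(F, E_inf, ep_basal, enrich_clamp = ep_basal, gir = 0)
  expect_equal(clamp_egp_suppressed(none)$suppression_pct, 0, tolerance = 1e-6)
  # zero basal EGP: suppression flagged undefined
  z <- clamp_record(1, 99, 99, enrich_clamp = 50, gir = 1)
  expect_warning(res <- clamp_egp_suppressed(z), "undefined")
  expect_true(is.na(res$suppression_pct))
})

test_that("steady-state conservation holds across an (F, Ra) grid", {
  for (F in c(0.4, 0.8)) for (Ra in c(5, 12, 20)) {
    ep <- ode_clamp_oracle(F, Ra)
    rec <- clamp_record(F, 99, ep)
    expect_lt(abs(basal_egp_steele(rec) - Ra) / Ra, 0.02)
  }
})

test_that("insulin/FFM adjustment normalises body size away", {
  expect_equal(adjust_metric(5, 1, 1), 5)
  expect_equal(adjust_metric(100, 50, 50), 0.04)
  expect_error(adjust_metric(1, 0, 50), "positive")
  # two subjects with equal tissue sensitivity but 2x FFM: whole-body rates
  # scale with FFM, adjusted values coincide
  per_kg_rate <- 0.12; insulin <- 40
  small <- per_kg_rate * 50 ; big <- per_kg_rate * 100
  expect_equal(adjust_metric(small, insulin, 50),
               adjust_metric(big, insulin, 100))
})

test_that("densitometric body composition matches the two-compartment closed form", {
  tab <- c(test = 1.100)
  # boundary densities
  expect_equal(body_composition(70, 70 / 1.100, "test",
                                d_ffm_table = tab)$fat_pct, 0)
  expect_equal(body_composition(70, 70 / 0.9007, "test",
                                d_ffm_table = tab)$fat_pct, 100,
               tolerance = 1e-9)
  # independent arithmetic oracle at the stated constants
  db <- 1.040
  frac <- (1 / db - 1 / 1.100) / (1 / 0.9007 - 1 / 1.100)
  res <- body_composition(65, 65 / db, "test", d_ffm_table = tab)
  expect_equal(res$fat_fraction, frac)
  expect_equal(res$fat_mass_kg + res$ffm_kg, 65)
  # monotone decreasing in density, bounded in [0, 1]
  fr <- vapply(seq(0.95, 1.09, by = 0.01), function(d)
    body_composition(70, 70 / d, "test", d_ffm_table = tab)$fat_fraction,
    numeric(1))
  expect_true(all(diff(fr) < 0))
  expect_true(all(fr >= 0 & fr <= 1))
  expect_warning(body_composition(70, 70 / 1.15, "test", d_ffm_table = tab),
                 "clamped")
})

test_that("IHL is the lipid/water area ratio, averaged over series", {
  expect_equal(ihl_fraction(0, 100), 0)
  expect_equal(ihl_fraction(5, 100), 0.05)
  # three acquisitions: mean of per-series ratios (oracle: direct mean)
  lip <- c(4, 5, 6); wat <- c(90, 100, 110)
  expect_equal(ihl_fraction(lip, wat), mean(lip / wat))
  expect_error(ihl_fraction(5, 0), "positive")
})

test_that("1/x-weighted calibration: exact fit, round trip, variance benefit", {
  x <- c(1, 2, 5, 10, 25, 50, 100)
  y <- 2 * x + 0.1
  curve <- fit_calibration(x, y)
  expect_equal(curve$slope, 2)
  expect_equal(curve$intercept, 0.1)
  expect_equal(curve$range, c(1, 100))
  # noiseless round trip reproduces the standards exactly
  q <- quantify(curve, y)
  expect_equal(q$concentration, x)
  expect_false(any(q$out_of_range))
  # out-of-range flags beyond the 1-100 ng/mL standards
  flags <- quantify(curve, c(0.5, 150) * 2 + 0.1)
  expect_true(all(flags$out_of_range))
  expect_equal(quantify(curve, 0.1)$concentration, 0)
  expect_error(fit_calibration(c(1, 2), c(2, 4)), "3 standards")
  expect_error(fit_calibration(c(0, 1, 2), c(1, 2, 3)), "positive")

  # Monte-Carlo: with noise SD proportional to x, the 1/x-weighted slope
  # has smaller variance than the unweighted one and both are unbiased
  set.seed(99)
  slopes <- replicate(1000, {
    yy <- 2 * x + 0.1 + rnorm(length(x), sd = 0.05 * x)
    c(fit_calibration(x, yy, "1/x")$slope,
      fit_calibration(x, yy, "none")$slope)
  })
  expect_lt(var(slopes[1, ]), var(slopes[2, ]))
  expect_lt(abs(mean(slopes[1, ]) - 2), 0.01)
  expect_lt(abs(mean(slopes[2, ]) - 2), 0.01)
})
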