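test_that("correlation_p_from_r reproduces the printed correlation table", {
  # rows that round cleanly to the printed 3 decimals
  expect_equal(round(correlation_p_from_r(0.335, 47), 3), 0.021)
  expect_equal(round(correlation_p_from_r(0.260, 47), 3), 0.078)
  expect_equal(round(correlation_p_from_r(0.245, 47), 3), 0.097)
  # remaining rows agree within +-0.002 of the printed values
  within_002 <- rbind(
    c(0.213, 47, 0.150), c(0.077, 47, 0.605), c(0.123, 47, 0.409),
    c(-0.035, 47, 0.814), c(-0.047, 43, 0.763), c(0.053, 43, 0.736),
    c(0.062, 45, 0.684), c(0.176, 45, 0.248), c(-0.119, 45, 0.438),
    c(0.103, 45, 0.500), c(-0.103, 45, 0.500))
  for (i in seq_len(nrow(within_002)))
    expect_lt(abs(correlation_p_from_r(within_002[i, 1], within_002[i, 2]) -
                    within_002[i, 3]), 0.002)
  # two rows sit 0.0021 off the printed value, consistent with the printed
  # r itself being rounded to 3 decimals (see methods vignette)
  expect_lt(abs(correlation_p_from_r(-0.015, 43) - 0.926), 0.003)
  expect_lt(abs(correlation_p_from_r(0.095, 45) - 0.537), 0.003)
})

test_that("correlation_p_from_r: null value, limits, and monotonicity", {
  expect_equal(correlation_p_from_r(0, 10), 1)
  expect_warning(p1 <- correlation_p_from_r(1, 10), "limit")
  expect_equal(p1, 0)
  expect_error(correlation_p_from_r(0.5, 2), "n >= 3")
  # symmetric in sign, decreasing in |r| at fixed n, decreasing in n
  rs <- seq(0.05, 0.95, by = 0.1)
  ps <- vapply(rs, correlation_p_from_r, numeric(1), n = 30)
  expect_true(all(diff(ps) < 0))
  expect_equal(ps, vapply(-rs, correlation_p_from_r, numeric(1), n = 30))
  ns <- c(5, 10, 20, 50, 200)
  pn <- vapply(ns, function(n) correlation_p_from_r(0.3, n), numeric(1))
  expect_true(all(diff(pn) < 0))
})

test_that("correlation_battery handles method maps, missingness and degeneracy", {
  tab <- simulate_cohort(cohort_spec(n = 200, quota = FALSE, seed = 13))
  b <- correlation_battery(tab)
  expect_true(all(c("variable", "method", "n", "r", "p") %in% names(b)))
  expect_equal(b$method[b$variable == "ihl"], "spearman")
  expect_equal(b$method[b$variable == "egp"], "spearman")
  expect_equal(b$method[b$variable == "weight"], "pearson")
  expect_true(all(abs(b$r) <= 1) && all(b$p > 0 & b$p <= 1))
  # missing values reduce per-variable n (complete-case per variable)
  tab2 <- tab
  tab2$insulin[tab2$stage == "late"][1:20] <- NA
  b2 <- correlation_battery(tab2)
  expect_equal(b2$n[b2$variable == "insulin"], 180)
  expect_equal(b2$n[b2$variable == "weight"], 200)
  # constant variable is skipped with a warning
  tab3 <- tab
  tab3$hdl <- 1
  expect_warning(b3 <- correlation_battery(tab3), "zero variance")
  expect_false("hdl" %in% b3$variable)
  # perfectly linear pair exercises the |r| = 1 path
  tab4 <- tab
  tab4$vldl[tab4$stage == "late"] <-
    tab4$vldl[tab4$stage == "early"] +
    (tab4$liver_volume[tab4$stage == "late"] -
       tab4$liver_volume[tab4$stage == "early"])
  b4 <- correlation_battery(tab4)
  expect_equal(b4$r[b4$variable == "vldl"], 1)
  expect_equal(b4$p[b4$variable == "vldl"], 0)
})

test_that("paired_test matches its closed form and the stated bound scenario", {
  set.seed(2)
  x <- rnorm(30, 100, 5)
  shifted <- x + 12 + rnorm(30, sd = 0.01)
  pt_res <- paired_test(x, shifted)
  expect_equal(pt_res$mean_diff, 12, tolerance = 0.01)
  ref <- t.test(shifted, x, paired = TRUE)
  expect_equal(pt_res$t, unname(ref$statistic))
  expect_equal(pt_res$p, ref$p.value)
  expect_error(paired_test(x, x), "zero variance")
  expect_error(paired_test(1:3, 1:4), "unpaired")
})

test_that("paired-t type-I error is calibrated at the nominal 5% level", {
  set.seed(77)
  reject <- replicate(2000, {
    before <- rnorm(20, 100, 10)
    after <- before + rnorm(20, 0, 8)
    paired_test(before, after)$p < 0.05
  })
  expect_gte(mean(reject), 0.04)
  expect_lte(mean(reject), 0.06)
})

test_that("subgroup comparisons recover injected group effects and exact counts", {
  tab <- simulate_cohort(cohort_spec(n = 47, seed = 2))
  pat <- cohort_patterns(tab)
  egp <- subgroup_comparison(tab, pat, "egp")
  expect_equal(egp$direction, "higher in gain-loss")
  expect_lt(egp$p, 0.05)
  rd <- subgroup_comparison(tab, pat, "rd")
  expect_equal(rd$direction, "higher in gain-loss")
  htn <- subgroup_comparison(tab, pat, "hypertension")
  expect_equal(unname(htn$counts["htn", "gain-loss"]), 0)
  expect_equal(unname(htn$prevalence[2]), 0.5)
  # null group difference: iid metric, fixed seed -> unremarkable p
  set.seed(5)
  fake <- tab
  fake$egp <- rnorm(nrow(fake))
  eq <- subgroup_comparison(fake, pat, "egp")
  expect_gt(eq$p, 0.05)
  # empty group errors by name
  solo <- pat; solo$pattern[solo$complete] <- "gain-loss"
  expect_error(subgroup_comparison(tab, solo, "egp"), "not gain-loss")
})

test_that("proportion_report uses half-up integer rounding", {
  expect_equal(proportion_report(c(34, 10, 3), 47), c(72L, 21L, 6L))
  expect_equal(proportion_report(17, 47), 36L)
  expect_equal(proportion_report(0, 12), 0L)
  expect_equal(proportion_report(1, 200), 1L)  # 0.5 rounds up
  expect_error(proportion_report(5, 0), "positive")
  expect_error(proportion_report(8, 5), "counts")
})

test_that("analyze_cohort and write_report assemble the full stage", {
  tab <- simulate_cohort(cohort_spec(n = 47, seed = 2))
  res <- analyze_cohort(tab)
  expect_s3_class(res, "cohort_analysis")
  expect_equal(res$pregnancy_pct, c(72L, 21L, 6L))
  expect_equal(res$completers_pct, 36L)
  expect_equal(res$gain_loss_pct, 53L)
  expect_lt(res$paired$p, 1e-3)
  expect_equal(round(res$headline_pct), round(100 * res$paired$mean_diff /
                                                res$mean_early))
  # raw p values only: no adjusted-p column anywhere in the battery
  expect_false(any(grepl("adj", names(res$battery), ignore.case = TRUE)))
  out <- file.path(tempdir(), "gestaliver-report")
  write_report(res, out)
  expect_true(file.exists(file.path(out, "report.md")))
  expect_true(file.exists(file.path(out, "correlation_table.csv")))
  md <- readLines(file.path(out, "report.md"))
  expect_true(any(grepl("gain-loss", md)))
  unlink(out, recursive = TRUE)
})
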