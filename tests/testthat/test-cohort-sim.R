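test_that("degenerate zero-SD spec puts everyone exactly at the means", {
  cv <- COHORT_CHANGE_VARS
  cv$change_sd[] <- 0; cv$base_sd[] <- 0
  spec <- cohort_spec(n = 12, early_sd = 0, change_sd = 0, change_vars = cv,
                      prop_gain = 1, prop_nochange = 0, prop_loss = 0,
                      completion_fraction = 0, seed = 5)
  tab <- simulate_cohort(spec)
  e <- tab[tab$stage == "early", ]; l <- tab[tab$stage == "late", ]
  expect_true(all(e$liver_volume == 1239))
  expect_true(all(l$liver_volume - e$liver_volume == 182))
  expect_true(all(e$ffm == 48))
})

test_that("fixed seed reproduces the cohort table exactly", {
  a <- simulate_cohort(cohort_spec(n = 47, seed = 20))
  b <- simulate_cohort(cohort_spec(n = 47, seed = 20))
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_cohort(cohort_spec(n = 47, seed = 21))
  expect_false(identical(a$liver_volume, c$liver_volume))
})

test_that("quota mode reproduces the printed subgroup counts at n = 47", {
  tab <- simulate_cohort(cohort_spec(n = 47, seed = 2))
  pat <- cohort_patterns(tab)
  expect_equal(unname(table(pat$pregnancy_change)[c("gain", "no-change", "loss")]),
               c(34, 10, 3), ignore_attr = TRUE)
  expect_equal(sum(pat$complete), 17)
  expect_equal(sum(pat$pattern == "gain-loss", na.rm = TRUE), 9)
  # hypertension confined to the not-gain-loss group
  early <- tab[tab$stage == "early", ]
  htn_ids <- early$id[early$hypertension]
  expect_true(all(pat$pattern[match(htn_ids, pat$id)] == "not gain-loss"))
  # every participant has early and late rows; postwean only for completers
  expect_equal(sum(tab$stage == "early"), 47)
  expect_equal(sum(tab$stage == "late"), 47)
  expect_equal(sum(tab$stage == "postwean"), 17)
  expect_true(all(tab$liver_volume > 0))
})

test_that("large-n generation recovers the spec means, SDs and correlations", {
  tab <- simulate_cohort(cohort_spec(n = 10000, quota = FALSE, seed = 7))
  e <- tab[tab$stage == "early", ]; l <- tab[tab$stage == "late", ]
  d <- l$liver_volume - e$liver_volume
  expect_lt(abs(mean(e$liver_volume) - 1239) / 1239, 0.01)
  expect_lt(abs(sd(e$liver_volume) - 220.8) / 220.8, 0.02)
  expect_lt(abs(mean(d) - 182) / 182, 0.02)
  expect_lt(abs(sd(d) - 197) / 197, 0.02)
  # subgroup fractions converge to the natural classification probabilities
  cls <- classify_change(e$liver_volume, l$liver_volume)
  expect_lt(abs(mean(cls == "gain") - 34 / 47), 0.06)
  # change-change correlations near targets
  b <- correlation_battery(tab)
  expect_lt(abs(b$r[b$variable == "ffm"] - 0.335), 0.02)
  expect_lt(abs(b$r[b$variable == "weight"] - 0.260), 0.02)
  expect_lt(abs(b$r[b$variable == "vat"] - 0.245), 0.02)
  # baseline hepatostat: early weight vs early liver volume
  expect_lt(abs(cor(e$weight, e$liver_volume) - 0.5), 0.03)
})

test_that("gain-loss completers carry the late EGP/Rd shifts and infeasible targets error", {
  tab <- simulate_cohort(cohort_spec(n = 470, seed = 9))
  pat <- cohort_patterns(tab)
  late <- tab[tab$stage == "late", ]
  gl <- late$egp[match(pat$id[which(pat$pattern == "gain-loss")], late$id)]
  ngl <- late$egp[match(pat$id[which(pat$pattern == "not gain-loss")], late$id)]
  expect_gt(mean(gl) - mean(ngl), 0)
  cv <- COHORT_CHANGE_VARS
  cv$r_target[1] <- 1.2
  expect_error(cohort_spec(change_vars = cv), "weight")
})

test_that("attach_imaging round-trips tabulated volumes", {
  tab <- simulate_cohort(cohort_spec(n = 5, seed = 3))
  stacks <- attach_imaging(tab, seed = 4)
  expect_equal(length(stacks), nrow(tab))
  for (i in seq_len(nrow(tab))) {
    v <- compute_liver_volume(stacks[[i]][[1]])
    expect_lt(abs(v - tab$liver_volume[i]) / tab$liver_volume[i], 0.001)
  }
  # n = 1 cohort: one stack per visit
  one <- simulate_cohort(cohort_spec(n = 1, prop_gain = 1, prop_nochange = 0,
                                     prop_loss = 0, completion_fraction = 0,
                                     seed = 6))
  s1 <- attach_imaging(one)
  expect_equal(length(s1), 2)  # early + late

  # operator-noise mode: the measurement-error range recovered through the
  # full stack pipeline (5 cases x 2 scans, as in the benchmark exercise)
  # agrees with a direct simulation oracle of the injected 3% spread
  set.seed(11)
  tab2 <- simulate_cohort(cohort_spec(n = 5, completion_fraction = 0,
                                      seed = 31))
  pipeline_ranges <- replicate(100, {
    st <- attach_imaging(tab2, replicates = 2, operator_noise_sd = 0.03,
                         seed = sample.int(1e6, 1))
    a <- vapply(st, function(s) compute_liver_volume(s[[1]]), numeric(1))
    b <- vapply(st, function(s) compute_liver_volume(s[[2]]), numeric(1))
    interoperator_variability(a, b)$range
  })
  oracle_ranges <- replicate(2000, {
    ea <- rnorm(10, sd = 0.03); eb <- rnorm(10, sd = 0.03)
    max(abs(100 * (ea - eb) / (1 + (ea + eb) / 2)))
  })
  expect_lt(abs(median(pipeline_ranges) - median(oracle_ranges)) /
              median(oracle_ranges), 0.2)
  # and the injected 3% spread is consistent with a +-7%-scale benchmark
  expect_lt(median(pipeline_ranges), 12)
  expect_gt(median(pipeline_ranges), 4)
})
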