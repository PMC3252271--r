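test_that("zero kinetic variability reproduces the wild type exactly", {
  rep0 <- robustness_kinetic(ref_params, cv = 0, n_trials = 5, seed = 1,
                             horizon = 60)
  expect_true(all(rep0$success))
  expect_equal(attr(rep0, "success_fraction"), 1)
  expect_lt(diff(range(rep0$t_peak)), 1e-9)
})

test_that("robustness reports are bit-reproducible from the seed", {
  r1 <- robustness_kinetic(ref_params, cv = 0.2, n_trials = 6, seed = 42,
                           horizon = 60)
  r2 <- robustness_kinetic(ref_params, cv = 0.2, n_trials = 6, seed = 42,
                           horizon = 60)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- robustness_kinetic(ref_params, cv = 0.2, n_trials = 6, seed = 43,
                           horizon = 60)
  expect_false(identical(r1$t_peak, r3$t_peak))
})

test_that("lognormal perturbation factors hit the requested CV", {
  set.seed(99)
  f <- meiodyn:::.cv_factors(2e4, 0.3)
  expect_true(all(f > 0))
  expect_lt(abs(mean(f) - 1), 0.02)
  expect_lt(abs(stats::sd(f) / mean(f) - 0.3), 0.02)
})

test_that("representative knockout protocols reproduce their phenotypes", {
  cat <- knockout_catalog()
  sub <- cat[cat$protocol %in% c("mek_inhibition", "emi2_overexpression"), ]
  ko <- knockout_suite(ref_params, catalog = sub)
  expect_equal(ko$label,
               c("MI_MII_failure_intermediate_plateau", "MI_arrest"))
  expect_true(all(ko$match))
})

test_that("a single input profile has zero path deviation", {
  rob <- robustness_input(ref_params, list(input_step(1)), horizon = 60)
  expect_equal(rob$max_path_deviation, 0)
})
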