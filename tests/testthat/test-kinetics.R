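test_that("Michaelis-Menten flux obeys its closed form and bounds", {
  expect_equal(michaelis_flux(0, 3, 1), 0)
  expect_equal(michaelis_flux(2, 1, 1), 1)          # half-saturation
  expect_equal(michaelis_flux(2, 3, 1), 1.5)
  expect_error(michaelis_flux(1, 1, 0), "positive")
  s <- seq(0, 10, by = 0.5)
  fl <- michaelis_flux(3, s, 0.2)
  expect_true(all(diff(fl) > 0))                    # monotone in substrate
  expect_true(all(fl <= 3))
})

test_that("one-step QSSA activity matches the linear-chain steady state", {
  expect_equal(class2_activity_one_step(1, 1), 0.5)
  expect_equal(class2_activity_one_step(0, 2), 0)
  expect_equal(class2_activity_one_step(2, 0), 1)
  set.seed(11)
  for (i in 1:25) {
    va <- runif(1, 0, 5); vi <- runif(1, 0.01, 5)
    expect_equal(class2_activity_one_step(va, vi),
                 oracle_one_step(va, vi), tolerance = 1e-12)
  }
})

test_that("two-step QSSA activity matches the two-site chain steady state", {
  expect_equal(class2_activity_two_step(1, 1), 0.25)
  expect_equal(class2_activity_two_step(0, 2), 0)
  expect_equal(class2_activity_two_step(2, 0), 1)
  set.seed(12)
  for (i in 1:25) {
    va <- runif(1, 0, 5); vi <- runif(1, 0.01, 5)
    expect_equal(class2_activity_two_step(va, vi),
                 oracle_two_step(va, vi), tolerance = 1e-12)
  }
})

test_that("degenerate class-II kinetics raise an error", {
  expect_error(class2_activity_one_step(0, 0), "degenerate")
  expect_error(class2_activity_two_step(0, 0), "degenerate")
})

test_that("class-II activities stay in [0, 1] for physiological inputs", {
  set.seed(13)
  for (i in 1:20) {
    s <- random_network_state()
    c2 <- class2_activities(s, ref_params, runif(1, 0, 2))
    expect_true(all(c2 >= 0 & c2 <= 1))
  }
})

test_that("rates vanish without regulators and scale linearly in couplings", {
  p <- ref_params
  ## remove basal terms so every remaining rate is regulator-driven
  p[c("ka_mpf_0", "ki_mpf_0", "ka_plx_0", "ks_mpf_0", "ks_c1_0",
      "ks_apc_0", "ks_emi_0")] <- 0
  zero <- stats::setNames(numeric(13), state_names())
  c2 <- class2_activities(zero, p, 0)
  r <- assemble_rates(zero, c2, p, 0)
  regulated <- c("ks_mos", "va_mos", "ks_mpf", "va_mpf", "va_apc",
                 "ks_c4", "va_c4", "ks_emi", "va_emi", "vi_emi", "va_c1")
  expect_true(all(r[regulated] == 0))

  ## doubling one coupling parameter doubles exactly the rates containing it
  s <- random_network_state()
  p1 <- ref_params
  c2 <- class2_activities(s, p1, 0.5)
  r1 <- assemble_rates(s, c2, p1, 0.5)
  p2 <- p1; p2[["ks_emi_c4"]] <- 2 * p2[["ks_emi_c4"]]
  r2 <- assemble_rates(s, class2_activities(s, p2, 0.5), p2, 0.5)
  expect_equal(r2[["ks_emi"]], 2 * r1[["ks_emi"]])  # ks_emi_0 is 0
  untouched <- setdiff(names(r1), "ks_emi")
  expect_identical(r1[untouched], r2[untouched])
})
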