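test_that("the G2 state is a fixed point at zero input", {
  g2 <- get_g2()
  traj <- simulate_maturation(ref_params, input_step(0), horizon = 50,
                              init = g2, n_grid = 201)
  dev <- max(abs(as.matrix(traj[, state_names()]) -
                   matrix(g2, nrow(traj), 13, byrow = TRUE)))
  expect_lt(dev, 1e-6)
})

test_that("wild-type MPF is non-monotonous: peak, trough, then plateau", {
  f <- get_wt_features()
  expect_true(is.finite(f$t_peak))
  expect_gt(f$m_trough, 0)
  expect_lt(f$m_trough, f$m_peak)
  expect_gt(f$m_plateau, f$m_trough)
  expect_true(f$plateau_converged)
  expect_lt(f$t_peak, f$t_trough)
})

test_that("ERK and Rsk switch on and stay on; APC activates transiently", {
  traj <- get_wt_traj()
  late <- traj[traj$time > 30, ]
  expect_gt(min(late$erk), 0.4)
  expect_gt(min(late$rsk), 0.35)
  ## APC: pronounced transient, low again at MII arrest
  expect_gt(max(traj$apc_a), 5 * late$apc_a[nrow(late)])
  ## Emi2 activates only near MI exit: negligible at the first MPF peak
  f <- get_wt_features()
  at_peak <- traj[which.min(abs(traj$time - f$t_peak)), ]
  expect_lt(at_peak$emi_a, 0.05 * max(traj$emi_a))
})

test_that("a long pulse and a sustained step give near-identical state paths", {
  rob <- robustness_input(ref_params,
                          list(input_step(1),
                               input_pulse(1, onset = 0, duration = 15)),
                          horizon = 60)
  expect_true(all(rob$per_profile$matured))
  expect_lt(rob$relative_deviation, 0.05)
})

test_that("maturation is irreversible after a supra-threshold pulse", {
  traj <- simulate_maturation(ref_params,
                              input_pulse(1, onset = 0, duration = 15),
                              horizon = 120, init = get_g2(), n_grid = 401)
  final <- unlist(traj[nrow(traj), state_names()])
  eq <- newton_equilibrium(final, ref_params, 0)
  expect_true(eq$converged)
  expect_true(eq$stable)
  expect_gt(eq$state[["mpf_a"]], 0.5)      # high-MPF MII state, not G2
})

test_that("sub-threshold pulses leave the system in G2", {
  g2 <- get_g2()
  traj <- simulate_maturation(ref_params,
                              input_pulse(0.1, onset = 0, duration = 30),
                              horizon = 150, init = g2, n_grid = 401)
  final <- unlist(traj[nrow(traj), state_names()])
  expect_lt(max(abs(final - g2) / pmax(abs(g2), 0.01)), 1e-4)
})

test_that("increasing step amplitude crosses a sharp maturation threshold", {
  g2 <- get_g2()
  matured <- vapply(c(0.15, 0.45), function(a) {
    tr <- simulate_maturation(ref_params, input_step(a), horizon = 120,
                              init = g2, n_grid = 301)
    max(tr$mpf_a) > 0.3
  }, logical(1))
  expect_identical(matured, c(FALSE, TRUE))
})
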