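test_that("the isolated MAPK module is a bistable switch with hysteresis", {
  sw <- mapk_switch_diagram(ref_params, c(0, 0.6))
  expect_equal(nrow(sw$folds), 2)
  expect_gt(sw$up_threshold, sw$down_threshold)
  expect_gt(sw$down_threshold, 0)
})

test_that("removing the ERK feedback with shallow kinetics flattens it", {
  p <- ref_params
  p[["ka_mos_erk"]] <- 0
  p[c("ka_mek_mos", "ka_erk_mek", "ka_rsk_erk")] <- 1
  sw <- mapk_switch_diagram(p, c(0, 0.6))
  expect_equal(nrow(sw$folds), 0)
  expect_true(all(diff(sw$points$q) > -1e-9))   # graded, single-valued
})

test_that("drive far above the window gives a single high-activity state", {
  fun <- mapk_field(ref_params)
  roots <- unique(round(vapply(c(0.05, 0.5, 0.95), function(x0) {
    meiodyn:::.newton_eq(fun, x0, 2, tol = 1e-12)$state
  }, numeric(1)), 6))
  expect_length(roots, 1)
  expect_gt(roots, 0.8)
})

test_that("the MPF-APC module oscillates in a drive window", {
  sc <- mpf_apc_scan(ref_params, c(0.5, 1.0, 2.0), horizon = 300)
  expect_identical(sc$oscillating, c(FALSE, TRUE, FALSE))
  expect_gt(sc$period[2], 0)
  expect_gt(sc$amplitude[2], 0.3)
})

test_that("below onset the module is excitable", {
  sn <- mpf_apc_sn(ref_params, tol = 1e-6)
  drive <- sn$drive - 0.05
  ## relax to the resting state, then apply a supra-threshold MPF bolus
  tr0 <- simulate_mpf_apc(ref_params, drive, horizon = 400, n_grid = 401)
  rest <- unlist(tr0[nrow(tr0), -1])
  kicked <- rest + c(0, 0.5, 0, 0)
  tr1 <- simulate_mpf_apc(ref_params, drive, horizon = 120, init = kicked,
                          n_grid = 1201)
  expect_gt(max(tr1$mpf_a), rest[["mpf_a"]] + 0.8)   # single large excursion
  final <- unlist(tr1[nrow(tr1), -1])
  expect_lt(sqrt(sum((final - rest)^2)), 1e-3)       # returns to rest
  ## small perturbations decay without an excursion
  tr2 <- simulate_mpf_apc(ref_params, drive, horizon = 120,
                          init = rest + c(0, 0.02, 0, 0), n_grid = 1201)
  expect_lt(max(tr2$mpf_a), rest[["mpf_a"]] + 0.1)
})

test_that("oscillations appear where the low-MPF equilibrium folds", {
  sn <- mpf_apc_sn(ref_params, tol = 1e-6)
  sc <- mpf_apc_scan(ref_params, sn$drive + c(-0.02, 0.02), horizon = 600)
  expect_identical(sc$oscillating, c(FALSE, TRUE))
})
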