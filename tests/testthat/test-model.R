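test_that("the class-I state has 13 variables covering 6 proteins", {
  expect_length(state_names(), 13)
  expect_length(grep("^emi_", state_names()), 3)
  ## five two-form proteins plus the three Emi2 forms
  expect_length(grep("_i$|_a$", setdiff(state_names(),
                                        grep("^emi", state_names(),
                                             value = TRUE))), 10)
})

test_that("hand-coded RHS agrees with the declarative reaction table", {
  tab <- reaction_table()
  set.seed(21)
  for (i in 1:50) {
    s <- random_network_state()
    pg <- runif(1, -0.5, 2)          # include formal negative inputs
    p <- ref_params
    if (i > 25) {                    # random parameter perturbations too
      free <- parameter_table(p)$id[parameter_table(p)$status == "free"]
      p[free] <- p[free] * runif(length(free), 0.5, 2)
    }
    d1 <- meiotic_rhs(0, s, p, pg)[[1]]
    d2 <- rhs_from_reactions(0, s, p, pg, tab)
    expect_equal(d1, d2, tolerance = 1e-12)
  }
})

test_that("form-sum derivatives equal synthesis minus degradation", {
  set.seed(22)
  for (i in 1:10) {
    s <- random_network_state()
    c2 <- class2_activities(s, ref_params, 1)
    r <- assemble_rates(s, c2, ref_params, 1)
    d <- meiotic_rhs(0, s, ref_params, 1)[[1]]
    expect_equal(d[["mos_i"]] + d[["mos_a"]],
                 r[["ks_mos"]] - r[["kd_mos"]] * (s[["mos_i"]] + s[["mos_a"]]),
                 tolerance = 1e-12)
    expect_equal(d[["mpf_i"]] + d[["mpf_a"]],
                 r[["ks_mpf"]] - r[["kd_mpf"]] * (s[["mpf_i"]] + s[["mpf_a"]]),
                 tolerance = 1e-12)
    expect_equal(d[["emi_u"]] + d[["emi_a"]] + d[["emi_p"]],
                 r[["ks_emi"]] - r[["kd_emi"]] * (s[["emi_u"]] + s[["emi_a"]]) -
                   r[["kd_emi_p"]] * s[["emi_p"]],
                 tolerance = 1e-12)
  }
})

test_that("total concentration is conserved when turnover is switched off", {
  p <- apply_intervention(ref_params,
                          intervention(c("ks_mos_c1", "kd_mos_0"), "zero"))
  init <- get_g2()
  init[["mos_i"]] <- 0.4
  init[["mos_a"]] <- 0.3
  traj <- simulate_maturation(p, input_step(1), horizon = 20, init = init,
                              n_grid = 201)
  total <- traj$mos_i + traj$mos_a
  expect_lt(max(abs(total - 0.7)), 1e-6)
})

test_that("synthesis-only derivatives appear at the zero state", {
  zero <- stats::setNames(numeric(13), state_names())
  d <- meiotic_rhs(0, zero, ref_params, 0)[[1]]
  expect_equal(d[["mpf_a"]], ref_params[["ks_mpf_0"]])
  expect_equal(d[["apc_i"]], ref_params[["ks_apc_0"]])
  expect_equal(d[["c1_i"]], ref_params[["ks_c1_0"]])
  expect_equal(unname(d[c("mos_i", "c4_i", "c4_a", "emi_u", "emi_a",
                          "emi_p")]), rep(0, 6))
})

test_that("non-finite states are rejected", {
  s <- random_network_state()
  s[3] <- NaN
  expect_error(meiotic_rhs(0, s, ref_params, 1), "non-finite")
})
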