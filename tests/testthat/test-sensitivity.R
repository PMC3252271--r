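test_that("a coupling that is zero in the reference has zero sensitivity", {
  ref <- get_reference()
  d <- dynamic_sensitivity(ref_params, "ks_emi_0", ref = ref)
  b <- bifurcation_sensitivity(ref_params, "ks_emi_0", ref = ref)
  expect_equal(d$s_dyn, 0)
  expect_equal(b$s_bif, 0)
})

test_that("dynamic sensitivities are consistent across perturbation sizes", {
  ref <- get_reference()
  for (id in c("ka_plx_pg", "ks_emi_c4", "kd_mpf_apc")) {
    s1 <- dynamic_sensitivity(ref_params, id, rel_delta = 0.1, ref = ref)
    s2 <- dynamic_sensitivity(ref_params, id, rel_delta = 0.05, ref = ref)
    expect_false(s1$censored_dyn)
    expect_lt(abs(s1$s_dyn - s2$s_dyn),
              0.2 * max(s1$s_dyn, s2$s_dyn, 0.05))
  }
})

test_that("fold tracking agrees with full-diagram recomputation", {
  ref <- get_reference()
  id <- "ka_plx_pg"
  m <- 1.1
  p_up <- ref_params
  p_up[[id]] <- p_up[[id]] * m
  tracked <- meiodyn:::.fold_displacement(p_up, ref$fold_I, ref$P_I)
  full <- bifurcation_diagram(p_up)$P_I
  expect_lt(abs(tracked - full), 1e-4)
})

test_that("early/late split matches the known role of signature couplings", {
  ref <- get_reference()
  ## progesterone-dependent Plx1 activation controls meiotic resumption
  plx <- dynamic_sensitivity(ref_params, "ka_plx_pg", ref = ref)
  expect_lt(plx$s_dyn_norm, 0.5)
  ## Emi2 translation controls MPF reaccumulation at MI/MII
  emi <- dynamic_sensitivity(ref_params, "ks_emi_c4", ref = ref)
  expect_gt(emi$s_dyn_norm, 0.5)
  bif <- bifurcation_sensitivity(ref_params, "ka_plx_pg", ref = ref)
  expect_gt(bif$s_bif_I, bif$s_bif_IV)
})

test_that("the screen is deterministic and resumes per-parameter", {
  ref <- get_reference()
  ids <- c("ka_plx_pg", "ks_emi_c4")
  s1 <- sensitivity_screen(ref_params, ids = ids, ref = ref)
  s2 <- sensitivity_screen(ref_params, ids = ids, ref = ref)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})

test_that("module partition handles degenerate records", {
  rec <- tibble::tibble(
    id = c("a", "b", "c"),
    s_dyn = c(0, 2, 1), s_dyn_norm = c(NA, 0.9, 0.1),
    s_bif = c(0, 1, 2), s_bif_norm = c(NA, 0.95, 0.2),
    censored_dyn = FALSE, censored_bif = FALSE
  )
  part <- partition_modules(rec, negligible_thr = 0.1)
  expect_equal(part$module, c("negligible", "MI_MII", "G2_MI"))
  all_zero <- dplyr::mutate(rec, s_dyn = 0, s_bif = 0,
                            s_dyn_norm = NA_real_, s_bif_norm = NA_real_)
  expect_true(all(partition_modules(all_zero,
                                    negligible_thr = 0.1)$module ==
                    "negligible"))
  expect_error(partition_modules(rec, low_thr = 0.8, high_thr = 0.7))
})
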