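test_that("input profiles are piecewise constant with exact edges", {
  expect_equal(input_step(2)(c(0, 5, 100)), c(2, 2, 2))
  pr <- input_pulse(1.5, onset = 1, duration = 2)
  expect_equal(pr(c(0, 0.99, 1, 2.9, 3, 4)), c(0, 0, 1.5, 1.5, 0, 0))
  expect_equal(input_pulse(0, onset = 1, duration = 2)(seq(0, 5)),
               rep(0, 6))
  expect_error(make_input_profile("ramp"))
  expect_error(input_pulse(1, duration = 0), "duration")
})

test_that("feature extraction is exact on a constructed triangle fixture", {
  tt <- seq(0, 40, by = 0.1)
  ## rise to 1 at t=5, fall to 0.3 at t=12, rise to 0.8 at t=25, flat after
  y <- approx(c(0, 5, 12, 25, 40), c(0, 1, 0.3, 0.8, 0.8), xout = tt)$y
  f <- mpf_features(data.frame(time = tt, mpf_a = y), refine = FALSE)
  expect_equal(f$t_peak, 5)
  expect_equal(f$m_peak, 1)
  expect_equal(f$m_trough, 0.3)
  expect_equal(f$t_trough, 12)
  expect_equal(f$m_plateau, 0.8)
  expect_true(f$plateau_converged)
  expect_equal(f$n_peaks, 1L)
})

test_that("smooth extrema are recovered exactly by parabolic refinement", {
  tt <- seq(0, 40, by = 0.1)
  ## piecewise-quadratic trace with analytically known extrema off the grid
  tp <- 5.03; tm <- 12.07
  y <- ifelse(tt <= 8.55, 1 - 0.02 * (tt - tp)^2,
       ifelse(tt <= 20, 0.3 + 0.02 * (tt - tm)^2,
              0.3 + 0.02 * (20 - tm)^2))
  f <- mpf_features(data.frame(time = tt, mpf_a = y))
  expect_equal(f$t_peak, tp, tolerance = 1e-9)
  expect_equal(f$m_peak, 1, tolerance = 1e-9)
  expect_equal(f$t_trough, tm, tolerance = 1e-9)
  expect_equal(f$m_trough, 0.3, tolerance = 1e-9)
})

test_that("a flat zero trace yields absent features, not errors", {
  f <- mpf_features(data.frame(time = 0:100, mpf_a = rep(0, 101)))
  expect_true(is.na(f$t_peak))
  expect_equal(f$m_plateau, 0)
  expect_equal(f$n_peaks, 0L)
})

test_that("the classifier assigns each phenotype from its defining features", {
  wt <- mpf_features(data.frame(
    time = seq(0, 40, by = 0.1),
    mpf_a = approx(c(0, 2, 5, 15, 40), c(0, 1, 0.3, 1.1, 1.1),
                   xout = seq(0, 40, by = 0.1))$y))
  mk <- function(t_peak = 2, m_peak = 1, m_trough = 0.3, m_plateau = 1.1,
                 t_act = 1.8, n_peaks = 1L, peak_heights = m_peak,
                 m_final = m_plateau, m_max = max(m_peak, m_plateau)) {
    structure(list(t_peak = t_peak, m_peak = m_peak, t_act = t_act,
                   t_trough = t_peak + 2, m_trough = m_trough,
                   m_plateau = m_plateau, plateau_converged = TRUE,
                   n_peaks = n_peaks, peak_heights = peak_heights,
                   m_final = m_final, m_max = m_max, horizon = 40),
              class = "meio_features")
  }
  lab <- function(f) classify_phenotype(f, wt)$label
  expect_equal(lab(mk()), "normal_maturation")
  expect_equal(lab(mk(t_peak = 4, t_act = 3.6)), "MI_entry_delay")
  expect_equal(lab(mk(t_peak = NA, t_act = NA, m_peak = NA, m_trough = NA,
                      m_plateau = 0.01, m_final = 0.01, m_max = 0.05,
                      n_peaks = 0L, peak_heights = numeric(0))),
               "MI_entry_failure")
  expect_equal(lab(mk(m_plateau = 0.1, m_final = 0.1)), "MII_entry_failure")
  expect_equal(lab(mk(m_plateau = 0.45, m_final = 0.45)),
               "MI_MII_failure_intermediate_plateau")
  expect_equal(lab(mk(m_trough = 0.95, m_plateau = 1.2, m_final = 1.2)),
               "MI_arrest")
  expect_equal(lab(mk(n_peaks = 4L, peak_heights = c(1, 0.9, 0.95, 0.9))),
               "oscillations")
  ## dissimilar repeated maxima are not oscillations
  expect_equal(lab(mk(n_peaks = 3L, peak_heights = c(1, 0.2, 1))),
               "normal_maturation")
})

test_that("inconsistent classifier thresholds are rejected", {
  bad <- classifier_rules()
  bad$fail_plateau_frac <- 0.9          # overlaps the intermediate band
  wt <- structure(list(t_peak = 2, m_plateau = 1), class = "meio_features")
  f <- structure(list(t_peak = 2, m_peak = 1, t_act = 1.8, t_trough = 4,
                      m_trough = 0.3, m_plateau = 1, plateau_converged = TRUE,
                      n_peaks = 1L, peak_heights = 1, m_final = 1, m_max = 1,
                      horizon = 40), class = "meio_features")
  expect_error(classify_phenotype(f, wt, bad), "inconsistent")
})
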