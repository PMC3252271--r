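## ---- in-silico knockout suite and robustness Monte Carlo ----------------

#' Catalogue of maturation-defect protocols
#'
#' The built-in knockout / inhibition / overexpression protocols emulating
#' antisense and pharmacological treatments, with the phenotype classes they
#' are expected to produce: cyclin-synthesis ablation (MII-entry failure
#' with a delayed first peak), Mos-synthesis ablation (MII-entry failure or
#' sustained oscillations), combined cyclin+Mos ablation (MI-entry failure),
#' progesterone-dependent Plx1-activation ablation (MI-entry delay or
#' failure), MEK inhibition (intermediate-plateau MI/MII failure), Emi2
#' overexpression (metaphase-I arrest) and Emi2-synthesis ablation
#' (MII-entry failure).
#'
#' @return Tibble: `protocol`, `spec` (list of intervention tibbles),
#'   `expected` (list of accepted label sets), `requires_delay` (logical:
#'   the match additionally requires a strictly delayed first peak).
#' @export
knockout_catalog <- function() {
  tibble::tibble(
    protocol = c("cyclin_synthesis_ablation", "mos_synthesis_ablation",
                 "cyclin_mos_ablation", "plx1_activation_ablation",
                 "mek_inhibition", "emi2_overexpression",
                 "emi2_synthesis_ablation"),
    spec = list(
      intervention(c("ks_mpf_0", "ks_mpf_c1", "ks_mpf_c4"), "zero"),
      intervention("ks_mos_c1", "zero"),
      intervention(c("ks_mpf_0", "ks_mpf_c1", "ks_mpf_c4", "ks_mos_c1"),
                   "zero"),
      intervention("ka_plx_pg", "zero"),
      intervention("ka_erk_mek", "zero"),
      intervention("ks_emi_0", "set", 0.2),
      intervention(c("ks_emi_0", "ks_emi_c4"), "zero")
    ),
    expected = list(
      "MII_entry_failure",
      c("MII_entry_failure", "oscillations"),
      "MI_entry_failure",
      c("MI_entry_delay", "MI_entry_failure"),
      "MI_MII_failure_intermediate_plateau",
      "MI_arrest",
      "MII_entry_failure"
    ),
    requires_delay = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
}

#' Run the knockout-phenotype suite
#'
#' Simulates every catalogued protocol under the standard progesterone step
#' (starting from the unperturbed G2 state, as in the corresponding
#' experiments where the treatment is applied to resting oocytes),
#' classifies the resulting MPF time course against the wild-type
#' reference, and flags whether each phenotype matches its catalogued
#' class. Per-protocol failures are recorded and the suite continues.
#'
#' @param params Named numeric parameter vector.
#' @param catalog Protocol table, see [knockout_catalog()].
#' @param amplitude Progesterone step amplitude.
#' @param horizon Simulation horizon.
#' @param rules Classifier thresholds, see [classifier_rules()].
#' @return Tibble of class `meio_knockouts`: `protocol`, `label`,
#'   `expected`, `match`, `t_peak`, `t_peak_ratio`, `plateau_ratio`,
#'   `delayed`, `error`.
#' @export
knockout_suite <- function(params, catalog = knockout_catalog(),
                           amplitude = 1, horizon = 60,
                           rules = classifier_rules()) {
  validate_parameters(params)
  g2 <- g2_state(params)
  wt_traj <- simulate_maturation(params, input_step(amplitude),
                                 horizon = horizon, init = g2)
  wt <- mpf_features(wt_traj)
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    res <- tryCatch({
      p <- apply_intervention(params, catalog$spec[[i]])
      traj <- simulate_maturation(p, input_step(amplitude),
                                  horizon = horizon, init = g2)
      f <- mpf_features(traj, min_peak = 0.2 * wt$m_plateau)
      cl <- classify_phenotype(f, wt, rules)
      strictly_delayed <- is.finite(cl$t_peak_ratio) && cl$t_peak_ratio > 1
      tibble::tibble(
        protocol = catalog$protocol[i],
        label = cl$label,
        expected = paste(catalog$expected[[i]], collapse = "|"),
        match = cl$label %in% catalog$expected[[i]] &&
          (!catalog$requires_delay[i] || strictly_delayed),
        t_peak = f$t_peak,
        t_peak_ratio = cl$t_peak_ratio,
        plateau_ratio = cl$plateau_ratio,
        delayed = cl$delayed,
        error = NA_character_
      )
    }, error = function(e) {
      tibble::tibble(protocol = catalog$protocol[i], label = NA_character_,
                     expected = paste(catalog$expected[[i]], collapse = "|"),
                     match = FALSE, t_peak = NA_real_,
                     t_peak_ratio = NA_real_, plateau_ratio = NA_real_,
                     delayed = NA, error = conditionMessage(e))
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("meio_knockouts", class(out))
  attr(out, "wild_type") <- wt
  out
}

## lognormal multiplicative factors with mean 1 and coefficient of
## variation cv
.cv_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Robustness of maturation to kinetic-parameter variability
#'
#' Monte Carlo: each trial multiplies every free kinetic parameter by an
#' independent lognormal factor with mean 1 and coefficient of variation
#' `cv`, relaxes the perturbed system to its resting state at zero input,
#' applies the standard progesterone step and classifies the phenotype
#' against the unperturbed wild type. Maturation success means a
#' `normal_maturation` or `MI_entry_delay` label (timing changes alone are
#' not failures). Fully reproducible from `seed`.
#'
#' @param params Named numeric parameter vector.
#' @param cv Coefficient of variation of the multiplicative perturbations.
#' @param n_trials Number of Monte Carlo trials.
#' @param seed Integer seed.
#' @param amplitude Progesterone step amplitude.
#' @param horizon Simulation horizon.
#' @return Tibble of class `meio_robustness` with one row per trial:
#'   `trial`, `label`, `success`, `t_peak`, `m_plateau`; attributes `cv`,
#'   `seed`, `success_fraction`, `t_peak_sd`.
#' @export
robustness_kinetic <- function(params, cv, n_trials = 100, seed = 1,
                               amplitude = 1, horizon = 60) {
  validate_parameters(params)
  stopifnot(cv >= 0, n_trials >= 1)
  free_ids <- parameter_table(params)$id[
    parameter_table(params)$status == "free"]
  g2 <- g2_state(params)
  wt <- mpf_features(simulate_maturation(params, input_step(amplitude),
                                         horizon = horizon, init = g2))
  set.seed(seed)
  factors <- matrix(.cv_factors(n_trials * length(free_ids), cv),
                    nrow = n_trials)
  rows <- lapply(seq_len(n_trials), function(i) {
    p <- params
    p[free_ids] <- p[free_ids] * factors[i, ]
    res <- tryCatch({
      f0 <- function(t, state, parms) meiotic_rhs(t, state, parms, 0)
      rest <- deSolve::lsoda(resting_state(p), c(0, 200), f0, p,
                             rtol = 1e-8, atol = 1e-10, maxsteps = 20000)
      init <- rest[nrow(rest), state_names()]
      traj <- simulate_maturation(p, input_step(amplitude),
                                  horizon = horizon, init = init,
                                  n_grid = 401)
      f <- mpf_features(traj, min_peak = 0.2 * wt$m_plateau)
      cl <- classify_phenotype(f, wt)
      tibble::tibble(trial = i, label = cl$label,
                     success = cl$label %in% c("normal_maturation",
                                               "MI_entry_delay"),
                     t_peak = f$t_peak, m_plateau = f$m_plateau)
    }, error = function(e) {
      tibble::tibble(trial = i, label = "simulation_failure",
                     success = FALSE, t_peak = NA_real_,
                     m_plateau = NA_real_)
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("meio_robustness", class(out))
  attr(out, "cv") <- cv
  attr(out, "seed") <- seed
  attr(out, "success_fraction") <- mean(out$success)
  attr(out, "t_peak_sd") <- stats::sd(out$t_peak, na.rm = TRUE)
  out
}

## resample a 2-D path to m points equally spaced in arc length
.arclength_resample <- function(x, y, m = 200) {
  ds <- sqrt(diff(x)^2 + diff(y)^2)
  s <- c(0, cumsum(ds))
  if (s[length(s)] == 0) {
    return(cbind(rep(x[1], m), rep(y[1], m)))
  }
  s <- s / s[length(s)]
  keep <- !duplicated(s)
  grid <- seq(0, 1, length.out = m)
  cbind(stats::approx(s[keep], x[keep], xout = grid)$y,
        stats::approx(s[keep], y[keep], xout = grid)$y)
}

#' Robustness of the maturation path to progesterone-input variability
#'
#' Simulates a set of supra-threshold input profiles and measures how much
#' the state-space trajectory -- the (MPF, APC) activity path from G2
#' arrest to metaphase-II arrest -- varies, after arc-length
#' reparameterization, compared with how much the timing (`t_peak`)
#' varies. Sub-threshold profiles (no maturation within the horizon) are
#' flagged and excluded from the invariance statistic.
#'
#' @param params Named numeric parameter vector.
#' @param profiles List of `meio_input` profiles.
#' @param horizon Simulation horizon.
#' @return List of class `meio_input_robustness`: `per_profile` tibble
#'   (`profile`, `kind`, `amplitude`, `matured`, `t_peak`, terminal MPF),
#'   `max_path_deviation` (maximum pairwise mean path distance),
#'   `path_diameter`, `relative_deviation`, `t_peak_spread`
#'   (relative), `timing_to_path_ratio`.
#' @export
robustness_input <- function(params, profiles, horizon = 60) {
  validate_parameters(params)
  g2 <- g2_state(params)
  runs <- lapply(profiles, function(pr) {
    traj <- simulate_maturation(params, pr, horizon = horizon, init = g2)
    f <- mpf_features(traj)
    list(traj = traj, f = f,
         matured = is.finite(f$t_peak) && f$m_plateau > 0.2 * f$m_peak)
  })
  per <- dplyr::bind_rows(lapply(seq_along(runs), function(i) {
    tibble::tibble(
      profile = i,
      kind = attr(profiles[[i]], "kind"),
      amplitude = attr(profiles[[i]], "amplitude"),
      matured = runs[[i]]$matured,
      t_peak = runs[[i]]$f$t_peak,
      mpf_final = runs[[i]]$f$m_final
    )
  }))
  ok <- which(per$matured)
  if (length(ok) < 1) stop("no supra-threshold profile matured", call. = FALSE)
  paths <- lapply(runs[ok], function(r) {
    .arclength_resample(r$traj$mpf_a, r$traj$apc_a)
  })
  all_pts <- do.call(rbind, paths)
  diam <- sqrt(max(rowSums(sweep(all_pts, 2,
                                 apply(all_pts, 2, min))^2)))
  maxdev <- 0
  if (length(ok) > 1) {
    for (i in seq_along(paths)) {
      for (j in seq_len(i - 1)) {
        d <- mean(sqrt(rowSums((paths[[i]] - paths[[j]])^2)))
        maxdev <- max(maxdev, d)
      }
    }
  }
  tp <- per$t_peak[ok]
  out <- list(
    per_profile = per,
    max_path_deviation = maxdev,
    path_diameter = diam,
    relative_deviation = maxdev / diam,
    t_peak_spread = (max(tp) - min(tp)) / mean(tp),
    timing_to_path_ratio = ((max(tp) - min(tp)) / mean(tp)) /
      max(maxdev / diam, .Machine$double.eps)
  )
  class(out) <- "meio_input_robustness"
  out
}

#' @export
print.meio_input_robustness <- function(x, ...) {
  cat("Input-profile robustness:\n")
  cat(sprintf("  relative (MPF, APC) path deviation : %.4f\n",
              x$relative_deviation))
  cat(sprintf("  relative t_peak spread             : %.4f\n",
              x$t_peak_spread))
  cat(sprintf("  timing-to-path ratio               : %.2f\n",
              x$timing_to_path_ratio))
  invisible(x)
}

#' @export
glance.meio_robustness <- function(x, ...) {
  tibble::tibble(cv = attr(x, "cv"), n_trials = nrow(x),
                 seed = attr(x, "seed"),
                 success_fraction = attr(x, "success_fraction"),
                 t_peak_sd = attr(x, "t_peak_sd"))
}

#' @export
glance.meio_knockouts <- function(x, ...) {
  tibble::tibble(n_protocols = nrow(x), n_match = sum(x$match),
                 match_fraction = mean(x$match))
}
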