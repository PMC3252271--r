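#' Extract MPF trajectory indicators
#'
#' Computes the quantitative indicators of the MPF activity time course that
#' summarize maturation progression: the time and height of the first
#' prominent MPF peak (G2/MI transition), the trough between the first peak
#' and the late plateau (MI/MII transition), the late plateau level
#' (metaphase-II arrest), and the number of prominent maxima over the
#' horizon. Absent features are encoded as `NA`, not errors.
#'
#' A peak is the first local maximum of MPF activity exceeding `min_peak`
#' (default: 20% of the trace maximum; supply 20% of the wild-type plateau
#' when comparing perturbed trajectories against a reference). The plateau
#' is the mean over the final `plateau_frac` of the horizon and is accepted
#' as converged only if `|dMPF/dt|` there is below
#' `1e-3 * m_peak / horizon`.
#'
#' @param traj A `meio_trajectory` (or a data frame with columns `time` and
#'   `mpf_a`).
#' @param min_peak Minimal height for a maximum to count as a peak; `NULL`
#'   for 20% of the trace maximum.
#' @param plateau_frac Fraction of the horizon defining the plateau window.
#' @param refine Refine peak/trough locations between grid points by local
#'   parabolic interpolation (exact for smooth extrema; disable for
#'   piecewise-linear traces whose vertices lie on the grid).
#' @return A list of class `meio_features`: `t_peak`, `m_peak`, `m_trough`,
#'   `t_trough`, `m_plateau`, `plateau_converged`, `n_peaks`,
#'   `peak_heights`, `m_final`, `m_max`, `horizon`.
#' @export
mpf_features <- function(traj, min_peak = NULL, plateau_frac = 0.1,
                         refine = TRUE) {
  tt <- traj$time
  y <- traj$mpf_a
  stopifnot(length(tt) == length(y), !is.unsorted(tt))
  n <- length(y)
  horizon <- tt[n] - tt[1]
  if (is.null(min_peak)) min_peak <- 0.2 * max(y)

  ## interior local maxima: a rising segment followed -- possibly across a
  ## flat stretch -- by a falling segment; a terminal plateau is not a peak
  slope_runs <- rle(sign(diff(y)))
  run_ends <- cumsum(slope_runs$lengths)
  nz <- which(slope_runs$values != 0)
  is_max <- integer(0)
  if (length(nz) > 1) {
    for (k in seq_len(length(nz) - 1)) {
      if (slope_runs$values[nz[k]] > 0 && slope_runs$values[nz[k + 1]] < 0) {
        is_max <- c(is_max, run_ends[nz[k]] + 1L)
      }
    }
  }
  peaks <- is_max[y[is_max] >= min_peak & min_peak > 0]
  ## activation time: first crossing of the peak-detection floor
  t_act <- if (max(y) >= min_peak && min_peak > 0) {
    tt[which(y >= min_peak)[1]]
  } else NA_real_
  ## plateau over the final window
  win <- tt >= tt[n] - plateau_frac * horizon
  m_plateau <- mean(y[win])
  slope_end <- abs((y[n] - y[which(win)[1]]) /
                     max(tt[n] - tt[which(win)[1]], .Machine$double.eps))
  if (length(peaks) == 0) {
    out <- list(t_peak = NA_real_, m_peak = NA_real_, t_act = t_act,
                t_trough = NA_real_,
                m_trough = NA_real_, m_plateau = m_plateau,
                plateau_converged = NA, n_peaks = 0L,
                peak_heights = numeric(0), m_final = y[n], m_max = max(y),
                horizon = horizon)
    class(out) <- "meio_features"
    return(out)
  }
  first <- peaks[1]
  ## parabolic refinement of the peak location between grid points
  refine_max <- function(i) {
    if (!refine || i <= 1 || i >= n) return(c(tt[i], y[i]))
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    if (denom >= 0) return(c(tt[i], y[i]))
    delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
    delta <- max(-0.5, min(0.5, delta))
    c(tt[i] + delta * (tt[min(i + 1, n)] - tt[i]),
      y[i] - 0.25 * (y[i - 1] - y[i + 1]) * delta)
  }
  pk <- refine_max(first)
  t_peak_ref <- pk[1]
  m_peak <- pk[2]
  plateau_converged <- slope_end < 1e-3 * m_peak / horizon * max(tt[n], 1)
  ## trough: global minimum between the first peak and the plateau window,
  ## refined parabolically between grid points
  span <- seq(first, max(first, which(win)[1]))
  imin <- span[which.min(y[span])]
  tr <- if (refine && imin > 1 && imin < n &&
            (y[imin - 1] - 2 * y[imin] + y[imin + 1]) > 0) {
    delta <- 0.5 * (y[imin - 1] - y[imin + 1]) /
      (y[imin - 1] - 2 * y[imin] + y[imin + 1])
    delta <- max(-0.5, min(0.5, delta))
    c(tt[imin] + delta * (tt[min(imin + 1, n)] - tt[imin]),
      y[imin] - 0.25 * (y[imin - 1] - y[imin + 1]) * delta)
  } else c(tt[imin], y[imin])
  t_trough <- tr[1]
  m_trough <- tr[2]
  out <- list(
    t_peak = t_peak_ref, m_peak = m_peak, t_act = t_act,
    t_trough = t_trough, m_trough = m_trough,
    m_plateau = m_plateau, plateau_converged = plateau_converged,
    n_peaks = length(peaks), peak_heights = y[peaks],
    m_final = y[n], m_max = max(y), horizon = horizon
  )
  class(out) <- "meio_features"
  out
}

#' @export
print.meio_features <- function(x, ...) {
  cat("MPF trajectory indicators\n")
  cat(sprintf("  first peak : t = %s, height = %s\n",
              signif(x$t_peak, 4), signif(x$m_peak, 4)))
  cat(sprintf("  trough     : t = %s, level = %s\n",
              signif(x$t_trough, 4), signif(x$m_trough, 4)))
  cat(sprintf("  plateau    : %s (converged: %s)\n",
              signif(x$m_plateau, 4), x$plateau_converged))
  cat(sprintf("  peaks      : %d\n", x$n_peaks))
  invisible(x)
}

#' Default phenotype-classification rules
#'
#' Thresholds (all relative to the wild-type reference) used by
#' [classify_phenotype()]. See that function for the rule definitions.
#'
#' @return Named list of thresholds.
#' @export
classifier_rules <- function() {
  list(
    delay_factor = 1.5,        # t_peak > 1.5 x wild type => entry delay
    no_peak_factor = 3,        # no peak within 3 x wild-type t_peak
    fail_plateau_frac = 0.2,   # plateau below 0.2 x wild type => MII failure
    inter_plateau_frac = 0.7,  # 0.2-0.7 x wild type => intermediate plateau
    arrest_trough_frac = 0.8,  # trough > 0.8 x peak => no trough, MI arrest
    osc_min_peaks = 3,         # >= 3 prominent maxima
    osc_height_tol = 0.5,      # successive peak heights within 50%
    interphase_frac = 0.05     # MPF < 0.05 x wild-type plateau at the end
  )
}

#' Classify a maturation phenotype from MPF indicators
#'
#' Assigns exactly one phenotype label by comparing the MPF indicators of a
#' trajectory with the wild-type reference, using explicit threshold rules:
#' oscillations (>= `osc_min_peaks` prominent maxima with successive heights
#' within `osc_height_tol` of each other), MI arrest (no trough:
#' `m_trough > arrest_trough_frac * m_peak`), MII-entry failure (a peak but
#' `m_plateau < fail_plateau_frac` x wild type), MI/MII failure with
#' intermediate plateau (`fail_plateau_frac`-`inter_plateau_frac` x wild
#' type), MI-entry delay (`t_peak > delay_factor` x wild type), MI-entry
#' failure (no peak within `no_peak_factor` x wild-type `t_peak`),
#' interphase exit (no peak retained and MPF below `interphase_frac` x
#' wild-type plateau after an initial rise), else normal maturation.
#'
#' @param features `meio_features` of the trajectory under study.
#' @param wild_type `meio_features` of the unperturbed reference.
#' @param rules Threshold list, see [classifier_rules()].
#' @return A one-row tibble: `label`, the indicator ratios used as evidence
#'   (`t_peak_ratio`, `plateau_ratio`, `trough_peak_ratio`), `n_peaks` and
#'   the logical `delayed`.
#' @export
classify_phenotype <- function(features, wild_type, rules = classifier_rules()) {
  r <- rules
  if (!(r$fail_plateau_frac < r$inter_plateau_frac &&
        r$interphase_frac < r$fail_plateau_frac &&
        r$delay_factor < r$no_peak_factor &&
        r$arrest_trough_frac > 0 && r$arrest_trough_frac <= 1)) {
    stop("inconsistent classifier rule thresholds", call. = FALSE)
  }
  stopifnot(is.finite(wild_type$t_peak), is.finite(wild_type$m_plateau))
  f <- features
  t_ratio <- f$t_peak / wild_type$t_peak
  ta_ratio <- f$t_act / wild_type$t_peak
  pl_ratio <- f$m_plateau / wild_type$m_plateau
  tr_ratio <- if (is.finite(f$m_trough) && is.finite(f$m_peak) && f$m_peak > 0)
    f$m_trough / f$m_peak else NA_real_
  delayed <- (is.finite(t_ratio) && t_ratio > r$delay_factor) ||
    (is.finite(ta_ratio) && ta_ratio > r$delay_factor)

  osc <- FALSE
  if (f$n_peaks >= r$osc_min_peaks) {
    h <- f$peak_heights
    rel <- abs(diff(h)) / pmax(h[-length(h)], .Machine$double.eps)
    osc <- all(rel <= r$osc_height_tol)
  }

  no_trough <- is.na(tr_ratio) || tr_ratio > r$arrest_trough_frac
  label <- if (is.na(f$t_act)) {
    ## MPF never activated above the detection floor
    rose <- f$m_max >= r$fail_plateau_frac * wild_type$m_plateau
    fell <- f$m_final < r$interphase_frac * wild_type$m_plateau
    if (rose && fell) "interphase_exit" else "MI_entry_failure"
  } else if (osc) {
    "oscillations"
  } else if (pl_ratio >= r$inter_plateau_frac && no_trough &&
             f$t_act <= r$no_peak_factor * wild_type$t_peak) {
    ## activated on time, stayed high, never dipped: metaphase-I arrest
    "MI_arrest"
  } else if (f$t_act > r$no_peak_factor * wild_type$t_peak || is.na(f$t_peak)) {
    "MI_entry_failure"
  } else if (pl_ratio < r$fail_plateau_frac) {
    "MII_entry_failure"
  } else if (pl_ratio < r$inter_plateau_frac) {
    "MI_MII_failure_intermediate_plateau"
  } else if (delayed) {
    "MI_entry_delay"
  } else {
    "normal_maturation"
  }
  tibble::tibble(
    label = label,
    t_peak_ratio = t_ratio,
    t_act_ratio = ta_ratio,
    plateau_ratio = pl_ratio,
    trough_peak_ratio = tr_ratio,
    n_peaks = f$n_peaks,
    delayed = delayed
  )
}

#' Phenotype labels recognized by the classifier
#' @return Character vector of the closed label set.
#' @export
phenotype_labels <- function() {
  c("normal_maturation", "MI_entry_delay", "MI_entry_failure",
    "MII_entry_failure", "MI_MII_failure_intermediate_plateau",
    "MI_arrest", "oscillations", "interphase_exit")
}
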