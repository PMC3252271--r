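## ---- dual parameter-sensitivity measures --------------------------------

## Newton solve of the extended fold system {f = 0, J v = 0, |v| = 1}
## starting from a fold guess; shared by detect_folds() and fold tracking
.fold_newton <- function(fun, x0, q0, tol = 1e-10, max_iter = 40,
                         max_step = 1) {
  n <- length(x0)
  J <- .jac_x(fun, x0, q0)
  v <- svd(J)$v[, n]
  u <- c(x0, v, q0)
  G <- function(u) {
    x <- u[1:n]; v <- u[(n + 1):(2 * n)]; q <- u[2 * n + 1]
    c(fun(x, q), .jac_x(fun, x, q) %*% v, sum(v^2) - 1)
  }
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    g <- G(u)
    if (all(is.finite(g)) && sqrt(sum(g^2)) < tol * 10) { conv <- TRUE; break }
    if (!all(is.finite(g))) break
    m <- length(u)
    Jg <- matrix(0, m, m)
    for (j in seq_len(m)) {
      h <- 1e-6 * max(abs(u[j]), 1)
      up <- u; up[j] <- u[j] + h
      um <- u; um[j] <- u[j] - h
      Jg[, j] <- (G(up) - G(um)) / (2 * h)
    }
    du <- tryCatch(solve(Jg, -g), error = function(e) NULL)
    if (is.null(du)) break
    if (max(abs(du)) > max_step) du <- du * max_step / max(abs(du))
    u <- u + du
  }
  list(state = u[1:n], q = u[2 * n + 1], converged = conv)
}

#' Wild-type reference for sensitivity analysis
#'
#' Computes, once, everything the sensitivity measures compare against: the
#' G2 state, the wild-type trajectory and its MPF indicators, and the
#' bifurcation thresholds `P_I` and `P_IV` with the corresponding fold
#' states (used as starting points for local fold tracking under parameter
#' perturbations).
#'
#' @param params Named numeric parameter vector.
#' @param amplitude Progesterone step amplitude of the reference protocol.
#' @param horizon Simulation horizon.
#' @return List of class `meio_reference` with `params`, `features`,
#'   `P_I`, `P_IV`, `fold_I`, `fold_IV` (state vectors), `amplitude`,
#'   `horizon`.
#' @export
sensitivity_reference <- function(params, amplitude = 1, horizon = 60) {
  validate_parameters(params)
  g2 <- g2_state(params)
  traj <- simulate_maturation(params, input_step(amplitude),
                              horizon = horizon, init = g2)
  feat <- mpf_features(traj)
  diag <- bifurcation_diagram(params)
  structure(list(
    params = params, features = feat,
    P_I = diag$P_I, P_IV = diag$P_IV,
    fold_I = diag$fold_I_state, fold_IV = diag$fold_IV_state,
    amplitude = amplitude, horizon = horizon
  ), class = "meio_reference")
}

## indicator vector (t_peak, m_trough, m_plateau) of a perturbed run;
## NA components mean the indicator is undefined under the perturbation
.indicators <- function(params, ref) {
  traj <- tryCatch(
    simulate_maturation(params, input_step(ref$amplitude),
                        horizon = ref$horizon, init = g2_state(params)),
    error = function(e) NULL
  )
  if (is.null(traj)) return(c(t_peak = NA, m_trough = NA, m_plateau = NA))
  f <- mpf_features(traj, min_peak = 0.2 * ref$features$m_plateau)
  c(t_peak = f$t_peak, m_trough = f$m_trough, m_plateau = f$m_plateau)
}

#' Dynamic (trajectory-indicator) parameter sensitivity
#'
#' Measures how strongly a parameter shapes the MPF time course: the
#' parameter is perturbed two-sided on the log scale, the maturation
#' protocol re-simulated, and the weighted absolute central logarithmic
#' derivatives of the three indicators -- first-peak time `t_peak` (early,
#' G2/MI), trough `m_trough` and plateau `m_plateau` (late, MI/MII) --
#' combined. The normalized sensitivity is the late share
#' `late / (early + late)`, in `[0, 1]`: values near 0 mark parameters
#' controlling meiotic resumption, values near 1 parameters controlling the
#' MI/MII transition.
#'
#' A parameter whose reference value is zero has, by convention, zero
#' sensitivity. An indicator that disappears under perturbation (e.g., no
#' peak) contributes the saturation value `cap` and the record is flagged
#' censored.
#'
#' @param params Named numeric parameter vector.
#' @param param_id Parameter to perturb.
#' @param rel_delta Relative perturbation (default 0.1; factor
#'   `1 + rel_delta` up, its inverse down).
#' @param weights Named weights for `t_peak`, `m_trough`, `m_plateau`.
#' @param ref Reference from [sensitivity_reference()].
#' @param cap Saturation value for censored indicator derivatives.
#' @return One-row tibble: `id`, `s_dyn`, `s_dyn_early`, `s_dyn_late`,
#'   `s_dyn_norm`, `censored_dyn`.
#' @export
dynamic_sensitivity <- function(params, param_id, rel_delta = 0.1,
                                weights = c(t_peak = 1, m_trough = 1,
                                            m_plateau = 1),
                                ref = sensitivity_reference(params),
                                cap = 5) {
  stopifnot(param_id %in% names(params), rel_delta > 0, rel_delta <= 0.5)
  p0 <- params[[param_id]]
  if (p0 == 0) {
    return(tibble::tibble(id = param_id, s_dyn = 0, s_dyn_early = 0,
                          s_dyn_late = 0, s_dyn_norm = NA_real_,
                          censored_dyn = FALSE))
  }
  m <- 1 + rel_delta
  up <- params; up[[param_id]] <- p0 * m
  dn <- params; dn[[param_id]] <- p0 / m
  iu <- .indicators(up, ref)
  id_ <- .indicators(dn, ref)
  dln <- (log(iu) - log(id_)) / (2 * log(m))
  censored <- anyNA(dln) | any(!is.finite(dln))
  dln[!is.finite(dln)] <- cap
  dln <- pmin(abs(dln), cap)
  w <- weights[c("t_peak", "m_trough", "m_plateau")]
  early <- w[["t_peak"]] * dln[["t_peak"]]
  late <- w[["m_trough"]] * dln[["m_trough"]] +
    w[["m_plateau"]] * dln[["m_plateau"]]
  tibble::tibble(id = param_id, s_dyn = early + late, s_dyn_early = early,
                 s_dyn_late = late,
                 s_dyn_norm = if (early + late > 0) late / (early + late)
                 else NA_real_,
                 censored_dyn = censored)
}

## displacement of one fold under perturbed parameters, by local fold
## tracking from the reference fold state
.fold_displacement <- function(params, fold_state, fold_q) {
  fun <- .model_field(params)
  out <- .fold_newton(fun, fold_state, fold_q, tol = 1e-9)
  if (!out$converged || abs(out$q - fold_q) > 0.5) return(NA_real_)
  out$q
}

#' Bifurcation-threshold parameter sensitivity
#'
#' Measures how strongly a parameter displaces the two progesterone
#' thresholds of the maturation switch: `P_I` (the fold destabilizing the
#' G2 state) and `P_IV` (the fold bounding the metaphase-II state). The
#' parameter is perturbed two-sided on the log scale and each fold is
#' re-located by Newton iteration on the extended fold system starting from
#' the reference fold (local fold tracking). The sensitivity components are
#' the absolute central derivatives `|dP/d log k|`; the normalized form is
#' the `P_IV` share, in `[0, 1]`.
#'
#' @inheritParams dynamic_sensitivity
#' @return One-row tibble: `id`, `s_bif`, `s_bif_I`, `s_bif_IV`,
#'   `s_bif_norm`, `censored_bif` (fold lost under perturbation).
#' @export
bifurcation_sensitivity <- function(params, param_id, rel_delta = 0.1,
                                    ref = sensitivity_reference(params)) {
  stopifnot(param_id %in% names(params), rel_delta > 0, rel_delta <= 0.5)
  p0 <- params[[param_id]]
  if (p0 == 0) {
    return(tibble::tibble(id = param_id, s_bif = 0, s_bif_I = 0,
                          s_bif_IV = 0, s_bif_norm = NA_real_,
                          censored_bif = FALSE))
  }
  m <- 1 + rel_delta
  up <- params; up[[param_id]] <- p0 * m
  dn <- params; dn[[param_id]] <- p0 / m
  pi_u <- .fold_displacement(up, ref$fold_I, ref$P_I)
  pi_d <- .fold_displacement(dn, ref$fold_I, ref$P_I)
  piv_u <- .fold_displacement(up, ref$fold_IV, ref$P_IV)
  piv_d <- .fold_displacement(dn, ref$fold_IV, ref$P_IV)
  s_i <- abs(pi_u - pi_d) / (2 * log(m))
  s_iv <- abs(piv_u - piv_d) / (2 * log(m))
  censored <- anyNA(c(s_i, s_iv))
  s_i <- ifelse(is.na(s_i), 0, s_i)
  s_iv <- ifelse(is.na(s_iv), 0, s_iv)
  tibble::tibble(id = param_id, s_bif = s_i + s_iv, s_bif_I = s_i,
                 s_bif_IV = s_iv,
                 s_bif_norm = if (s_i + s_iv > 0) s_iv / (s_i + s_iv)
                 else NA_real_,
                 censored_bif = censored)
}

#' Systematic sensitivity screen over the interaction parameters
#'
#' Computes both sensitivity measures for every interaction parameter (a
#' parameter associated with a link in the network diagram; see
#' [parameter_table()]). Deterministic ordering; per-parameter failures are
#' recorded and the screen continues.
#'
#' @param params Named numeric parameter vector.
#' @param ids Parameter identifiers to screen (default: all interaction
#'   parameters).
#' @param rel_delta Relative perturbation size.
#' @param weights Indicator weights for the dynamic measure.
#' @param ref Precomputed [sensitivity_reference()]; computed if missing.
#' @param verbose Print progress.
#' @return Tibble of class `meio_sensitivity` with one row per parameter:
#'   dynamic and bifurcation components, normalized values and censoring
#'   flags.
#' @export
sensitivity_screen <- function(params, ids = NULL, rel_delta = 0.1,
                               weights = c(t_peak = 1, m_trough = 1,
                                           m_plateau = 1),
                               ref = NULL, verbose = FALSE) {
  validate_parameters(params)
  if (is.null(ids)) ids <- .interaction_params()
  ids <- sort(ids)
  if (is.null(ref)) ref <- sensitivity_reference(params)
  rows <- lapply(ids, function(id) {
    if (verbose) message("screening ", id)
    d <- tryCatch(
      dynamic_sensitivity(params, id, rel_delta, weights, ref),
      error = function(e) tibble::tibble(id = id, s_dyn = NA_real_,
                                         s_dyn_early = NA_real_,
                                         s_dyn_late = NA_real_,
                                         s_dyn_norm = NA_real_,
                                         censored_dyn = TRUE))
    b <- tryCatch(
      bifurcation_sensitivity(params, id, rel_delta, ref),
      error = function(e) tibble::tibble(id = id, s_bif = NA_real_,
                                         s_bif_I = NA_real_,
                                         s_bif_IV = NA_real_,
                                         s_bif_norm = NA_real_,
                                         censored_bif = TRUE))
    dplyr::left_join(d, b, by = "id")
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("meio_sensitivity", class(out))
  attr(out, "rel_delta") <- rel_delta
  attr(out, "weights") <- weights
  out
}

#' Partition interaction parameters into maturation-control modules
#'
#' Assigns each screened parameter to the G2/MI (meiotic resumption) or
#' MI/MII (meiotic transition) control module from its normalized
#' sensitivities: parameters with total sensitivity below `negligible_thr`
#' are negligible; otherwise the mean of the available normalized values is
#' compared with `low_thr` (at or below: G2/MI) and `high_thr` (at or
#' above: MI/MII); intermediate values are reported as ambiguous.
#'
#' @param records `meio_sensitivity` tibble from [sensitivity_screen()].
#' @param low_thr,high_thr Normalized-value thresholds
#'   (`0 <= low_thr < high_thr <= 1`).
#' @param negligible_thr Total-sensitivity floor; default 5% of the median
#'   total sensitivity.
#' @return Tibble: `id`, `s_total`, `s_norm`, `module` (one of `"G2_MI"`,
#'   `"MI_MII"`, `"negligible"`, `"ambiguous"`).
#' @export
partition_modules <- function(records, low_thr = 0.3, high_thr = 0.7,
                              negligible_thr = NULL) {
  stopifnot(low_thr >= 0, high_thr <= 1, low_thr < high_thr)
  s_total <- rowSums(cbind(records$s_dyn, records$s_bif), na.rm = TRUE)
  if (is.null(negligible_thr)) {
    negligible_thr <- 0.05 * stats::median(s_total, na.rm = TRUE)
  }
  s_norm <- rowMeans(cbind(records$s_dyn_norm, records$s_bif_norm),
                     na.rm = TRUE)
  module <- dplyr::case_when(
    s_total < negligible_thr | is.nan(s_norm) ~ "negligible",
    s_norm >= high_thr ~ "MI_MII",
    s_norm <= low_thr ~ "G2_MI",
    TRUE ~ "ambiguous"
  )
  tibble::tibble(id = records$id, s_total = s_total, s_norm = s_norm,
                 module = module)
}

#' @export
glance.meio_sensitivity <- function(x, ...) {
  ok <- stats::complete.cases(x$s_dyn_norm, x$s_bif_norm)
  tibble::tibble(
    n_params = nrow(x),
    cor_norm = stats::cor(x$s_dyn_norm[ok], x$s_bif_norm[ok]),
    frac_extreme = {
      v <- c(x$s_dyn_norm[ok], x$s_bif_norm[ok])
      mean(pmin(v, 1 - v) <= 0.2)
    },
    n_censored = sum(x$censored_dyn | x$censored_bif)
  )
}
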