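#' Simulate the maturation network in time
#'
#' Integrates the 13-variable class-I system under a progesterone input with
#' a stiff-capable solver ([deSolve::lsoda()]). The default initial state is
#' the G2-arrest equilibrium at zero input, so that the trajectory isolates
#' the response to the progesterone signal.
#'
#' @param params Named numeric parameter vector.
#' @param input Progesterone input: a `meio_input` profile from
#'   [make_input_profile()], or a single number (constant signal).
#' @param horizon Integration horizon (hours).
#' @param init Initial state; default the G2 equilibrium from [g2_state()].
#' @param n_grid Number of output time points (at least 201; default
#'   resolves the horizon to 1/400).
#' @param rtol,atol Solver tolerances (reference contract: 1e-8 / 1e-10).
#' @return A tibble of class `meio_trajectory`: `time`, the 13 state
#'   variables, derived totals and activities (`mos`, `mpf`, `apc`, `c1`,
#'   `c4`, `emi` totals; `mpf_act` etc. aliases), the six class-II
#'   activities, and the input value `pg`. Solver settings and inputs are
#'   attached as attributes.
#' @export
#' @examples
#' \donttest{
#' traj <- simulate_maturation(default_parameters(), input_step(1),
#'                             horizon = 30)
#' mpf_features(traj)
#' }
simulate_maturation <- function(params, input = input_step(1), horizon = 40,
                                init = NULL, n_grid = 801,
                                rtol = 1e-8, atol = 1e-10) {
  validate_parameters(params)
  if (horizon <= 0) stop("horizon must be positive", call. = FALSE)
  n_grid <- max(n_grid, 201)
  profile <- if (is.function(input)) input else make_input_profile(
    "step", amplitude = input)
  if (is.null(init)) init <- g2_state(params)
  init <- init[.state_names]
  times <- seq(0, horizon, length.out = n_grid)
  ## restart integration at input discontinuities so lsoda cannot step over
  ## a pulse edge
  breaks <- c(attr(profile, "onset"), attr(profile, "onset") +
                attr(profile, "duration"))
  breaks <- breaks[!is.na(breaks) & breaks > 0 & breaks < horizon]
  segs <- sort(unique(c(0, breaks, horizon)))
  out <- NULL
  y <- init
  for (k in seq_len(length(segs) - 1)) {
    tt <- unique(sort(c(segs[k], times[times > segs[k] & times < segs[k + 1]],
                        segs[k + 1])))
    mid <- (segs[k] + segs[k + 1]) / 2
    seg_fun <- function(t, state, parms) {
      meiotic_rhs(t, state, parms, profile)
    }
    sol <- deSolve::lsoda(y, tt, seg_fun, params, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      stop("integrator failure near t = ", max(sol[, "time"]), call. = FALSE)
    }
    y <- sol[nrow(sol), .state_names]
    keep <- if (is.null(out)) sol else sol[-1, , drop = FALSE]
    out <- rbind(out, keep)
  }
  tb <- tibble::as_tibble(as.data.frame(out))
  names(tb)[1] <- "time"   # remaining columns: 13 states + 6 class-II aux
  tb$pg <- profile(tb$time)
  tb <- dplyr::mutate(tb,
    mos = .data$mos_i + .data$mos_a,
    mpf = .data$mpf_i + .data$mpf_a,
    apc = .data$apc_i + .data$apc_a,
    c1 = .data$c1_i + .data$c1_a,
    c4 = .data$c4_i + .data$c4_a,
    emi = .data$emi_u + .data$emi_a + .data$emi_p
  )
  structure(tb,
            class = c("meio_trajectory", class(tb)),
            params = params, input = profile,
            solver = list(rtol = rtol, atol = atol, n_grid = n_grid,
                          horizon = horizon))
}

#' G2-arrest equilibrium at zero progesterone
#'
#' Relaxes the system from the nominal resting state at zero input and
#' polishes the endpoint with Newton iterations to an equilibrium residual
#' below `tol`.
#'
#' @param params Named numeric parameter vector.
#' @param tol Residual tolerance.
#' @param t_relax Relaxation horizon before polishing.
#' @return Named equilibrium state vector.
#' @export
g2_state <- function(params, tol = 1e-10, t_relax = 400) {
  f <- function(t, state, parms) meiotic_rhs(t, state, parms, 0)
  sol <- deSolve::lsoda(resting_state(params), c(0, t_relax / 2, t_relax),
                        f, params, rtol = 1e-9, atol = 1e-11)
  y <- sol[nrow(sol), .state_names]
  eq <- newton_equilibrium(y, params, progesterone = 0, tol = tol)
  if (!eq$converged) {
    warning("G2 state polish did not reach tolerance; residual ",
            signif(eq$residual, 3), call. = FALSE)
  }
  eq$state
}

#' Tidy a trajectory to long format
#'
#' @param x A `meio_trajectory`.
#' @param ... Unused.
#' @return Long tibble with columns `time`, `species`, `value`.
#' @export
tidy.meio_trajectory <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"time",
                      names_to = "species", values_to = "value")
}

#' One-row summary of a trajectory
#'
#' @param x A `meio_trajectory`.
#' @param ... Unused.
#' @return One-row tibble with the MPF trajectory indicators.
#' @export
glance.meio_trajectory <- function(x, ...) {
  f <- mpf_features(x)
  tibble::as_tibble(f[c("t_peak", "m_peak", "m_trough", "m_plateau",
                        "n_peaks")])
}
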