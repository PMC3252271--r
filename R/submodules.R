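## ---- isolated submodule analyses (calibration constraints) --------------

#' Vector field of the isolated MAPK module
#'
#' The MAPK cascade in isolation: Mos total fixed at 1 (synthesis and
#' degradation frozen, as at G2), MEK/ERK/Rsk by quasi-steady state, the
#' ERK-to-Mos feedback active, and a Mos-activating drive as control
#' parameter. The state is the single variable `mos_a`.
#'
#' @param params Named numeric parameter vector.
#' @return `function(x, drive)` returning `d mos_a / dt`.
#' @export
mapk_field <- function(params) {
  p <- params
  function(x, drive) {
    mos_a <- x[1]
    mek <- class2_activity_two_step(p[["ka_mek_mos"]] * mos_a, p[["ki_mek_0"]])
    erk <- class2_activity_two_step(p[["ka_erk_mek"]] * mek, p[["ki_erk_0"]])
    michaelis_flux(drive + p[["ka_mos_erk"]] * erk, 1 - mos_a,
                   p[["km_act_mos"]]) -
      michaelis_flux(p[["ki_mos_0"]], mos_a, p[["km_inact_mos"]])
  }
}

#' ERK activity implied by a Mos activity level
#' @param params Named numeric parameter vector.
#' @param mos_a Active Mos level(s).
#' @return ERK doubly-phosphorylated fraction.
#' @export
mapk_erk_activity <- function(params, mos_a) {
  mek <- class2_activity_two_step(params[["ka_mek_mos"]] * mos_a,
                                  params[["ki_mek_0"]])
  class2_activity_two_step(params[["ka_erk_mek"]] * mek, params[["ki_erk_0"]])
}

#' Bifurcation diagram of the isolated MAPK switch
#'
#' Continues the steady state of the isolated MAPK module against the
#' Mos-activating drive. In the reference configuration the module is a
#' bistable switch: the diagram has two folds and the up-switch threshold
#' exceeds the down-switch threshold (hysteresis).
#'
#' @param params Named numeric parameter vector.
#' @param drive_range Control-parameter window.
#' @param ... Passed to [continue_branch()].
#' @return List of class `meio_mapk_switch` with `points` (tibble: `q`,
#'   `mos_a`, `erk`, `stable`), `folds`, `up_threshold`, `down_threshold`.
#' @export
mapk_switch_diagram <- function(params, drive_range = c(0, 0.6), ...) {
  fun <- mapk_field(params)
  eq <- .newton_eq(fun, 0.01, drive_range[1], tol = 1e-12)
  br <- continue_branch(fun, eq$state, drive_range[1], drive_range,
                        direction = 1, h0 = 0.005, h_max = 0.02,
                        tol = 1e-12, ...)
  folds <- detect_folds(br, fun, tol = 1e-12)
  pts <- tibble::tibble(
    q = br$q,
    mos_a = vapply(br$state, `[`, numeric(1), 1),
    stable = br$stable, max_re = br$max_re
  )
  pts$erk <- mapk_erk_activity(params, pts$mos_a)
  up <- if (nrow(folds) >= 1) max(folds$q) else NA_real_
  down <- if (nrow(folds) >= 2) min(folds$q) else NA_real_
  structure(list(points = pts, folds = folds,
                 up_threshold = up, down_threshold = down),
            class = "meio_mapk_switch")
}

#' @export
print.meio_mapk_switch <- function(x, ...) {
  cat("Isolated MAPK switch: ", nrow(x$folds), " fold(s); up ",
      signif(x$up_threshold, 4), ", down ", signif(x$down_threshold, 4),
      "\n", sep = "")
  invisible(x)
}

#' Vector field of the isolated MPF-APC module
#'
#' The core oscillator: MPF (two forms) and APC (two forms), with Cdc25 and
#' Myt1 at quasi-steady state driven by MPF only, no Emi2 (frozen at its G2
#' value of zero) and no Plx1/MAPK couplings. Cyclin synthesis is the drive.
#'
#' @param params Named numeric parameter vector.
#' @return `function(x, drive)` on the state
#'   `(mpf_i, mpf_a, apc_i, apc_a)`.
#' @export
mpf_apc_field <- function(params) {
  p <- params
  function(x, drive) {
    mpf_i <- x[1]; mpf_a <- x[2]; apc_i <- x[3]; apc_a <- x[4]
    c25 <- class2_activity_one_step(p[["ka_c25_mpf"]] * mpf_a, p[["ki_c25_0"]])
    myt <- class2_activity_one_step(p[["ka_myt_0"]],
                                    p[["ki_myt_mpf"]] * mpf_a)
    kd <- p[["kd_mpf_0"]] + p[["kd_mpf_apc"]] * apc_a
    act <- michaelis_flux(p[["ka_mpf_0"]] + p[["ka_mpf_c25"]] * c25, mpf_i,
                          p[["km_act_mpf"]])
    ina <- michaelis_flux(p[["ki_mpf_0"]] + p[["ki_mpf_myt"]] * myt, mpf_a,
                          p[["km_inact_mpf"]])
    act_apc <- michaelis_flux(p[["ka_apc_mpf"]] * mpf_a, apc_i,
                              p[["km_act_apc"]])
    ina_apc <- michaelis_flux(p[["ki_apc_0"]], apc_a, p[["km_inact_apc"]])
    c(-act + ina - kd * mpf_i,
      drive + act - ina - kd * mpf_a,
      p[["ks_apc_0"]] - act_apc + ina_apc - p[["kd_apc_0"]] * apc_i,
      act_apc - ina_apc - p[["kd_apc_0"]] * apc_a)
  }
}

#' Simulate the isolated MPF-APC module
#'
#' @param params Named numeric parameter vector.
#' @param drive Cyclin-synthesis drive.
#' @param horizon Integration horizon.
#' @param init Initial state (default: small cyclin store, all inactive).
#' @param n_grid Output grid size.
#' @return Tibble with `time`, `mpf_i`, `mpf_a`, `apc_i`, `apc_a`.
#' @export
simulate_mpf_apc <- function(params, drive, horizon = 400,
                             init = c(0.1, 0, 1, 0), n_grid = 4001) {
  fun <- mpf_apc_field(params)
  f <- function(t, y, parms) list(fun(y, drive))
  sol <- deSolve::lsoda(init, seq(0, horizon, length.out = n_grid), f, NULL,
                        rtol = 1e-9, atol = 1e-11)
  out <- tibble::as_tibble(as.data.frame(sol))
  names(out) <- c("time", "mpf_i", "mpf_a", "apc_i", "apc_a")
  out
}

## period of sustained oscillation from MPF maxima after transient discard;
## NA if the tail is steady or cycles are not resolved
.osc_period <- function(time, y, discard_frac = 0.5, amp_tol = 1e-3) {
  keep <- time >= time[1] + discard_frac * (max(time) - time[1])
  tt <- time[keep]; yy <- y[keep]
  if (max(yy) - min(yy) < amp_tol) return(list(period = NA_real_,
                                               amplitude = max(yy) - min(yy),
                                               n_cycles = 0L))
  im <- which(diff(sign(diff(yy))) < 0) + 1
  im <- im[yy[im] > min(yy) + 0.5 * (max(yy) - min(yy))]
  if (length(im) < 3) return(list(period = NA_real_,
                                  amplitude = max(yy) - min(yy),
                                  n_cycles = length(im)))
  per <- diff(tt[im])
  list(period = stats::median(per), amplitude = max(yy) - min(yy),
       n_cycles = length(im))
}

#' Oscillation scan of the isolated MPF-APC module
#'
#' Long-run simulation at each drive value classifies the attractor as
#' steady or periodic; periods are measured from successive MPF maxima after
#' transient discard. Oscillations appear at a saddle-node of the low-MPF
#' equilibrium (see [mpf_apc_sn()]) with steeply increasing period toward
#' onset, and the module is excitable below onset.
#'
#' @param params Named numeric parameter vector.
#' @param drives Numeric vector of drive values to scan.
#' @param horizon Simulation horizon per drive.
#' @return Tibble of class `meio_limit_cycle_scan`: `drive`, `oscillating`,
#'   `period`, `amplitude`, `censored` (period unresolved within the
#'   horizon).
#' @export
mpf_apc_scan <- function(params, drives, horizon = 600) {
  rows <- lapply(drives, function(d) {
    traj <- simulate_mpf_apc(params, d, horizon = horizon)
    o <- .osc_period(traj$time, traj$mpf_a)
    tibble::tibble(drive = d, oscillating = is.finite(o$period),
                   period = o$period, amplitude = o$amplitude,
                   censored = !is.finite(o$period) & o$amplitude > 1e-3)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("meio_limit_cycle_scan", class(out))
  out
}

#' Oscillation onset of the MPF-APC module by bisection
#'
#' @param params Named numeric parameter vector.
#' @param lo,hi Bracket: `lo` steady, `hi` oscillating.
#' @param tol Drive tolerance.
#' @param horizon Simulation horizon per probe.
#' @return Onset drive estimate.
#' @export
mpf_apc_onset <- function(params, lo, hi, tol = 1e-5, horizon = 800) {
  osc <- function(d) {
    traj <- simulate_mpf_apc(params, d, horizon = horizon)
    is.finite(.osc_period(traj$time, traj$mpf_a)$period)
  }
  if (osc(lo)) stop("lower bracket oscillates", call. = FALSE)
  if (!osc(hi)) stop("upper bracket does not oscillate", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (osc(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Saddle-node of the low-MPF state of the isolated MPF-APC module
#'
#' Tracks the low-MPF stable node in the cyclin-synthesis drive by Newton
#' continuation and brackets the drive value at which it disappears (the
#' saddle-node at the oscillation onset) by bisection.
#'
#' @param params Named numeric parameter vector.
#' @param q0 Starting drive (low, node must be stable there).
#' @param qmax Upper search bound.
#' @param dq Tracking step.
#' @param tol Bisection tolerance on the drive.
#' @return List with `drive` (the saddle-node location) and `state` (the node
#'   just below it).
#' @export
mpf_apc_sn <- function(params, q0 = 0.15, qmax = 6, dq = 0.01, tol = 1e-9) {
  fun <- mpf_apc_field(params)
  f <- function(t, y, parms) list(fun(y, q0))
  y <- deSolve::lsoda(c(0.5, 0.01, 1, 0.01), c(0, 600), f, NULL,
                      rtol = 1e-9, atol = 1e-11)[2, -1]
  r0 <- .newton_eq(fun, y, q0, tol = 1e-11)
  if (!r0$converged) stop("no stable node at the starting drive", call. = FALSE)
  ok_at <- function(q, xs) {
    r <- .newton_eq(fun, xs, q, tol = 1e-11)
    if (r$converged && max(abs(r$state - xs)) < 5 && all(r$state > -1e-8) &&
        .stability(fun, r$state, q)$stable) r$state else NULL
  }
  x <- r0$state; q <- q0
  while (q < qmax) {
    xn <- ok_at(q + dq, x)
    if (is.null(xn)) break
    x <- xn; q <- q + dq
  }
  if (q >= qmax) stop("no saddle-node found below qmax", call. = FALSE)
  lo <- q; hi <- q + dq
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    xn <- ok_at(mid, x)
    if (!is.null(xn)) { lo <- mid; x <- xn } else hi <- mid
  }
  list(drive = hi, state = x)
}
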