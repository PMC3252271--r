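## ---- generic equilibrium / continuation machinery -----------------------
## All routines work on a generic autonomous vector field fun(x, q) where q
## is the scalar continuation parameter (progesterone for the full model).

## finite-difference Jacobian wrt the state, central differences,
## relative step 1e-6 on max(|x|, 1)
.jac_x <- function(fun, x, q) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 1e-6 * max(abs(x[j]), 1)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (fun(xp, q) - fun(xm, q)) / (2 * h)
  }
  J
}

.jac_q <- function(fun, x, q) {
  h <- 1e-6 * max(abs(q), 1)
  (fun(x, q + h) - fun(x, q - h)) / (2 * h)
}

## Newton solve of fun(x, q) = 0 at fixed q
.newton_eq <- function(fun, x, q, tol = 1e-10, max_iter = 50) {
  for (i in seq_len(max_iter)) {
    f <- fun(x, q)
    res <- sqrt(sum(f^2))
    if (!is.finite(res)) return(list(state = x, residual = Inf,
                                     converged = FALSE))
    if (res < tol) return(list(state = x, residual = res, converged = TRUE))
    J <- .jac_x(fun, x, q)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) return(list(state = x, residual = res,
                                   converged = FALSE))
    ## damping against overshoot
    lam <- 1
    repeat {
      xn <- x + lam * step
      fn <- fun(xn, q)
      if (all(is.finite(fn)) && sqrt(sum(fn^2)) < res * (1 - 0.25 * lam) ||
          lam < 1e-4) break
      lam <- lam / 2
    }
    x <- x + lam * step
  }
  f <- fun(x, q)
  list(state = x, residual = sqrt(sum(f^2)),
       converged = sqrt(sum(f^2)) < tol)
}

.stability <- function(fun, x, q) {
  ev <- eigen(.jac_x(fun, x, q), only.values = TRUE)$values
  max_re <- max(Re(ev))
  list(eigenvalues = ev, max_re = max_re, stable = max_re < 0)
}

## vector field of the full model at fixed parameters, as fun(x, pg);
## progesterone is a formal real parameter (may be negative during
## continuation)
.model_field <- function(params) {
  force(params)
  function(x, q) {
    names(x) <- .state_names
    meiotic_rhs(0, x, params, q)[[1]]
  }
}

#' Solve for an equilibrium of the full model
#'
#' Newton iteration on the 13-variable right-hand side at a fixed
#' progesterone level, with central-difference Jacobians.
#'
#' @param state Starting state (named or in [state_names()] order).
#' @param params Named numeric parameter vector.
#' @param progesterone Progesterone level (formal real parameter).
#' @param tol Residual tolerance.
#' @return List with `state`, `residual`, `converged`, `stable`, `max_re`
#'   and `eigenvalues`.
#' @export
newton_equilibrium <- function(state, params, progesterone = 0, tol = 1e-10) {
  fun <- .model_field(params)
  x <- unname(state[.state_names])
  out <- .newton_eq(fun, x, progesterone, tol = tol)
  st <- .stability(fun, out$state, progesterone)
  names(out$state) <- .state_names
  c(out, st)
}

#' Locate equilibria of the full model by multistart Newton search
#'
#' Runs Newton iterations from seeded random states plus the G2 and
#' high-MPF anchor states and deduplicates the converged roots.
#'
#' @param params Named numeric parameter vector.
#' @param progesterone Progesterone level.
#' @param n_starts Number of random starting states.
#' @param seed Seed for the random starts.
#' @param tol Residual tolerance for acceptance.
#' @param merge_tol Distance below which two roots are considered identical.
#' @return Tibble with one row per equilibrium: `pg`, `mpf_a`, `stable`,
#'   `max_re`, `residual` and a list-column `state`.
#' @export
find_equilibria <- function(params, progesterone = 0, n_starts = 40,
                            seed = 1, tol = 1e-10, merge_tol = 1e-5) {
  validate_parameters(params)
  fun <- .model_field(params)
  starts <- list(unname(g2_state(params)[.state_names]),
                 unname(mii_state(params)[.state_names]))
  set.seed(seed)
  for (i in seq_len(n_starts)) {
    starts[[length(starts) + 1]] <- stats::runif(13, 0, 1.5)
  }
  roots <- list()
  for (x0 in starts) {
    out <- .newton_eq(fun, x0, progesterone, tol = tol)
    if (!out$converged) next
    x <- out$state
    if (any(x < -1e-8)) next   # non-physical root
    dup <- any(vapply(roots, function(r) sqrt(sum((r - x)^2)) < merge_tol,
                      logical(1)))
    if (!dup) roots[[length(roots) + 1]] <- x
  }
  if (length(roots) == 0) {
    return(tibble::tibble(pg = numeric(0), mpf_a = numeric(0),
                          stable = logical(0), max_re = numeric(0),
                          residual = numeric(0), state = list()))
  }
  rows <- lapply(roots, function(x) {
    st <- .stability(fun, x, progesterone)
    names(x) <- .state_names
    tibble::tibble(pg = progesterone, mpf_a = x[["mpf_a"]],
                   stable = st$stable, max_re = st$max_re,
                   residual = sqrt(sum(fun(unname(x), progesterone)^2)),
                   state = list(x))
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$mpf_a)
}

#' Metaphase-II (high-MPF) equilibrium at zero progesterone
#'
#' Obtained by driving the system with a saturating step, letting it settle,
#' switching the input off, relaxing, and polishing with Newton iterations.
#'
#' @inheritParams g2_state
#' @return Named equilibrium state vector.
#' @export
mii_state <- function(params, tol = 1e-10) {
  f1 <- function(t, state, parms) meiotic_rhs(t, state, parms, 2)
  f0 <- function(t, state, parms) meiotic_rhs(t, state, parms, 0)
  sol <- deSolve::lsoda(resting_state(params), c(0, 100), f1, params,
                        rtol = 1e-8, atol = 1e-10)
  y <- sol[nrow(sol), .state_names]
  sol <- deSolve::lsoda(y, c(0, 200), f0, params, rtol = 1e-8, atol = 1e-10)
  y <- sol[nrow(sol), .state_names]
  eq <- newton_equilibrium(y, params, 0, tol = tol)
  eq$state
}

#' Pseudo-arclength continuation of an equilibrium branch
#'
#' Predictor-corrector continuation of `fun(x, q) = 0` with a secant
#' predictor and a Newton corrector on the bordered system, traversing folds
#' without stopping. Steps adapt between `h_min` and `h_max` in scaled
#' arclength; each accepted point is re-converged to the residual tolerance
#' and its stability evaluated from the leading Jacobian eigenvalue.
#'
#' @param fun Vector field `function(x, q)`.
#' @param x0 Converged equilibrium state at `q0`.
#' @param q0 Starting parameter value.
#' @param q_range Length-2 numeric; continuation stops when `q` leaves it.
#' @param direction +1 or -1, initial direction of the parameter.
#' @param h0,h_min,h_max Initial, minimal and maximal arclength steps.
#' @param max_steps Maximum number of accepted points.
#' @param tol Equilibrium residual tolerance.
#' @param x_cap Stop if any state coordinate exceeds this bound.
#' @return Tibble with `step`, `q`, `s` (arclength), `readout` (first state
#'   coordinate of interest is left to the caller via the `state` column),
#'   `stable`, `max_re` and list-column `state`. Attribute `truncated`
#'   reports step-size underflow.
#' @export
continue_branch <- function(fun, x0, q0, q_range, direction = 1,
                            h0 = 0.01, h_min = 1e-4, h_max = 0.1,
                            max_steps = 2000, tol = 1e-10, x_cap = 100) {
  n <- length(x0)
  start <- .newton_eq(fun, x0, q0, tol = tol)
  if (!start$converged) stop("continuation start is not an equilibrium",
                             call. = FALSE)
  x <- start$state; q <- q0
  ## initial tangent from the bordered Jacobian null space
  J <- cbind(.jac_x(fun, x, q), .jac_q(fun, x, q))
  tang <- c(qr.Q(qr(t(J)), complete = TRUE)[, n + 1])
  tang <- tang / sqrt(sum(tang^2))
  if (sign(tang[n + 1]) != sign(direction)) tang <- -tang
  st <- .stability(fun, x, q)
  pts_x <- list(x); pts_q <- q; pts_s <- 0
  pts_stab <- st$stable; pts_re <- st$max_re
  h <- h0; s <- 0; truncated <- FALSE
  for (step in seq_len(max_steps)) {
    repeat {
      u_pred <- c(x, q) + h * tang
      ## Newton on the bordered system
      u <- u_pred; ok <- FALSE
      for (it in 1:12) {
        xx <- u[1:n]; qq <- u[n + 1]
        f <- fun(xx, qq)
        g <- c(f, sum(tang * (u - c(x, q))) - h)
        if (all(is.finite(g)) && sqrt(sum(g^2)) < tol * 10) { ok <- TRUE; break }
        if (!all(is.finite(g))) break
        Jb <- rbind(cbind(.jac_x(fun, xx, qq), .jac_q(fun, xx, qq)), tang)
        du <- tryCatch(solve(Jb, -g), error = function(e) NULL)
        if (is.null(du)) break
        u <- u + du
      }
      if (ok) break
      h <- h / 2
      if (h < h_min) { truncated <- TRUE; break }
    }
    if (truncated) break
    x_new <- u[1:n]; q_new <- u[n + 1]
    if (max(abs(x_new)) > x_cap) break
    ds <- sqrt(sum((c(x_new, q_new) - c(x, q))^2))
    tang <- (c(x_new, q_new) - c(x, q)) / ds
    s <- s + ds
    x <- x_new; q <- q_new
    st <- .stability(fun, x, q)
    pts_x[[length(pts_x) + 1]] <- x
    pts_q <- c(pts_q, q); pts_s <- c(pts_s, s)
    pts_stab <- c(pts_stab, st$stable); pts_re <- c(pts_re, st$max_re)
    if (it <= 4) h <- min(h * 1.4, h_max)
    if (q < min(q_range) || q > max(q_range)) break
  }
  out <- tibble::tibble(
    step = seq_along(pts_q) - 1L, q = pts_q, s = pts_s,
    stable = pts_stab, max_re = pts_re, state = pts_x
  )
  attr(out, "truncated") <- truncated
  out
}

#' Detect and refine fold (saddle-node) points along a branch
#'
#' Folds are located where the parameter derivative along arclength changes
#' sign, then refined by Newton iteration on the extended fold system
#' `{f(x, q) = 0, J(x, q) v = 0, |v| = 1}`; each refined fold is
#' cross-checked by the near-zero leading real eigenvalue.
#'
#' @param branch Tibble from [continue_branch()].
#' @param fun The vector field used to produce the branch.
#' @param tol Newton tolerance on the extended system.
#' @return Tibble with one row per fold: `q`, `readout_index`-free
#'   list-column `state`, `null_vector`, `eig_min_abs_re` and `converged`.
#' @export
detect_folds <- function(branch, fun, tol = 1e-10) {
  if (nrow(branch) < 3) {
    return(tibble::tibble(q = numeric(0), state = list(),
                          eig_min_abs_re = numeric(0),
                          converged = logical(0)))
  }
  dq <- diff(branch$q)
  flips <- which(dq[-1] * dq[-length(dq)] < 0) + 1
  rows <- lapply(flips, function(i) {
    x_seed <- branch$state[[i]]; q_seed <- branch$q[i]
    out <- .fold_newton(fun, x_seed, q_seed, tol = tol)
    ## trust check: the refined fold must stay near its seed; retry with a
    ## tight step cap if Newton wandered to a different fold
    far <- function(o) {
      !o$converged || abs(o$q - q_seed) > 0.05 ||
        sqrt(sum((o$state - x_seed)^2)) > 0.3
    }
    if (far(out)) {
      out2 <- .fold_newton(fun, x_seed, q_seed, tol = tol, max_step = 0.02)
      if (!far(out2)) out <- out2
    }
    ev <- eigen(.jac_x(fun, out$state, out$q), only.values = TRUE)$values
    tibble::tibble(q = out$q, state = list(out$state),
                   eig_min_abs_re = min(abs(Re(ev))),
                   converged = out$converged)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(q = numeric(0), state = list(),
                          eig_min_abs_re = numeric(0), converged = logical(0))
  }
  out
}

#' One-parameter bifurcation diagram of the full model versus progesterone
#'
#' Continues the equilibrium branches emanating from the G2 state (upward in
#' progesterone) and from the metaphase-II state (downward, into formally
#' negative progesterone), detects the saddle-node points on each, and
#' extracts the maturation thresholds: `P_I`, the fold terminating the
#' stable G2 branch, and `P_IV`, the fold terminating the stable high-MPF
#' branch.
#'
#' @param params Named numeric parameter vector.
#' @param pg_range Progesterone continuation window (formal parameter;
#'   negative values allowed).
#' @param ... Passed to [continue_branch()].
#' @return Object of class `meio_bifurcation`: list with `points` (tibble of
#'   branch points: `branch`, `q`, `s`, `mpf_a`, `stable`, `max_re`),
#'   `folds` (tibble with `branch`, `q`, `mpf_a`), `P_I`, `P_IV`.
#' @export
bifurcation_diagram <- function(params, pg_range = c(-1.5, 2), ...) {
  validate_parameters(params)
  fun <- .model_field(params)
  g2 <- unname(g2_state(params)[.state_names])
  mii <- unname(mii_state(params)[.state_names])
  br_g2 <- continue_branch(fun, g2, 0, pg_range, direction = 1, ...)
  br_mii <- continue_branch(fun, mii, 0, pg_range, direction = -1, ...)
  add_readout <- function(br, label) {
    br$mpf_a <- vapply(br$state, function(x) x[4], numeric(1))
    br$branch <- label
    br
  }
  br_g2 <- add_readout(br_g2, "g2")
  br_mii <- add_readout(br_mii, "mii")
  f_g2 <- detect_folds(br_g2, fun)
  f_mii <- detect_folds(br_mii, fun)
  fold_tab <- function(f, label) {
    if (nrow(f) == 0) {
      return(tibble::tibble(branch = character(0), q = numeric(0),
                            mpf_a = numeric(0), state = list(),
                            eig_min_abs_re = numeric(0)))
    }
    tibble::tibble(branch = label, q = f$q,
                   mpf_a = vapply(f$state, function(x) x[4], numeric(1)),
                   state = f$state, eig_min_abs_re = f$eig_min_abs_re)
  }
  folds <- dplyr::bind_rows(fold_tab(f_g2, "g2"), fold_tab(f_mii, "mii"))
  ## both runs can trace the same connected curve from opposite ends; merge
  ## folds that coincide in (parameter, state)
  if (nrow(folds) > 1) {
    keep <- rep(TRUE, nrow(folds))
    for (i in 2:nrow(folds)) {
      for (j in seq_len(i - 1)) {
        if (keep[j] && abs(folds$q[i] - folds$q[j]) < 1e-5 &&
            max(abs(folds$state[[i]] - folds$state[[j]])) < 1e-4) {
          keep[i] <- FALSE
          break
        }
      }
    }
    folds <- folds[keep, ]
  }
  ## thresholds: the fold terminating the stable segment each run starts on
  ## (the run begins on the stable G2 / MII branch at zero progesterone)
  terminal_fold <- function(br) {
    if (!br$stable[1]) return(NULL)
    i_end <- which(!br$stable)[1]
    if (is.na(i_end)) return(NULL)
    seed_x <- br$state[[i_end - 1]]; seed_q <- br$q[i_end - 1]
    d <- vapply(seq_len(nrow(folds)), function(k) {
      sqrt(sum((folds$state[[k]] - seed_x)^2)) + abs(folds$q[k] - seed_q)
    }, numeric(1))
    if (length(d) == 0) return(NULL)
    folds[which.min(d), ]
  }
  f_i <- terminal_fold(br_g2)
  f_iv <- terminal_fold(br_mii)
  structure(list(
    points = dplyr::bind_rows(br_g2[, c("branch", "step", "q", "s", "mpf_a",
                                        "stable", "max_re", "state")],
                              br_mii[, c("branch", "step", "q", "s", "mpf_a",
                                         "stable", "max_re", "state")]),
    folds = folds,
    P_I = if (is.null(f_i)) NA_real_ else f_i$q,
    P_IV = if (is.null(f_iv)) NA_real_ else f_iv$q,
    fold_I_state = if (is.null(f_i)) NULL else f_i$state[[1]],
    fold_IV_state = if (is.null(f_iv)) NULL else f_iv$state[[1]],
    params = params
  ), class = "meio_bifurcation")
}

#' Progesterone thresholds of the maturation switch
#'
#' @param diagram A `meio_bifurcation` from [bifurcation_diagram()].
#' @return Named numeric vector `c(P_I, P_IV)`; `NA` with a message if a
#'   bounding fold is missing.
#' @export
progesterone_thresholds <- function(diagram) {
  stopifnot(inherits(diagram, "meio_bifurcation"))
  out <- c(P_I = diagram$P_I, P_IV = diagram$P_IV)
  if (anyNA(out)) message("missing fold: ",
                          paste(names(out)[is.na(out)], collapse = ", "))
  out
}

#' @export
print.meio_bifurcation <- function(x, ...) {
  cat("Bifurcation diagram vs progesterone\n")
  cat("  branch points:", nrow(x$points), "\n")
  cat("  folds:", nrow(x$folds), "at q =",
      paste(signif(x$folds$q, 4), collapse = ", "), "\n")
  cat("  P_I =", signif(x$P_I, 6), " P_IV =", signif(x$P_IV, 6), "\n")
  invisible(x)
}

#' @export
tidy.meio_bifurcation <- function(x, ...) {
  dplyr::select(x$points, "branch", "q", "s", "mpf_a", "stable", "max_re")
}

#' @export
glance.meio_bifurcation <- function(x, ...) {
  tibble::tibble(n_folds = nrow(x$folds), P_I = x$P_I, P_IV = x$P_IV)
}

#' Maturation threshold amplitude by simulation bisection
#'
#' Bisects the step amplitude between maturation failure and success, where
#' success is a sustained departure from the G2 state. Used to verify that
#' the dynamic threshold matches the continuation threshold `P_I`.
#'
#' @param params Named numeric parameter vector.
#' @param lo,hi Bracketing amplitudes.
#' @param horizon Simulation horizon per probe.
#' @param tol Amplitude tolerance of the bisection.
#' @return The threshold amplitude.
#' @export
maturation_threshold <- function(params, lo = 0, hi = 1, horizon = 300,
                                 tol = 1e-4) {
  g2 <- g2_state(params)
  matures <- function(a) {
    traj <- simulate_maturation(params, input_step(a), horizon = horizon,
                                init = g2, n_grid = 301,
                                rtol = 1e-8, atol = 1e-10)
    max(traj$mpf_a) > 10 * max(g2[["mpf_a"]], 0.02)
  }
  if (matures(lo)) stop("lower bracket already matures", call. = FALSE)
  if (!matures(hi)) stop("upper bracket does not mature", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (matures(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
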