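#' Right-hand side of the maturation network ODE system
#'
#' Evaluates the 13 class-I differential equations at time `t`. Class-II
#' activities are first computed by the quasi-steady-state approximation,
#' then the regulator-dependent reaction rates are assembled and the
#' derivatives formed: synthesis enters the inactive (or unphosphorylated)
#' form, degradation removes both forms, and activation/inactivation are
#' conservative Michaelis-Menten exchanges between forms. The function is
#' deterministic and side-effect-free.
#'
#' @param t Time.
#' @param state Named numeric state vector (see [state_names()]).
#' @param params Named numeric parameter vector.
#' @param input_profile Function of time returning the progesterone level, or
#'   a single number for a constant signal.
#' @return List whose first element is the derivative vector, as required by
#'   [deSolve::lsoda()]; class-II activities are returned as auxiliary
#'   values.
#' @export
meiotic_rhs <- function(t, state, params, input_profile) {
  if (anyNA(state) || any(!is.finite(state))) {
    stop("non-finite state passed to meiotic_rhs", call. = FALSE)
  }
  pg <- if (is.function(input_profile)) input_profile(t) else input_profile
  c2 <- class2_activities(state, params, pg)
  r <- assemble_rates(state, c2, params, pg)
  p <- params
  s <- state

  mm <- michaelis_flux

  ## Mos; newly translated Mos is active, ERK/MPF phosphorylation returns
  ## the dephosphorylated pool to the active form
  act_mos <- mm(r[["va_mos"]], s[["mos_i"]], p[["km_act_mos"]])
  ina_mos <- mm(r[["vi_mos"]], s[["mos_a"]], p[["km_inact_mos"]])
  d_mos_i <- -act_mos + ina_mos - r[["kd_mos"]] * s[["mos_i"]]
  d_mos_a <- r[["ks_mos"]] + act_mos - ina_mos - r[["kd_mos"]] * s[["mos_a"]]

  ## MPF (cyclin B-Cdk1); newly synthesized cyclin binds Cdk1 in the active
  ## state and is driven into the pre-MPF store by Myt1; APC-dependent
  ## degradation hits both forms
  act_mpf <- mm(r[["va_mpf"]], s[["mpf_i"]], p[["km_act_mpf"]])
  ina_mpf <- mm(r[["vi_mpf"]], s[["mpf_a"]], p[["km_inact_mpf"]])
  d_mpf_i <- -act_mpf + ina_mpf - r[["kd_mpf"]] * s[["mpf_i"]]
  d_mpf_a <- r[["ks_mpf"]] + act_mpf - ina_mpf - r[["kd_mpf"]] * s[["mpf_a"]]

  ## APC
  act_apc <- mm(r[["va_apc"]], s[["apc_i"]], p[["km_act_apc"]])
  ina_apc <- mm(r[["vi_apc"]], s[["apc_a"]], p[["km_inact_apc"]])
  d_apc_i <- r[["ks_apc"]] - act_apc + ina_apc - r[["kd_apc"]] * s[["apc_i"]]
  d_apc_a <- act_apc - ina_apc - r[["kd_apc"]] * s[["apc_a"]]

  ## CPEB1
  act_c1 <- mm(r[["va_c1"]], s[["c1_i"]], p[["km_act_c1"]])
  ina_c1 <- mm(r[["vi_c1"]], s[["c1_a"]], p[["km_inact_c1"]])
  d_c1_i <- r[["ks_c1"]] - act_c1 + ina_c1 - r[["kd_c1"]] * s[["c1_i"]]
  d_c1_a <- act_c1 - ina_c1 - r[["kd_c1"]] * s[["c1_a"]]

  ## CPEB4
  act_c4 <- mm(r[["va_c4"]], s[["c4_i"]], p[["km_act_c4"]])
  ina_c4 <- mm(r[["vi_c4"]], s[["c4_a"]], p[["km_inact_c4"]])
  d_c4_i <- r[["ks_c4"]] - act_c4 + ina_c4 - r[["kd_c4"]] * s[["c4_i"]]
  d_c4_a <- act_c4 - ina_c4 - r[["kd_c4"]] * s[["c4_a"]]

  ## Emi2: u (unphosphorylated, partially active), a (Rsk-phosphorylated,
  ## fully active), p (MPF-phosphorylated, inactive, destabilized). Rsk
  ## phosphorylates both u and p to a with the same rate; dephosphorylation
  ## returns a and p to u; Rsk phosphorylation protects a from MPF.
  u_to_a <- mm(r[["va_emi"]], s[["emi_u"]], p[["km_act_emi"]])
  p_to_a <- mm(r[["va_emi"]], s[["emi_p"]], p[["km_act_emi"]])
  u_to_p <- mm(r[["vi_emi"]], s[["emi_u"]], p[["km_inact_emi"]])
  a_to_u <- r[["vdp_emi"]] * s[["emi_a"]]
  p_to_u <- r[["vdp_emi"]] * s[["emi_p"]]
  d_emi_u <- r[["ks_emi"]] - u_to_a - u_to_p + a_to_u + p_to_u -
    r[["kd_emi"]] * s[["emi_u"]]
  d_emi_a <- u_to_a + p_to_a - a_to_u - r[["kd_emi"]] * s[["emi_a"]]
  d_emi_p <- u_to_p - p_to_a - p_to_u - r[["kd_emi_p"]] * s[["emi_p"]]

  deriv <- c(d_mos_i, d_mos_a, d_mpf_i, d_mpf_a, d_apc_i, d_apc_a,
             d_c1_i, d_c1_a, d_c4_i, d_c4_a, d_emi_u, d_emi_a, d_emi_p)
  names(deriv) <- .state_names
  list(deriv, c2)
}

#' Declarative reaction table of the maturation network
#'
#' A second, independent transcription of the model as a table of reactions.
#' Each row carries a stoichiometry over the 13 state variables and a rate
#' function of `(state, class2, params, progesterone)`. Summing
#' `stoichiometry * rate` over rows reproduces the right-hand side; the test
#' suite checks agreement with [meiotic_rhs()] on random states, guarding
#' both transcriptions against typos.
#'
#' @return A tibble with columns `reaction`, `stoich` (list of named numeric
#'   vectors) and `rate` (list of functions).
#' @export
reaction_table <- function() {
  sn <- .state_names
  sto <- function(...) {
    v <- c(...)
    out <- stats::setNames(numeric(length(sn)), sn)
    out[names(v)] <- v
    out
  }
  mm <- michaelis_flux
  rows <- list(
    list("mos_synthesis", sto(mos_a = 1),
         function(s, c2, p, pg) p[["ks_mos_c1"]] * s[["c1_a"]]),
    list("mos_degradation_i", sto(mos_i = -1),
         function(s, c2, p, pg) p[["kd_mos_0"]] * s[["mos_i"]]),
    list("mos_degradation_a", sto(mos_a = -1),
         function(s, c2, p, pg) p[["kd_mos_0"]] * s[["mos_a"]]),
    list("mos_activation", sto(mos_i = -1, mos_a = 1),
         function(s, c2, p, pg) {
           mm(p[["ka_mos_erk"]] * c2[["erk"]] +
                p[["ka_mos_mpf"]] * s[["mpf_a"]],
              s[["mos_i"]], p[["km_act_mos"]])
         }),
    list("mos_inactivation", sto(mos_a = -1, mos_i = 1),
         function(s, c2, p, pg) {
           mm(p[["ki_mos_0"]], s[["mos_a"]], p[["km_inact_mos"]])
         }),

    list("mpf_synthesis", sto(mpf_a = 1),
         function(s, c2, p, pg) {
           p[["ks_mpf_0"]] + p[["ks_mpf_c1"]] * s[["c1_a"]] +
             p[["ks_mpf_c4"]] * s[["c4_a"]]
         }),
    list("mpf_degradation_i", sto(mpf_i = -1),
         function(s, c2, p, pg) {
           (p[["kd_mpf_0"]] + p[["kd_mpf_apc"]] * s[["apc_a"]]) * s[["mpf_i"]]
         }),
    list("mpf_degradation_a", sto(mpf_a = -1),
         function(s, c2, p, pg) {
           (p[["kd_mpf_0"]] + p[["kd_mpf_apc"]] * s[["apc_a"]]) * s[["mpf_a"]]
         }),
    list("mpf_activation", sto(mpf_i = -1, mpf_a = 1),
         function(s, c2, p, pg) {
           mm(p[["ka_mpf_0"]] + p[["ka_mpf_c25"]] * c2[["c25"]],
              s[["mpf_i"]], p[["km_act_mpf"]])
         }),
    list("mpf_inactivation", sto(mpf_a = -1, mpf_i = 1),
         function(s, c2, p, pg) {
           mm(p[["ki_mpf_0"]] + p[["ki_mpf_myt"]] * c2[["myt"]],
              s[["mpf_a"]], p[["km_inact_mpf"]])
         }),

    list("apc_synthesis", sto(apc_i = 1),
         function(s, c2, p, pg) p[["ks_apc_0"]]),
    list("apc_degradation_i", sto(apc_i = -1),
         function(s, c2, p, pg) p[["kd_apc_0"]] * s[["apc_i"]]),
    list("apc_degradation_a", sto(apc_a = -1),
         function(s, c2, p, pg) p[["kd_apc_0"]] * s[["apc_a"]]),
    list("apc_activation", sto(apc_i = -1, apc_a = 1),
         function(s, c2, p, pg) {
           mm(p[["ka_apc_mpf"]] * s[["mpf_a"]], s[["apc_i"]],
              p[["km_act_apc"]])
         }),
    list("apc_inactivation", sto(apc_a = -1, apc_i = 1),
         function(s, c2, p, pg) {
           mm(p[["ki_apc_0"]] + p[["ki_apc_e0"]] * s[["emi_u"]] +
                p[["ki_apc_ea"]] * s[["emi_a"]],
              s[["apc_a"]], p[["km_inact_apc"]])
         }),

    list("c1_synthesis", sto(c1_i = 1),
         function(s, c2, p, pg) p[["ks_c1_0"]]),
    list("c1_degradation_i", sto(c1_i = -1),
         function(s, c2, p, pg) {
           (p[["kd_c1_0"]] +
              p[["kd_c1_mpfapc"]] * s[["mpf_a"]] * s[["apc_a"]]) * s[["c1_i"]]
         }),
    list("c1_degradation_a", sto(c1_a = -1),
         function(s, c2, p, pg) {
           (p[["kd_c1_0"]] +
              p[["kd_c1_mpfapc"]] * s[["mpf_a"]] * s[["apc_a"]]) * s[["c1_a"]]
         }),
    list("c1_activation", sto(c1_i = -1, c1_a = 1),
         function(s, c2, p, pg) {
           mm(p[["ka_c1_pg"]] * pg + p[["ka_c1_mpf"]] * s[["mpf_a"]],
              s[["c1_i"]], p[["km_act_c1"]])
         }),
    list("c1_inactivation", sto(c1_a = -1, c1_i = 1),
         function(s, c2, p, pg) {
           mm(p[["ki_c1_0"]], s[["c1_a"]], p[["km_inact_c1"]])
         }),

    list("c4_synthesis", sto(c4_i = 1),
         function(s, c2, p, pg) p[["ks_c4_c1"]] * s[["c1_a"]]),
    list("c4_degradation_i", sto(c4_i = -1),
         function(s, c2, p, pg) p[["kd_c4_0"]] * s[["c4_i"]]),
    list("c4_degradation_a", sto(c4_a = -1),
         function(s, c2, p, pg) p[["kd_c4_0"]] * s[["c4_a"]]),
    list("c4_activation", sto(c4_i = -1, c4_a = 1),
         function(s, c2, p, pg) {
           mm(p[["ka_c4_mpf"]] * s[["mpf_a"]], s[["c4_i"]], p[["km_act_c4"]])
         }),
    list("c4_inactivation", sto(c4_a = -1, c4_i = 1),
         function(s, c2, p, pg) {
           mm(p[["ki_c4_0"]], s[["c4_a"]], p[["km_inact_c4"]])
         }),

    list("emi_synthesis", sto(emi_u = 1),
         function(s, c2, p, pg) {
           p[["ks_emi_0"]] + p[["ks_emi_c4"]] * s[["c4_a"]]
         }),
    list("emi_degradation_u", sto(emi_u = -1),
         function(s, c2, p, pg) p[["kd_emi_0"]] * s[["emi_u"]]),
    list("emi_degradation_a", sto(emi_a = -1),
         function(s, c2, p, pg) p[["kd_emi_0"]] * s[["emi_a"]]),
    list("emi_degradation_p", sto(emi_p = -1),
         function(s, c2, p, pg) {
           (p[["kd_emi_0"]] + p[["kd_emi_x"]]) * s[["emi_p"]]
         }),
    list("emi_u_to_a_rsk", sto(emi_u = -1, emi_a = 1),
         function(s, c2, p, pg) {
           mm(p[["ka_emi_rsk"]] * c2[["rsk"]], s[["emi_u"]], p[["km_act_emi"]])
         }),
    list("emi_p_to_a_rsk", sto(emi_p = -1, emi_a = 1),
         function(s, c2, p, pg) {
           mm(p[["ka_emi_rsk"]] * c2[["rsk"]], s[["emi_p"]], p[["km_act_emi"]])
         }),
    list("emi_u_to_p_mpf", sto(emi_u = -1, emi_p = 1),
         function(s, c2, p, pg) {
           mm(p[["ki_emi_mpf"]] * s[["mpf_a"]], s[["emi_u"]],
              p[["km_inact_emi"]])
         }),
    list("emi_a_dephos", sto(emi_a = -1, emi_u = 1),
         function(s, c2, p, pg) p[["kdp_emi"]] * s[["emi_a"]]),
    list("emi_p_dephos", sto(emi_p = -1, emi_u = 1),
         function(s, c2, p, pg) p[["kdp_emi"]] * s[["emi_p"]])
  )
  tibble::tibble(
    reaction = vapply(rows, `[[`, character(1), 1),
    stoich = lapply(rows, `[[`, 2),
    rate = lapply(rows, `[[`, 3)
  )
}

#' Right-hand side evaluated from the declarative reaction table
#'
#' Independent evaluation path used to cross-check [meiotic_rhs()].
#'
#' @inheritParams meiotic_rhs
#' @param table Reaction table from [reaction_table()].
#' @return Named derivative vector of length 13.
#' @export
rhs_from_reactions <- function(t, state, params, input_profile,
                               table = reaction_table()) {
  pg <- if (is.function(input_profile)) input_profile(t) else input_profile
  c2 <- class2_activities(state, params, pg)
  deriv <- stats::setNames(numeric(length(.state_names)), .state_names)
  for (i in seq_len(nrow(table))) {
    v <- table$rate[[i]](state, c2, params, pg)
    deriv <- deriv + table$stoich[[i]] * v
  }
  deriv
}

#' Default resting (pre-stimulation) state
#'
#' A nominal prophase-I-like state used to seed the search for the G2
#' equilibrium: the cyclin store in its inactive (pre-MPF) form, CPEB1
#' present but inactive, APC present but inactive, everything else at zero.
#'
#' @param params Named numeric parameter vector.
#' @return Named numeric state vector.
#' @export
resting_state <- function(params = default_parameters()) {
  s <- stats::setNames(numeric(13), .state_names)
  s[["mpf_i"]] <- params[["ks_mpf_0"]] / max(params[["kd_mpf_0"]], 1e-8)
  s[["apc_i"]] <- params[["ks_apc_0"]] / max(params[["kd_apc_0"]], 1e-8)
  s[["c1_i"]] <- params[["ks_c1_0"]] / max(params[["kd_c1_0"]], 1e-8)
  s
}
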