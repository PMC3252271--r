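#' Michaelis-Menten flux
#'
#' Saturating rate law `vmax * s / (km + s)` used for all class-I
#' activation/inactivation reactions of the network.
#'
#' @param vmax Maximal rate (non-negative).
#' @param substrate Substrate concentration (non-negative).
#' @param km Michaelis constant (strictly positive).
#' @return The flux, bounded by `vmax`.
#' @export
#' @examples
#' michaelis_flux(2, 3, 1)  # 1.5
michaelis_flux <- function(vmax, substrate, km) {
  if (any(km <= 0)) stop("Michaelis constant must be positive", call. = FALSE)
  vmax * substrate / (km + substrate)
}

#' Quasi-steady-state active fraction, one-step phosphorylation
#'
#' Steady-state active fraction of a two-form species of unit total with
#' linear interconversion at rates `v_act` (forward) and `v_inact`
#' (backward): `v_act / (v_act + v_inact)`. Used for Cdc25, Myt1 and Plx1.
#'
#' @param v_act,v_inact Activation and inactivation rates (non-negative, not
#'   both zero).
#' @return Active fraction in `[0, 1]`.
#' @export
#' @examples
#' class2_activity_one_step(1, 1)  # 0.5
class2_activity_one_step <- function(v_act, v_inact) {
  denom <- v_act + v_inact
  if (any(denom == 0)) {
    stop("degenerate kinetics: activation and inactivation rates both zero",
         call. = FALSE)
  }
  v_act / denom
}

#' Quasi-steady-state active fraction, two-step phosphorylation
#'
#' Steady-state doubly-phosphorylated fraction of a species with two
#' phosphorylation sites processed distributively, each site driven at
#' `v_act` and reverted at `v_inact`: the squared one-step fraction
#' `(v_act / (v_act + v_inact))^2`. Equivalently, the top state of the
#' three-form chain with binomial site degeneracy (forward rates `2 v_act`,
#' `v_act`; backward rates `v_inact`, `2 v_inact`). Used for MEK, ERK and
#' Rsk; squaring sharpens the cascade's input-output response.
#'
#' @inheritParams class2_activity_one_step
#' @return Doubly-phosphorylated fraction in `[0, 1]`.
#' @export
#' @examples
#' class2_activity_two_step(1, 1)  # 0.25
class2_activity_two_step <- function(v_act, v_inact) {
  class2_activity_one_step(v_act, v_inact)^2
}

## species order of the 13-dimensional state vector
.state_names <- c(
  "mos_i", "mos_a",
  "mpf_i", "mpf_a",
  "apc_i", "apc_a",
  "c1_i", "c1_a",
  "c4_i", "c4_a",
  "emi_u", "emi_a", "emi_p"
)

#' State variable names of the class-I system
#'
#' Thirteen variables: inactive/active forms of Mos, MPF, APC, CPEB1 (`c1`)
#' and CPEB4 (`c4`), plus the three Emi2 phosphoforms -- `emi_u`
#' (unphosphorylated, partially active), `emi_a` (Rsk-phosphorylated, fully
#' active) and `emi_p` (MPF-phosphorylated, inactive and destabilized).
#'
#' @return Character vector of length 13.
#' @export
state_names <- function() .state_names

#' Class-II quasi-steady-state activities
#'
#' Evaluates the active fractions of the six class-II proteins (Plx1, Cdc25,
#' Myt1 by one-step; MEK, ERK, Rsk by two-step phosphorylation) given the
#' current class-I state and progesterone level. The absolute class-II rate
#' scale `lambda_class2` multiplies both the activation and inactivation
#' rates and therefore cancels in every activity.
#'
#' @param state Named numeric state vector (see [state_names()]).
#' @param params Named numeric parameter vector.
#' @param progesterone Progesterone signal level.
#' @return Named numeric vector `c(plx, c25, myt, mek, erk, rsk)`, each in
#'   `[0, 1]` for non-negative inputs.
#' @export
class2_activities <- function(state, params, progesterone) {
  p <- params
  lam <- p[["lambda_class2"]]
  mos_a <- state[["mos_a"]]; mpf_a <- state[["mpf_a"]]
  plx <- class2_activity_one_step(
    lam * (p[["ka_plx_0"]] + p[["ka_plx_pg"]] * progesterone +
             p[["ka_plx_mpf"]] * mpf_a),
    lam * p[["ki_plx_0"]]
  )
  c25 <- class2_activity_one_step(
    lam * (p[["ka_c25_mpf"]] * mpf_a + p[["ka_c25_plx"]] * plx),
    lam * p[["ki_c25_0"]]
  )
  myt <- class2_activity_one_step(
    lam * p[["ka_myt_0"]],
    lam * (p[["ki_myt_mpf"]] * mpf_a + p[["ki_myt_plx"]] * plx +
             p[["ki_myt_mos"]] * mos_a)
  )
  mek <- class2_activity_two_step(lam * p[["ka_mek_mos"]] * mos_a,
                                  lam * p[["ki_mek_0"]])
  erk <- class2_activity_two_step(lam * p[["ka_erk_mek"]] * mek,
                                  lam * p[["ki_erk_0"]])
  rsk <- class2_activity_two_step(lam * p[["ka_rsk_erk"]] * erk,
                                  lam * p[["ki_rsk_0"]])
  c(plx = unname(plx) * p[["total_plx"]],
    c25 = unname(c25) * p[["total_c25"]],
    myt = unname(myt) * p[["total_myt"]],
    mek = unname(mek) * p[["total_mek"]],
    erk = unname(erk) * p[["total_erk"]],
    rsk = unname(rsk) * p[["total_rsk"]])
}

#' Assemble the regulator-dependent kinetic reaction rates
#'
#' Returns every synthesis, degradation, activation and inactivation rate of
#' the class-I equations as a function of the current regulator
#' concentrations, class-II activities and progesterone level. These are the
#' `vmax`-type rates entering the Michaelis-Menten fluxes (activation /
#' inactivation) or multiplying concentrations linearly (synthesis,
#' degradation, Emi2 phosphoform transitions).
#'
#' @inheritParams class2_activities
#' @param class2 Named class-II activity vector from [class2_activities()].
#' @return Named numeric vector of reaction rates, all non-negative for
#'   non-negative inputs.
#' @export
assemble_rates <- function(state, class2, params, progesterone) {
  p <- params
  s <- state
  c2 <- class2
  c(
    ks_mos = p[["ks_mos_c1"]] * s[["c1_a"]],
    kd_mos = p[["kd_mos_0"]],
    va_mos = p[["ka_mos_erk"]] * c2[["erk"]] + p[["ka_mos_mpf"]] * s[["mpf_a"]],
    vi_mos = p[["ki_mos_0"]],

    ks_mpf = p[["ks_mpf_0"]] + p[["ks_mpf_c1"]] * s[["c1_a"]] +
      p[["ks_mpf_c4"]] * s[["c4_a"]],
    kd_mpf = p[["kd_mpf_0"]] + p[["kd_mpf_apc"]] * s[["apc_a"]],
    va_mpf = p[["ka_mpf_0"]] + p[["ka_mpf_c25"]] * c2[["c25"]],
    vi_mpf = p[["ki_mpf_0"]] + p[["ki_mpf_myt"]] * c2[["myt"]],

    ks_apc = p[["ks_apc_0"]],
    kd_apc = p[["kd_apc_0"]],
    va_apc = p[["ka_apc_mpf"]] * s[["mpf_a"]],
    vi_apc = p[["ki_apc_0"]] + p[["ki_apc_e0"]] * s[["emi_u"]] +
      p[["ki_apc_ea"]] * s[["emi_a"]],

    ks_c1 = p[["ks_c1_0"]],
    kd_c1 = p[["kd_c1_0"]] + p[["kd_c1_mpfapc"]] * s[["mpf_a"]] * s[["apc_a"]],
    va_c1 = p[["ka_c1_pg"]] * progesterone + p[["ka_c1_mpf"]] * s[["mpf_a"]],
    vi_c1 = p[["ki_c1_0"]],

    ks_c4 = p[["ks_c4_c1"]] * s[["c1_a"]],
    kd_c4 = p[["kd_c4_0"]],
    va_c4 = p[["ka_c4_mpf"]] * s[["mpf_a"]],
    vi_c4 = p[["ki_c4_0"]],

    ks_emi = p[["ks_emi_0"]] + p[["ks_emi_c4"]] * s[["c4_a"]],
    kd_emi = p[["kd_emi_0"]],
    kd_emi_p = p[["kd_emi_0"]] + p[["kd_emi_x"]],
    va_emi = p[["ka_emi_rsk"]] * c2[["rsk"]],
    vi_emi = p[["ki_emi_mpf"]] * s[["mpf_a"]],
    vdp_emi = p[["kdp_emi"]]
  )
}
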