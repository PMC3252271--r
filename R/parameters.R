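#' Reference kinetic parameters of the maturation network
#'
#' Returns the full kinetic parameter set of the meiotic maturation model as a
#' named numeric vector. Identifiers are systematic: `ks_<target>_<driver>`
#' (synthesis), `kd_<target>[_<driver>]` (degradation), `ka_*` / `ki_*`
#' (maximal activation / inactivation rates, with `_0` suffixes for
#' regulator-independent basal rates), `km_act_*` / `km_inact_*` (Michaelis
#' constants of class-I (in)activation), `total_*` (class-II total
#' concentrations) and `lambda_class2` (the free absolute scale of class-II
#' interconversion rates, which cancels in the quasi-steady-state activities).
#'
#' The set contains 73 parameters. Under the model's normalization conventions
#' -- class-II totals fixed at 1, all class-I Michaelis constants set to one
#' shared value, and the class-II rate scale arbitrary -- 54 of them are free.
#' The free parameters split into the 7-parameter MAPK cascade module, the
#' 15-parameter MPF-APC core module, and 32 remaining couplings; see
#' [parameter_table()] and [audit_parameters()].
#'
#' Concentrations are in arbitrary units normalized so that class-II totals
#' and the resting pre-MPF store are of order one; time is in hours.
#'
#' @return Named numeric vector of length 73.
#' @seealso [parameter_table()], [audit_parameters()], [load_parameters()]
#' @export
#' @examples
#' p <- default_parameters()
#' length(p)
default_parameters <- function() {
  c(
    ## --- MAPK cascade module (7 free) ---------------------------------
    ka_mek_mos  = 4,     # MEK activation by active Mos
    ki_mek_0    = 1,     # MEK dephosphorylation
    ka_erk_mek  = 4,     # ERK activation by active MEK
    ki_erk_0    = 1,
    ka_rsk_erk  = 4,     # Rsk activation by active ERK
    ki_rsk_0    = 1,
    ka_mos_erk  = 0.6,   # feedback phosphorylation of Mos by ERK

    ## --- MPF-APC core module (15 free) --------------------------------
    ks_mpf_0    = 0.08,  # basal cyclin B synthesis (pre-MPF store)
    kd_mpf_0    = 0.08,  # basal cyclin B turnover
    kd_mpf_apc  = 3,  # APC-dependent cyclin B degradation
    ka_mpf_0    = 0.02,  # Cdc25-independent basal MPF activation
    ka_mpf_c25  = 3,     # MPF activation by active Cdc25
    ki_mpf_0    = 0.10,  # Myt1-independent basal MPF inactivation
    ki_mpf_myt  = 4,     # MPF inactivation by active Myt1
    ka_c25_mpf  = 3,     # Cdc25 activation by MPF
    ki_c25_0    = 1,     # Cdc25 dephosphorylation
    ka_myt_0    = 1,     # Myt1 reactivation (dephosphorylation)
    ki_myt_mpf  = 3,     # Myt1 inactivation by MPF
    ks_apc_0    = 0.30,  # APC subunit synthesis
    kd_apc_0    = 0.30,  # APC turnover
    ka_apc_mpf  = 2,   # APC activation by MPF
    ki_apc_0    = 0.50,  # basal APC inactivation

    ## --- remaining couplings (32 free) --------------------------------
    ks_mos_c1   = 0.20,  # Mos translation driven by active CPEB1
    kd_mos_0    = 0.15,
    ka_mos_mpf  = 1.5,     # Mos phosphorylation/stabilisation by MPF
    ki_mos_0    = 0.30,

    ks_mpf_c1   = 0.08,  # cyclin B1/B5 translation wave (CPEB1)
    ks_mpf_c4   = 0.10,  # cyclin B2 translation wave (CPEB4)

    ki_apc_e0   = 4.5,     # APC inhibition by unphosphorylated Emi2
    ki_apc_ea   = 5,     # APC inhibition by Rsk-phosphorylated Emi2

    ks_c1_0     = 0.10,  # CPEB1 synthesis
    kd_c1_0     = 0.10,
    kd_c1_mpfapc = 2,    # CPEB1 degradation by joint MPF and APC action
    ka_c1_pg    = 1,     # CPEB1 activation by progesterone (Aurora A axis)
    ka_c1_mpf   = 0.75,  # CPEB1 activation by MPF
    ki_c1_0     = 0.30,

    ks_c4_c1    = 0.30,  # CPEB4 translation driven by CPEB1
    kd_c4_0     = 0.20,
    ka_c4_mpf   = 1.2,     # CPEB4 activation by MPF
    ki_c4_0     = 0.30,

    ks_emi_0    = 0,     # basal Emi2 synthesis (zero in reference)
    ks_emi_c4   = 0.30,  # Emi2 translation driven by CPEB4
    kd_emi_0    = 0.15,
    kd_emi_x    = 0.50,  # extra degradation of MPF-phosphorylated Emi2
    ka_emi_rsk  = 3,     # Emi2 activating phosphorylation by Rsk
    ki_emi_mpf  = 1.5,     # Emi2 inactivating phosphorylation by MPF
    kdp_emi     = 0.50,  # Emi2 dephosphorylation back to the ground form

    ka_plx_0    = 0.02,  # basal Plx1 activation
    ka_plx_pg   = 0.35,     # progesterone-dependent Plx1 activation
    ka_plx_mpf  = 2,     # Plx1 activation by MPF
    ki_plx_0    = 1,

    ka_c25_plx  = 1.3,     # Cdc25 activation by Plx1
    ki_myt_plx  = 1.0,     # Myt1 inactivation by Plx1
    ki_myt_mos  = 6,     # Myt1 inactivation by Mos

    ## --- fixed by normalization (19) ----------------------------------
    km_act_mos   = 0.1, km_inact_mos = 0.1,
    km_act_mpf   = 0.1, km_inact_mpf = 0.1,
    km_act_apc   = 0.1, km_inact_apc = 0.1,
    km_act_c1    = 0.1, km_inact_c1  = 0.1,
    km_act_c4    = 0.1, km_inact_c4  = 0.1,
    km_act_emi   = 0.1, km_inact_emi = 0.1,
    total_plx = 1, total_c25 = 1, total_myt = 1,
    total_mek = 1, total_erk = 1, total_rsk = 1,
    lambda_class2 = 1
  )
}

## module membership of the free parameters (internal bookkeeping)
.par_modules <- function() {
  list(
    mapk = c("ka_mek_mos", "ki_mek_0", "ka_erk_mek", "ki_erk_0",
             "ka_rsk_erk", "ki_rsk_0", "ka_mos_erk"),
    mpf_apc = c("ks_mpf_0", "kd_mpf_0", "kd_mpf_apc", "ka_mpf_0",
                "ka_mpf_c25", "ki_mpf_0", "ki_mpf_myt", "ka_c25_mpf",
                "ki_c25_0", "ka_myt_0", "ki_myt_mpf", "ks_apc_0",
                "kd_apc_0", "ka_apc_mpf", "ki_apc_0"),
    coupling = c("ks_mos_c1", "kd_mos_0", "ka_mos_mpf", "ki_mos_0",
                 "ks_mpf_c1", "ks_mpf_c4", "ki_apc_e0", "ki_apc_ea",
                 "ks_c1_0", "kd_c1_0", "kd_c1_mpfapc", "ka_c1_pg",
                 "ka_c1_mpf", "ki_c1_0", "ks_c4_c1", "kd_c4_0",
                 "ka_c4_mpf", "ki_c4_0", "ks_emi_0", "ks_emi_c4",
                 "kd_emi_0", "kd_emi_x", "ka_emi_rsk", "ki_emi_mpf",
                 "kdp_emi", "ka_plx_0", "ka_plx_pg", "ka_plx_mpf",
                 "ki_plx_0", "ka_c25_plx", "ki_myt_plx", "ki_myt_mos")
  )
}

## parameters associated with a link between two molecular actors
## (or between the progesterone input and an actor)
.interaction_params <- function() {
  c("ka_mek_mos", "ka_erk_mek", "ka_rsk_erk", "ka_mos_erk",
    "kd_mpf_apc", "ka_mpf_c25", "ki_mpf_myt", "ka_c25_mpf",
    "ki_myt_mpf", "ka_apc_mpf",
    "ks_mos_c1", "ka_mos_mpf", "ks_mpf_c1", "ks_mpf_c4",
    "ki_apc_e0", "ki_apc_ea", "kd_c1_mpfapc", "ka_c1_pg", "ka_c1_mpf",
    "ks_c4_c1", "ka_c4_mpf", "ks_emi_0", "ks_emi_c4", "ka_emi_rsk",
    "ki_emi_mpf", "ka_plx_pg", "ka_plx_mpf", "ka_c25_plx",
    "ki_myt_plx", "ki_myt_mos")
}

#' Parameter metadata table
#'
#' One row per kinetic parameter with its value, role, normalization status,
#' network-module membership used during calibration, and whether it
#' represents an interaction (a link between two molecular actors, or between
#' the progesterone input and an actor) -- the set screened by
#' [sensitivity_screen()].
#'
#' @param params Named numeric parameter vector (default
#'   [default_parameters()]).
#' @return A tibble with columns `id`, `value`, `status` (`"free"` or
#'   `"fixed"`), `module` (`"mapk"`, `"mpf_apc"`, `"coupling"`, or `"fixed"`)
#'   and `interaction` (logical).
#' @export
parameter_table <- function(params = default_parameters()) {
  mods <- .par_modules()
  ids <- names(params)
  module <- rep("fixed", length(ids))
  for (m in names(mods)) module[ids %in% mods[[m]]] <- m
  tibble::tibble(
    id = ids,
    value = unname(params),
    status = ifelse(module == "fixed", "fixed", "free"),
    module = module,
    interaction = ids %in% .interaction_params()
  )
}

#' Audit the parameter set against the model's structural counts
#'
#' Checks that the parameter set has the expected structure: 73 parameters in
#' total, 54 free after the normalization conventions (class-II totals fixed
#' at 1, one shared Michaelis constant for class-I (in)activation, arbitrary
#' class-II rate scale), split 7 / 15 / 32 between the MAPK module, the
#' MPF-APC module and the remaining couplings.
#'
#' @inheritParams parameter_table
#' @return A tibble with columns `check`, `expected`, `observed`, `pass`.
#' @export
#' @examples
#' audit_parameters()
audit_parameters <- function(params = default_parameters()) {
  tab <- parameter_table(params)
  km <- tab$value[startsWith(tab$id, "km_")]
  tot <- tab$value[startsWith(tab$id, "total_")]
  checks <- tibble::tribble(
    ~check, ~expected, ~observed,
    "n_parameters_raw", 73, nrow(tab),
    "n_parameters_free", 54, sum(tab$status == "free"),
    "n_mapk_module", 7, sum(tab$module == "mapk"),
    "n_mpf_apc_module", 15, sum(tab$module == "mpf_apc"),
    "n_remaining_couplings", 32, sum(tab$module == "coupling"),
    "n_shared_michaelis", 12, length(km),
    "michaelis_shared_value", 1, as.numeric(length(unique(km)) == 1),
    "class2_totals_unit", 1, as.numeric(all(tot == 1))
  )
  dplyr::mutate(checks, pass = .data$expected == .data$observed)
}

#' Validate a kinetic parameter vector
#'
#' @param params Named numeric vector.
#' @param reference Reference vector whose names define the schema.
#' @return `params`, invisibly, after validation.
#' @keywords internal
validate_parameters <- function(params, reference = default_parameters()) {
  if (is.null(names(params)) || any(names(params) == "")) {
    stop("parameters must be a fully named numeric vector", call. = FALSE)
  }
  missing <- setdiff(names(reference), names(params))
  if (length(missing) > 0) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(names(params), names(reference))
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(params) || any(!is.finite(params))) {
    stop("parameters must be finite", call. = FALSE)
  }
  if (any(params < 0)) {
    bad <- names(params)[params < 0]
    stop("negative parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(params)
}

#' Apply an intervention to a parameter set
#'
#' Interventions model knockout, pharmacological-inhibition and
#' overexpression protocols: each element sets a parameter to zero, scales it
#' by a factor, or sets it to an explicit value. Untouched parameters are
#' returned bit-identical.
#'
#' @param params Named numeric parameter vector.
#' @param spec A data frame (or tibble) with columns `id`, `action` (one of
#'   `"zero"`, `"scale"`, `"set"`) and `value` (scale factor or target value;
#'   ignored for `"zero"`). May have zero rows.
#' @return The modified parameter vector.
#' @export
#' @examples
#' p <- apply_intervention(default_parameters(),
#'   intervention(c("ks_mpf_0", "ks_mpf_c1", "ks_mpf_c4"), "zero"))
#' p[["ks_mpf_0"]]
apply_intervention <- function(params, spec) {
  validate_parameters(params)
  stopifnot(is.data.frame(spec))
  if (nrow(spec) == 0) return(params)
  if (!all(c("id", "action") %in% names(spec))) {
    stop("intervention spec needs columns 'id' and 'action'", call. = FALSE)
  }
  unknown <- setdiff(spec$id, names(params))
  if (length(unknown) > 0) {
    stop("intervention references unknown parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- params
  for (i in seq_len(nrow(spec))) {
    id <- spec$id[i]
    val <- if ("value" %in% names(spec)) spec$value[i] else NA_real_
    out[[id]] <- switch(spec$action[i],
      zero = 0,
      scale = {
        if (is.na(val)) stop("scale action needs a value", call. = FALSE)
        out[[id]] * val
      },
      set = {
        if (is.na(val)) stop("set action needs a value", call. = FALSE)
        val
      },
      stop("unknown intervention action: ", spec$action[i], call. = FALSE)
    )
  }
  if (any(out < 0)) {
    stop("intervention produced negative parameter(s)", call. = FALSE)
  }
  out
}

#' Build an intervention specification
#'
#' @param id Character vector of parameter identifiers.
#' @param action Action applied to every `id`: `"zero"`, `"scale"` or
#'   `"set"`.
#' @param value Scale factor or target value (recycled).
#' @param label Optional protocol label.
#' @return A tibble usable with [apply_intervention()].
#' @export
intervention <- function(id, action = "zero", value = NA_real_, label = NULL) {
  out <- tibble::tibble(id = id, action = action, value = value)
  attr(out, "label") <- label
  out
}

#' Read kinetic parameters from a YAML file
#'
#' The file layout groups parameters in named sections (any grouping is
#' accepted; section names are documentation only). Every parameter of the
#' reference schema must be present exactly once, all values must be
#' non-negative and finite. The structural audit is run after loading and a
#' warning is raised if any count deviates from the model's 73-raw / 54-free
#' convention.
#'
#' @param path Path to a YAML parameter file.
#' @return Named numeric parameter vector.
#' @seealso [write_parameters()], [audit_parameters()]
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  sections <- raw[setdiff(names(raw), "provenance")]
  flat <- unlist(lapply(unname(sections), function(sec) {
    vapply(sec, function(x) {
      if (is.list(x)) as.numeric(x$value) else as.numeric(x)
    }, numeric(1))
  }))
  dup <- names(flat)[duplicated(names(flat))]
  if (length(dup) > 0) {
    stop("duplicated parameter(s) in file: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  params <- flat[names(default_parameters())]
  if (anyNA(params)) {
    missing <- names(default_parameters())[is.na(params)]
    stop("parameter file is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  names(params) <- names(default_parameters())
  extra <- setdiff(names(flat), names(params))
  if (length(extra) > 0) {
    stop("unknown parameter(s) in file: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  validate_parameters(params)
  audit <- audit_parameters(params)
  if (!all(audit$pass)) {
    warning("parameter audit failed for: ",
            paste(audit$check[!audit$pass], collapse = ", "), call. = FALSE)
  }
  params
}

#' Write kinetic parameters to a YAML file
#'
#' @param params Named numeric parameter vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  tab <- parameter_table(params)
  grp <- list(
    synthesis = tab$id[startsWith(tab$id, "ks_")],
    degradation = tab$id[startsWith(tab$id, "kd_") | tab$id == "kdp_emi"],
    activation = tab$id[startsWith(tab$id, "ka_")],
    inactivation = tab$id[startsWith(tab$id, "ki_")],
    michaelis = tab$id[startsWith(tab$id, "km_")],
    class2_totals = tab$id[startsWith(tab$id, "total_")],
    class2_scale = "lambda_class2"
  )
  out <- lapply(grp, function(ids) as.list(params[ids]))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Default path of the packaged reference parameter file
#' @return File path within the installed package.
#' @export
reference_parameter_file <- function() {
  system.file("extdata", "params_reference.yaml", package = "meiodyn",
              mustWork = TRUE)
}
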