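## ---- ggplot2 figure methods ---------------------------------------------

#' Plot a maturation trajectory
#'
#' Activities of the key readouts (MPF, ERK, APC, active Emi2) against
#' time, with the progesterone input as a dashed line.
#'
#' @param object A `meio_trajectory`.
#' @param species Columns to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meio_trajectory <- function(object,
                                     species = c("mpf_a", "erk", "apc_a",
                                                 "emi_a"),
                                     ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("time", species)],
    -"time", names_to = "species", values_to = "activity")
  input <- tibble::as_tibble(object)[, c("time", "pg")]
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$activity,
                                     colour = .data$species)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_line(data = input,
                       ggplot2::aes(.data$time, .data$pg),
                       inherit.aes = FALSE, linetype = "dashed",
                       colour = "grey40") +
    ggplot2::labs(x = "time (h)", y = "activity (a.u.)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a bifurcation diagram
#'
#' Steady-state MPF activity versus progesterone, solid for stable and
#' dotted for unstable equilibria, with saddle-node points circled.
#'
#' @param object A `meio_bifurcation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meio_bifurcation <- function(object, ...) {
  pts <- tidy(object)
  ggplot2::ggplot(pts, ggplot2::aes(.data$q, .data$mpf_a,
                                    group = interaction(.data$branch,
                                                        .data$stable),
                                    linetype = .data$stable)) +
    ggplot2::geom_path(colour = "black") +
    ggplot2::geom_point(data = object$folds,
                        ggplot2::aes(.data$q, .data$mpf_a),
                        inherit.aes = FALSE, shape = 1, size = 3) +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid",
                                              `FALSE` = "dotted"),
                                   labels = c(`TRUE` = "stable",
                                              `FALSE` = "unstable")) +
    ggplot2::labs(x = "progesterone (a.u.)", y = "MPF activity (a.u.)",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the isolated MAPK switch diagram
#'
#' @param object A `meio_mapk_switch`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meio_mapk_switch <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(.data$q, .data$erk,
                               linetype = .data$stable)) +
    ggplot2::geom_path(ggplot2::aes(group = 1), colour = "black") +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid",
                                              `FALSE` = "dotted")) +
    ggplot2::labs(x = "Mos-activating drive", y = "ERK activity",
                  linetype = "stable") +
    ggplot2::theme_minimal()
}

#' Plot normalized sensitivities of the interaction parameters
#'
#' Paired bars of the dynamic and bifurcation normalized sensitivities per
#' parameter; values near 0 mark G2/MI (resumption) control, near 1 MI/MII
#' (transition) control.
#'
#' @param object A `meio_sensitivity` from [sensitivity_screen()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meio_sensitivity <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("id", "s_dyn_norm", "s_bif_norm")],
    -"id", names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$id, .data$value,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "normalized sensitivity", fill = NULL) +
    ggplot2::theme_minimal()
}
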