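#' Progesterone input profiles
#'
#' Builds a piecewise-constant progesterone signal. A `step` holds
#' `amplitude` forever after `onset`; a `pulse` returns to zero after
#' `onset + duration`; `custom` wraps a user-supplied function of time.
#'
#' @param kind One of `"step"`, `"pulse"`, `"custom"`.
#' @param amplitude Signal amplitude (non-negative).
#' @param onset Onset time (default 0).
#' @param duration Pulse duration (required for `"pulse"`).
#' @param f Function of time, for `kind = "custom"`.
#' @return A function of time with class `meio_input` and attributes
#'   recording the profile definition.
#' @export
#' @examples
#' input_step(1)(10)
#' input_pulse(1, onset = 1, duration = 2)(4)
make_input_profile <- function(kind = c("step", "pulse", "custom"),
                               amplitude = 1, onset = 0, duration = NULL,
                               f = NULL) {
  kind <- match.arg(kind)
  if (kind != "custom" && amplitude < 0) {
    stop("amplitude must be non-negative", call. = FALSE)
  }
  g <- switch(kind,
    step = function(t) ifelse(t >= onset, amplitude, 0),
    pulse = {
      if (is.null(duration) || duration <= 0) {
        stop("pulse requires a positive duration", call. = FALSE)
      }
      function(t) ifelse(t >= onset & t < onset + duration, amplitude, 0)
    },
    custom = {
      if (!is.function(f)) stop("custom profile requires a function",
                                call. = FALSE)
      f
    }
  )
  structure(g, class = c("meio_input", "function"),
            kind = kind, amplitude = amplitude, onset = onset,
            duration = if (kind == "pulse") duration else NA_real_)
}

#' @rdname make_input_profile
#' @export
input_step <- function(amplitude, onset = 0) {
  make_input_profile("step", amplitude = amplitude, onset = onset)
}

#' @rdname make_input_profile
#' @export
input_pulse <- function(amplitude, onset = 0, duration = 1) {
  make_input_profile("pulse", amplitude = amplitude, onset = onset,
                     duration = duration)
}

#' @export
print.meio_input <- function(x, ...) {
  kind <- attr(x, "kind")
  cat("<progesterone input: ", kind,
      ", amplitude ", attr(x, "amplitude"),
      ", onset ", attr(x, "onset"),
      if (kind == "pulse") paste0(", duration ", attr(x, "duration")),
      ">\n", sep = "")
  invisible(x)
}
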