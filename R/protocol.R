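#' Rectangular stimulation protocols
#'
#' A plasticity-inducing stimulus \eqn{I(t)} made of rectangular episodes:
#' drive `amplitude` for `t_on` time units, then 0 for `t_off`, repeated
#' `n_episodes` times (possibly unbounded). This abstracts an extracellular
#' high-frequency pulse train: the larger the pulse frequency, the larger
#' the amplitude; the intra-episode pulse structure is compressed into one
#' rectangle because inter-pulse gaps are short relative to the plasticity
#' timescale. `t_off = 0` is the DC (sustained-drive) limit. Times are in
#' units of \eqn{\tau_w}.
#'
#' Episode windows are half-open `[onset, onset + t_on)`: a time falling
#' exactly on an off-transition reads 0.
#'
#' @param amplitude signed drive level; positive potentiates.
#' @param t_on episode duration (> 0).
#' @param t_off inter-episode interval (>= 0).
#' @param n_episodes positive integer or `Inf`.
#' @return object of class `consol_protocol`.
#' @examples
#' p <- stimulus_protocol(17.75, t_on = 0.01, t_off = 0.11)
#' stimulus_at(p, c(0, 0.005, 0.01, 0.12))
#' @export
stimulus_protocol <- function(amplitude, t_on, t_off = 0, n_episodes = Inf) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1, is.finite(amplitude))
  if (!is.numeric(t_on) || t_on <= 0) stop("t_on must be positive")
  if (!is.numeric(t_off) || t_off < 0) stop("t_off must be nonnegative")
  if (!(is.infinite(n_episodes) || (n_episodes >= 1 && n_episodes == round(n_episodes))))
    stop("n_episodes must be a positive integer or Inf")
  structure(list(amplitude = amplitude, t_on = t_on, t_off = t_off,
                 n_episodes = n_episodes),
            class = "consol_protocol")
}

#' @rdname stimulus_protocol
#' @export
single_episode <- function(amplitude, t_on) {
  stimulus_protocol(amplitude, t_on, t_off = 0, n_episodes = 1)
}

#' @rdname stimulus_protocol
#' @export
dc_stimulus <- function(amplitude) {
  stimulus_protocol(amplitude, t_on = 1, t_off = 0, n_episodes = Inf)
}

#' @export
print.consol_protocol <- function(x, ...) {
  if (is.infinite(x$n_episodes) && x$t_off == 0) {
    cat(sprintf("DC stimulus, amplitude %g\n", x$amplitude))
  } else {
    cat(sprintf("Rectangular stimulus: amplitude %g, t_on %g, t_off %g, %s episode(s)\n",
                x$amplitude, x$t_on, x$t_off,
                if (is.infinite(x$n_episodes)) "unbounded" else x$n_episodes))
    if (is.finite(x$n_episodes))
      cat(sprintf("  total area %g\n", protocol_area(x, x$n_episodes)))
  }
  invisible(x)
}

#' Drive value at a time
#'
#' Evaluates the rectangular-episode stimulus at times `t >= 0` (vectorized).
#'
#' @param protocol a [stimulus_protocol()].
#' @param t times, in units of \eqn{\tau_w}.
#' @return drive values.
#' @export
stimulus_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "consol_protocol"))
  if (any(t < 0)) stop("t must be nonnegative")
  period <- protocol$t_on + protocol$t_off
  k <- floor(t / period)
  phase <- t - k * period
  on <- (k < protocol$n_episodes) & (phase < protocol$t_on)
  ifelse(on, protocol$amplitude, 0)
}

#' Cumulative stimulus area
#'
#' The total stimulation effort of `episodes_delivered` episodes:
#' `episodes_delivered * |amplitude| * t_on` (the time-integral of
#' \eqn{|I(t)|} over complete episodes).
#'
#' @inheritParams stimulus_at
#' @param episodes_delivered nonnegative integer.
#' @return scalar area.
#' @export
protocol_area <- function(protocol, episodes_delivered) {
  stopifnot(inherits(protocol, "consol_protocol"),
            episodes_delivered >= 0)
  episodes_delivered * abs(protocol$amplitude) * protocol$t_on
}
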