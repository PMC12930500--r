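#' Periodic pulse-train stimulation protocol
#'
#' Builds the deterministic input schedule x(t) used to probe the circuits:
#' `n_pulses` rectangular pulses of duration `dur_on`, each followed by an
#' input-free relaxation interval of duration `dur_off`, so the stimulation
#' period is `dur_on + dur_off`. Pulse windows are half-open
#' `[onset, onset + dur_on)` so that `input_level()` is single-valued at
#' the edges.
#'
#' @param n_pulses Number of pulses (>= 1).
#' @param dur_on On-time of each pulse (> 0).
#' @param dur_off Input-free interval after each pulse (>= 0).
#' @param amplitude Input level during pulses (> 0). The circuit models are
#'   nondimensional; 1 is the conventional default.
#' @param first_onset Time of the first pulse onset (default 0).
#' @return A `pulse_train` object.
#' @examples
#' pulse_train(n_pulses = 10, dur_on = 1, dur_off = 9)
#' @export
pulse_train <- function(n_pulses, dur_on, dur_off, amplitude = 1,
                        first_onset = 0) {
  stopifnot(is.numeric(n_pulses), length(n_pulses) == 1L,
            n_pulses >= 1, n_pulses == round(n_pulses))
  check_positive_scalar(dur_on, "dur_on")
  if (!is.numeric(dur_off) || length(dur_off) != 1L || is.na(dur_off) ||
      dur_off < 0) {
    stop("`dur_off` must be a single number >= 0.", call. = FALSE)
  }
  check_positive_scalar(amplitude, "amplitude")
  stopifnot(is.numeric(first_onset), length(first_onset) == 1L,
            is.finite(first_onset))
  structure(
    list(n_pulses = as.integer(n_pulses), dur_on = dur_on,
         dur_off = dur_off, amplitude = amplitude,
         first_onset = first_onset),
    class = "pulse_train"
  )
}

#' Massed-spaced stimulation protocol
#'
#' A fixed total stimulus duration `total_on_time` split into `n_pulses`
#' equal pulses separated by an input-free delay `gap`. With `n_pulses = 1`
#' the whole stimulus is delivered as one massed block and the gap is
#' irrelevant. The onset-to-onset spacing of the spaced protocol is
#' `total_on_time / n_pulses + gap`.
#'
#' @param total_on_time Total stimulus duration T (> 0); each pulse has
#'   width `T / n_pulses`, so the delivered on-time is identical for every
#'   `n_pulses`.
#' @param n_pulses Number of equal pulses (>= 1).
#' @param gap Input-free delay between consecutive pulses (>= 0).
#' @param amplitude Input level during pulses (> 0).
#' @return A `massed_spaced` object.
#' @examples
#' massed_spaced(total_on_time = 10, n_pulses = 5, gap = 50)
#' massed_spaced(10, n_pulses = 1, gap = 50)  # massed: gap has no effect
#' @export
massed_spaced <- function(total_on_time, n_pulses, gap, amplitude = 1) {
  check_positive_scalar(total_on_time, "total_on_time")
  stopifnot(is.numeric(n_pulses), length(n_pulses) == 1L,
            n_pulses >= 1, n_pulses == round(n_pulses))
  if (!is.numeric(gap) || length(gap) != 1L || is.na(gap) || gap < 0) {
    stop("`gap` must be a single number >= 0.", call. = FALSE)
  }
  check_positive_scalar(amplitude, "amplitude")
  structure(
    list(total_on_time = total_on_time, n_pulses = as.integer(n_pulses),
         gap = gap, amplitude = amplitude),
    class = "massed_spaced"
  )
}

#' Convert a massed-spaced protocol to an explicit pulse train
#'
#' @param p A `massed_spaced` protocol.
#' @return A `pulse_train` with `n_pulses` pulses of width
#'   `total_on_time / n_pulses` and off-gap `gap`. For `n_pulses = 1` this
#'   is a single massed pulse of the full width.
#' @examples
#' to_pulse_train(massed_spaced(10, n_pulses = 5, gap = 50))
#' @export
to_pulse_train <- function(p) {
  stopifnot(inherits(p, "massed_spaced"))
  pulse_train(n_pulses = p$n_pulses,
              dur_on = p$total_on_time / p$n_pulses,
              dur_off = p$gap,
              amplitude = p$amplitude)
}

as_pulse_train <- function(schedule) {
  if (inherits(schedule, "pulse_train")) return(schedule)
  if (inherits(schedule, "massed_spaced")) return(to_pulse_train(schedule))
  stop("`schedule` must be a pulse_train or massed_spaced object.",
       call. = FALSE)
}

#' Pulse onset times of a schedule
#'
#' @param schedule A `pulse_train` or `massed_spaced` object.
#' @return Numeric vector of pulse onset times.
#' @export
pulse_onsets <- function(schedule) {
  s <- as_pulse_train(schedule)
  s$first_onset + (seq_len(s$n_pulses) - 1) * (s$dur_on + s$dur_off)
}

#' Evaluate the input signal x(t)
#'
#' Piecewise-constant realization of the stimulation protocol: the
#' amplitude inside any half-open pulse window `[onset, onset + dur_on)`,
#' zero elsewhere (including all times before the first onset).
#'
#' @param t Numeric vector of times.
#' @param schedule A `pulse_train` or `massed_spaced` object.
#' @return Numeric vector of input levels.
#' @examples
#' s <- pulse_train(3, dur_on = 1, dur_off = 9)
#' input_level(c(0.5, 5, 10), s)  # 1 0 1
#' @export
input_level <- function(t, schedule) {
  stopifnot(is.numeric(t), all(is.finite(t)))
  s <- as_pulse_train(schedule)
  period <- s$dur_on + s$dur_off
  rel <- t - s$first_onset
  if (s$dur_off == 0) {
    inside <- rel >= 0 & rel < s$n_pulses * s$dur_on
  } else {
    k <- floor(rel / period)
    phase <- rel - k * period
    inside <- rel >= 0 & k < s$n_pulses & phase < s$dur_on
  }
  s$amplitude * as.numeric(inside)
}

#' Partition a trajectory horizon into per-stimulus intervals
#'
#' Peak-based learning metrics score the output once per stimulus: interval
#' i spans from the onset of pulse i to the onset of pulse i + 1, and the
#' final interval runs from the last onset to the horizon (a finite
#' truncation of the open-ended final interval; the default simulation
#' horizon is long enough that the final output peak falls inside it).
#'
#' @param schedule A `pulse_train` or `massed_spaced` object.
#' @param horizon End time of the final interval; must exceed the last
#'   pulse onset.
#' @return A tibble with columns `interval`, `start`, `end`, carrying class
#'   `interval_partition`.
#' @examples
#' stim_partition(pulse_train(2, 1, 9), horizon = 30)
#' @export
stim_partition <- function(schedule, horizon) {
  onsets <- pulse_onsets(schedule)
  check_positive_scalar(horizon - onsets[length(onsets)],
                        "horizon - last onset")
  out <- tibble::tibble(
    interval = seq_along(onsets),
    start = onsets,
    end = c(onsets[-1], horizon)
  )
  class(out) <- c("interval_partition", class(out))
  out
}

#' Default simulation horizon for a schedule
#'
#' Last pulse onset plus one full stimulation period, plus a settling tail
#' scaled by the slowest relevant decay rate: `10 / lambda` for circuits
#' whose output is degradation-tagged (habituation, sensitization, hybrid)
#' and `5 / gamma` for the massed-spaced circuit where every species decays
#' at the slow rate. This captures the final-interval peak and its tail.
#'
#' @param schedule A `pulse_train` or `massed_spaced` object.
#' @param circuit Circuit kind (see [circuit_params()]).
#' @param params A `circuit_params` object.
#' @return A single time value.
#' @export
default_horizon <- function(schedule, circuit, params) {
  s <- as_pulse_train(schedule)
  onsets <- pulse_onsets(s)
  period <- s$dur_on + s$dur_off
  tail_time <- if (identical(circuit, "msl")) 5 / params$gamma
               else 10 / params$lambda
  onsets[length(onsets)] + period + tail_time
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf(
    "<pulse_train> %d pulse(s): on %g, off %g (period %g), amplitude %g, first onset %g\n",
    x$n_pulses, x$dur_on, x$dur_off, x$dur_on + x$dur_off, x$amplitude,
    x$first_onset))
  invisible(x)
}

#' @export
print.massed_spaced <- function(x, ...) {
  cat(sprintf(
    "<massed_spaced> total on-time %g split into %d pulse(s) of width %g, gap %g, amplitude %g\n",
    x$total_on_time, x$n_pulses, x$total_on_time / x$n_pulses, x$gap,
    x$amplitude))
  invisible(x)
}
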