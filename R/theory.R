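#' Impulsive stimulation protocol for the analytic memory model
#'
#' In the impulsive approximation each finite stimulus pulse is replaced by
#' an instantaneous jump of the memory species followed by exponential
#' decay. It is accurate when the pulse is much shorter than the relaxation
#' interval (`dur_on << dur_off`) and the memory stays far from saturation.
#' The jump size (`pulse_weight`) equals the production accumulated over
#' one pulse at full promoter activity: `alpha * dur_on` for the
#' single-behavior circuits, or `alpha * dur_on / n_pulses` when a fixed
#' total on-time is split into `n_pulses` equal pulses.
#'
#' Two pulse-time conventions coexist in the analytic layer, each matching
#' the model it approximates: [impulsive_memory()] and
#' [periodic_envelope()] place pulses at `t_k = k * period` for
#' `k = 1..n_pulses`, while the simplified massed-spaced model
#' ([msl_output()] and friends) places them at `t_k = k * dur_off` for
#' `k = 0..n_pulses - 1`, with the first pulse at time zero.
#'
#' @param pulse_weight Memory jump per pulse (> 0).
#' @param decay Memory decay rate gamma (> 0).
#' @param n_pulses Number of pulses (>= 1).
#' @param period Inter-pulse spacing. In the short-pulse regime the period
#'   is approximately the relaxation interval `dur_off`.
#' @return An `impulsive_protocol` object.
#' @examples
#' impulsive_protocol(pulse_weight = 1.5, decay = 0.01, n_pulses = 10,
#'                    period = 10)
#' @export
impulsive_protocol <- function(pulse_weight, decay, n_pulses, period) {
  check_positive_scalar(pulse_weight, "pulse_weight")
  check_positive_scalar(decay, "decay")
  stopifnot(is.numeric(n_pulses), length(n_pulses) == 1L, n_pulses >= 1,
            n_pulses == round(n_pulses))
  if (!is.numeric(period) || length(period) != 1L || is.na(period) ||
      period < 0) {
    stop("`period` must be a single number >= 0.", call. = FALSE)
  }
  structure(list(pulse_weight = pulse_weight, decay = decay,
                 n_pulses = as.integer(n_pulses), period = period),
            class = "impulsive_protocol")
}

#' Memory level under a Dirac pulse train
#'
#' Closed-form memory trajectory when each pulse is an instantaneous jump:
#' `I(t) = sum_k w H(t - t_k) exp(-gamma (t - t_k))` with pulses at
#' `t_k = k * period`, `k = 1..n_pulses`, and weight `w = pulse_weight`.
#' The step convention H(0) = 1 means a pulse arriving exactly at `t`
#' counts in full.
#'
#' @param t Nonnegative times (vectorized).
#' @param ip An `impulsive_protocol`.
#' @return Memory levels at `t`.
#' @export
impulsive_memory <- function(t, ip) {
  stopifnot(inherits(ip, "impulsive_protocol"),
            is.numeric(t), all(is.finite(t)), all(t >= 0))
  tk <- seq_len(ip$n_pulses) * ip$period
  vapply(t, function(ti) {
    dt <- ti - tk
    sum(ip$pulse_weight * heaviside_raw(dt) * exp(-ip$decay * dt *
                                                    (dt >= 0)))
  }, numeric(1))
}

# heaviside() without the finiteness check, for internal hot paths
heaviside_raw <- function(v) as.numeric(v >= 0)

#' Net memory change over one stimulation cycle
#'
#' Under the impulsive approximation, a cycle starting from memory `I0`
#' receives a jump of `pulse_weight` and then decays for `dur_off`:
#' `delta_I = (I0 + pulse_weight) exp(-decay * dur_off) - I0`. Memory
#' accumulates across cycles while this is positive.
#'
#' @param I0 Memory level just before the pulse (>= 0).
#' @param pulse_weight Jump per pulse.
#' @param decay Memory decay rate gamma.
#' @param dur_off Relaxation interval.
#' @return The net change in memory over the cycle.
#' @examples
#' memory_increment(1, 1.5, 0.01, 9)
#' @export
memory_increment <- function(I0, pulse_weight, decay, dur_off) {
  stopifnot(is.numeric(I0), all(I0 >= 0))
  (I0 + pulse_weight) * exp(-decay * dur_off) - I0
}

#' Critical relaxation interval for memory accumulation
#'
#' The longest relaxation interval that still permits net memory gain:
#' `dur_off* = log(1 + pulse_weight / I0) / decay`, the root of
#' [memory_increment()] in `dur_off`. Strictly below it the increment is
#' positive, strictly above it negative. With `I0 = 0` any relaxation
#' admits gain, so `Inf` is returned.
#'
#' @inheritParams memory_increment
#' @return The critical `dur_off` (possibly `Inf`).
#' @examples
#' critical_relaxation(1, 1.5, 0.01)  # 100 * log(2.5)
#' @export
critical_relaxation <- function(I0, pulse_weight, decay) {
  stopifnot(is.numeric(I0), length(I0) == 1L, I0 >= 0)
  check_positive_scalar(decay, "decay")
  if (pulse_weight < 0) stop("`pulse_weight` must be >= 0.", call. = FALSE)
  if (I0 == 0) return(Inf)
  log1p(pulse_weight / I0) / decay
}

#' Periodic steady-state memory envelope
#'
#' As the number of pulses grows, the impulsive memory approaches a
#' periodic profile over the cycle phase `tau` in `[0, period)`:
#' `I(tau) = pulse_weight * exp(-decay * tau) / (1 - exp(-decay * period))`.
#'
#' @param tau Phase within the cycle, `0 <= tau < period` (vectorized).
#' @param ip An `impulsive_protocol`.
#' @return Memory levels along the limiting cycle.
#' @export
periodic_envelope <- function(tau, ip) {
  stopifnot(inherits(ip, "impulsive_protocol"),
            is.numeric(tau), all(tau >= 0), all(tau < ip$period))
  ip$pulse_weight * exp(-ip$decay * tau) / (1 - exp(-ip$decay * ip$period))
}

#' Post-pulse memory levels in the simplified massed-spaced model
#'
#' In the simplified all-or-nothing massed-spaced model, `n_pulses` equal
#' jumps of size `pulse_weight` arrive at `t_k = k * dur_off`
#' (`k = 0..n_pulses - 1`). The memory level immediately after the k-th
#' pulse is the geometric accumulation
#' `A_k = w (1 - exp(-(k+1) g d)) / (1 - exp(-g d))` with `w` the weight,
#' `g` the decay and `d = dur_off`; for `dur_off = 0` the continuous limit
#' `(k + 1) w` is returned.
#'
#' @param k Pulse index, `0 <= k <= n_pulses - 1` (vectorized).
#' @param ip An `impulsive_protocol` whose `period` is the inter-pulse
#'   relaxation `dur_off`.
#' @return Memory levels `A_k`, nondecreasing in `k`.
#' @examples
#' ip <- impulsive_protocol(pulse_weight = 5, decay = 0.01, n_pulses = 2,
#'                          period = 50)
#' msl_state_after_pulse(0:1, ip)
#' @export
msl_state_after_pulse <- function(k, ip) {
  stopifnot(inherits(ip, "impulsive_protocol"), is.numeric(k),
            all(k >= 0), all(k <= ip$n_pulses - 1), all(k == round(k)))
  g <- ip$decay * ip$period
  if (g == 0) return(ip$pulse_weight * (k + 1))
  ip$pulse_weight * (1 - exp(-(k + 1) * g)) / (1 - exp(-g))
}

#' Output production windows of the simplified massed-spaced model
#'
#' The simplified model produces output at full rate while the memory sits
#' above the normalized threshold 1 and not at all below it. After pulse k
#' the memory `A_k` decays and crosses the threshold after
#' `t_k* = log(A_k) / decay`. The production window of pulse k is
#' `l_k = H(A_k - 1) * min(t_k*, dur_off)` for all but the final pulse
#' (production is cut short by the next arrival) and
#' `l_k = H(A_k - 1) * t_k*` for the final pulse. The threshold is fixed at
#' 1 by the model's normalization and is not a parameter.
#'
#' @param ip An `impulsive_protocol` (see [msl_state_after_pulse()]).
#' @return A tibble with one row per pulse: `k`, `t_k` (arrival time),
#'   `A_k`, `t_star`, `window` (= l_k).
#' @export
msl_production_windows <- function(ip) {
  stopifnot(inherits(ip, "impulsive_protocol"))
  k <- seq_len(ip$n_pulses) - 1L
  A_k <- msl_state_after_pulse(k, ip)
  t_star <- ifelse(A_k > 0, log(A_k) / ip$decay, -Inf)
  above <- heaviside_raw(A_k - 1)
  window <- ifelse(k == ip$n_pulses - 1L,
                   above * pmax(t_star, 0),
                   above * pmax(pmin(t_star, ip$period), 0))
  tibble::tibble(k = k, t_k = k * ip$period, A_k = A_k,
                 t_star = t_star, window = window)
}

#' Closed-form output of the simplified massed-spaced model
#'
#' Superposition of the per-pulse output contributions: pulse k produces at
#' rate `beta` for its window `l_k` starting at `t_k`, and its contribution
#' then decays at `gamma`. At time `t`,
#' `G(t) = (beta / gamma) sum_k (1 - exp(-gamma tau_k+)) exp(-gamma tau_k-)
#' H(t - t_k)` with `tau_k+ = min(t - t_k, l_k)` the production time
#' accrued and `tau_k- = max(0, t - t_k - l_k)` the time since production
#' from pulse k halted. The global maximum is attained at the end of the
#' final production window.
#'
#' @param t Nonnegative times (vectorized).
#' @param ip An `impulsive_protocol`.
#' @param beta Output production rate (> 0).
#' @return Output levels `G(t)`.
#' @export
msl_output <- function(t, ip, beta) {
  stopifnot(is.numeric(t), all(is.finite(t)), all(t >= 0))
  check_positive_scalar(beta, "beta")
  win <- msl_production_windows(ip)
  g <- ip$decay
  vapply(t, function(ti) {
    dt <- ti - win$t_k
    on <- heaviside_raw(dt)
    tau_plus <- pmin(pmax(dt, 0), win$window)
    tau_minus <- pmax(0, dt - win$window)
    (beta / g) * sum(on * (1 - exp(-g * tau_plus)) * exp(-g * tau_minus))
  }, numeric(1))
}

#' Peak output of a massed stimulus in the simplified model
#'
#' For a single massed pulse with total weight `w = alpha * dur_on`, the
#' production window is `log(w) / gamma` and the peak output is
#' `(beta / gamma) (1 - 1 / w)`, provided the pulse lifts the memory above
#' the threshold (`w > 1`). At or below threshold no output is produced:
#' the function returns 0 with attribute `below_threshold = TRUE`.
#'
#' @param p A `circuit_params` object (uses `alpha`, `beta`, `gamma`).
#' @param dur_on Duration of the massed pulse.
#' @return The peak output level.
#' @examples
#' p <- circuit_params(alpha = 1, beta = 1, gamma = 0.01)
#' massed_peak(p, dur_on = 10)   # 100 * (1 - 1/10) = 90
#' @export
massed_peak <- function(p, dur_on) {
  stopifnot(inherits(p, "circuit_params"))
  check_positive_scalar(dur_on, "dur_on")
  w <- p$alpha * dur_on
  if (w <= 1) {
    return(structure(0, below_threshold = TRUE))
  }
  (p$beta / p$gamma) * (1 - 1 / w)
}

#' Peak output of a two-pulse split in the simplified model
#'
#' When the same total weight `w = alpha * dur_on` is split into two equal
#' pulses separated by `dur_off`, and the half-weight pulse sustains
#' production across the whole gap (the spaced-superiority assumption,
#' `log(w / 2) >= gamma * dur_off`), the peak output is
#' `(beta / gamma) (1 - 2 exp(-gamma dur_off) /
#' (w (1 + exp(-gamma dur_off))))`. This strictly exceeds [massed_peak()]
#' whenever `gamma * dur_off > 0`. Outside the assumption's validity region
#' the closed form does not apply and the function refuses rather than
#' extrapolating.
#'
#' @inheritParams massed_peak
#' @param dur_off Gap between the two pulses (>= 0).
#' @return The peak output level.
#' @examples
#' p <- circuit_params(alpha = 1, beta = 1, gamma = 0.01)
#' two_pulse_peak(p, dur_on = 10, dur_off = 50)
#' @export
two_pulse_peak <- function(p, dur_on, dur_off) {
  stopifnot(inherits(p, "circuit_params"))
  check_positive_scalar(dur_on, "dur_on")
  stopifnot(is.numeric(dur_off), length(dur_off) == 1L, dur_off >= 0)
  if (!spaced_superiority_holds(p, dur_on, dur_off, n_pulses = 2)) {
    stop("closed form invalid: a half-weight pulse must sustain output ",
         "production across the whole gap (log(alpha * dur_on / 2) >= ",
         "gamma * dur_off).", call. = FALSE)
  }
  w <- p$alpha * dur_on
  e <- exp(-p$gamma * dur_off)
  (p$beta / p$gamma) * (1 - 2 * e / (w * (1 + e)))
}

#' Does the spaced-superiority condition hold?
#'
#' Splitting a stimulus of weight `alpha * dur_on` into `n_pulses` equal
#' pulses separated by `dur_off` is guaranteed to beat the massed delivery
#' when each split pulse alone sustains output production for the full
#' relaxation phase: `log(alpha * dur_on / n_pulses) >= gamma * dur_off`.
#' This is a sufficient condition carving out a strict subset of the region
#' where spacing actually helps.
#'
#' @inheritParams two_pulse_peak
#' @param n_pulses Number of equal pulses (>= 1).
#' @return `TRUE` or `FALSE`.
#' @export
spaced_superiority_holds <- function(p, dur_on, dur_off, n_pulses) {
  stopifnot(inherits(p, "circuit_params"), n_pulses >= 1)
  log(p$alpha * dur_on / n_pulses) >= p$gamma * dur_off
}
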