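#' Integration grid settings
#'
#' Controls the fixed-step integrator. `max_step` bounds the RK4 step (the
#' actual step within each smooth segment is the segment length divided by
#' an integer, hence <= `max_step`); `sample_spacing` sets the dense-output
#' grid, produced by cubic Hermite interpolation of the accepted steps.
#'
#' @param max_step Upper bound on the RK4 step. Default
#'   `min(0.01, dur_on / 100)` of the schedule.
#' @param sample_spacing Spacing of emitted samples. Default `dur_on / 10`.
#' @param horizon End of integration. Default from [default_horizon()].
#' @return A `simulation_grid` object.
#' @export
simulation_grid <- function(max_step = NULL, sample_spacing = NULL,
                            horizon = NULL) {
  if (!is.null(max_step)) check_positive_scalar(max_step, "max_step")
  if (!is.null(sample_spacing)) {
    check_positive_scalar(sample_spacing, "sample_spacing")
  }
  if (!is.null(horizon)) check_positive_scalar(horizon, "horizon")
  structure(list(max_step = max_step, sample_spacing = sample_spacing,
                 horizon = horizon),
            class = "simulation_grid")
}

resolve_grid <- function(grid, schedule, circuit, params) {
  s <- as_pulse_train(schedule)
  if (is.null(grid)) grid <- simulation_grid()
  stopifnot(inherits(grid, "simulation_grid"))
  list(
    max_step = grid$max_step %||% min(0.01, s$dur_on / 100),
    sample_spacing = grid$sample_spacing %||% (s$dur_on / 10),
    horizon = grid$horizon %||% default_horizon(s, circuit, params)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Smooth-segment boundaries: every pulse edge inside (0, horizon), plus the
# endpoints. The input is constant on each resulting segment, so the RK4
# never steps across a discontinuity.
segment_breaks <- function(schedule, horizon) {
  s <- as_pulse_train(schedule)
  onsets <- pulse_onsets(s)
  edges <- sort(unique(c(onsets, onsets + s$dur_on)))
  edges <- edges[edges > 0 & edges < horizon]
  c(0, edges, horizon)
}

#' Integrate a circuit over a stimulation schedule
#'
#' Deterministic integration of one of the four circuit models from its
#' resting state (or a user-supplied initial state) over a pulse-train or
#' massed-spaced schedule. The integrator is a classical fixed-step
#' fourth-order Runge-Kutta scheme restarted exactly at every pulse edge,
#' so the discontinuous input never straddles a step; results are
#' bit-for-bit reproducible for a given grid. Dense output at
#' `sample_spacing` is produced by cubic Hermite interpolation of the
#' accepted steps (using the stored state derivatives).
#'
#' Tiny negative excursions caused by roundoff (above -1e-9) are clipped to
#' zero in the emitted trajectory; anything more negative, or a non-finite
#' state, raises an error naming the offending time.
#'
#' @param circuit Circuit kind (`"habituation"`, `"sensitization"`,
#'   `"hybrid"`, `"msl"`).
#' @param params A `circuit_params` object.
#' @param schedule A `pulse_train` or `massed_spaced` object.
#' @param grid Optional [simulation_grid()].
#' @param state0 Optional initial state (named or in [circuit_species()]
#'   order); defaults to [resting_state()]. Useful for perturbation
#'   experiments such as starting with preloaded memory.
#' @return A `circuit_trajectory`: a tibble with columns `time`, `input`
#'   and one column per species, with the circuit kind, parameters,
#'   schedule and grid attached as attributes.
#' @examples
#' p <- circuit_params(alpha = 1.5, beta = 5, gamma = 0.01, lambda = 1, mu = 1)
#' traj <- simulate_protocol("habituation", p, pulse_train(3, 1, 9))
#' dplyr::slice_max(traj, G, n = 1)
#' @export
integrate_circuit <- function(circuit, params, schedule, grid = NULL,
                              state0 = NULL) {
  circuit <- check_circuit(circuit)
  check_params_for(circuit, params)
  s <- as_pulse_train(schedule)
  g <- resolve_grid(grid, s, circuit, params)
  last_off <- pulse_onsets(s)[s$n_pulses] + s$dur_on
  if (g$horizon < last_off) {
    stop(sprintf("horizon (%g) ends before the schedule does (%g).",
                 g$horizon, last_off), call. = FALSE)
  }

  state <- if (is.null(state0)) resting_state(circuit, params)
           else check_state(state0, circuit)
  species <- circuit_species(circuit)
  d <- length(species)
  rhs <- circuit_rhs_fast(circuit, params)

  breaks <- segment_breaks(s, g$horizon)
  sample_times <- seq(0, g$horizon, by = g$sample_spacing)
  if (sample_times[length(sample_times)] < g$horizon) {
    sample_times <- c(sample_times, g$horizon)
  }
  out <- matrix(NA_real_, nrow = length(sample_times), ncol = d)

  state <- as.numeric(state)
  filled <- 0L
  for (seg in seq_len(length(breaks) - 1L)) {
    a <- breaks[seg]; b <- breaks[seg + 1L]
    x_seg <- input_level((a + b) / 2, s)
    n_steps <- max(1L, ceiling((b - a) / g$max_step - 1e-12))
    h <- (b - a) / n_steps
    states <- matrix(NA_real_, nrow = n_steps + 1L, ncol = d)
    derivs <- matrix(NA_real_, nrow = n_steps + 1L, ncol = d)
    states[1L, ] <- state
    derivs[1L, ] <- rhs(state, x_seg)
    for (i in seq_len(n_steps)) {
      k1 <- derivs[i, ]
      k2 <- rhs(state + (h / 2) * k1, x_seg)
      k3 <- rhs(state + (h / 2) * k2, x_seg)
      k4 <- rhs(state + h * k3, x_seg)
      state <- state + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
      states[i + 1L, ] <- state
      derivs[i + 1L, ] <- rhs(state, x_seg)
    }
    if (any(!is.finite(states))) {
      bad <- which(!is.finite(rowSums(states)))[1L]
      stop(sprintf("state became non-finite near t = %g; check parameters.",
                   a + (bad - 1L) * h), call. = FALSE)
    }
    # samples falling in [a, b); the final segment also takes t = horizon
    in_seg <- sample_times >= a - 1e-12 & sample_times < b - 1e-12
    if (seg == length(breaks) - 1L) {
      in_seg <- in_seg | abs(sample_times - b) <= 1e-12
    }
    idx <- which(in_seg & seq_along(sample_times) > filled)
    if (length(idx)) {
      tt <- sample_times[idx]
      u <- pmin(pmax((tt - a) / h, 0), n_steps)
      j <- pmin(floor(u), n_steps - 1L)
      f <- u - j            # local coordinate in [0, 1]
      j1 <- as.integer(j) + 1L
      h00 <- (1 + 2 * f) * (1 - f)^2
      h10 <- f * (1 - f)^2
      h01 <- f^2 * (3 - 2 * f)
      h11 <- f^2 * (f - 1)
      for (col in seq_len(d)) {
        out[idx, col] <- h00 * states[j1, col] + h10 * h * derivs[j1, col] +
          h01 * states[j1 + 1L, col] + h11 * h * derivs[j1 + 1L, col]
      }
      filled <- max(idx)
    }
  }

  too_negative <- out < -1e-9
  if (any(too_negative)) {
    bad <- which(too_negative, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "species %s reached %g at t = %g (below the -1e-9 roundoff slack).",
      species[bad[2L]], out[bad[1L], bad[2L]], sample_times[bad[1L]]),
      call. = FALSE)
  }
  out[out < 0] <- 0

  traj <- tibble::tibble(time = sample_times,
                         input = input_level(sample_times, s))
  for (col in seq_len(d)) traj[[species[col]]] <- out[, col]
  new_trajectory(traj, circuit, params, s, g)
}

new_trajectory <- function(tbl, circuit, params, schedule, grid) {
  structure(tbl,
            class = c("circuit_trajectory", class(tibble::tibble())),
            circuit = circuit, params = params, schedule = schedule,
            grid = grid)
}

#' @rdname integrate_circuit
#' @param ... Passed on to [integrate_circuit()].
#' @export
simulate_protocol <- function(circuit, params, schedule, ...) {
  integrate_circuit(circuit, params, schedule, ...)
}

#' Trajectory metadata accessors
#'
#' @param traj A `circuit_trajectory`.
#' @return The circuit kind, parameters or schedule stored on the
#'   trajectory.
#' @export
trajectory_circuit <- function(traj) attr(traj, "circuit", exact = TRUE)

#' @rdname trajectory_circuit
#' @export
trajectory_params <- function(traj) attr(traj, "params", exact = TRUE)

#' @rdname trajectory_circuit
#' @export
trajectory_schedule <- function(traj) attr(traj, "schedule", exact = TRUE)
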