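# Independent oracles used across the suite. These deliberately take
# different routes than the package code they check.

# Event-driven exact solution of the simplified all-or-nothing
# massed-spaced model: N instantaneous memory jumps of size w at
# t_k = k * dur_off, memory decaying at `gamma` between jumps, and output
# dG = beta * [A >= 1] - gamma * G integrated exactly on each segment
# where the production indicator is constant. Breakpoints are the jump
# times and the analytically located threshold crossings.
oracle_msl_G <- function(t_query, w, gamma, n_pulses, dur_off, beta) {
  t_jump <- (seq_len(n_pulses) - 1) * dur_off

  # memory level just after each jump, by direct decay recursion
  A_post <- numeric(n_pulses)
  A_post[1] <- w
  if (n_pulses > 1) {
    for (k in 2:n_pulses) {
      A_post[k] <- A_post[k - 1] * exp(-gamma * dur_off) + w
    }
  }

  # breakpoints: jump times, threshold crossings, and a far horizon
  horizon <- t_jump[n_pulses] +
    max(dur_off, log(max(A_post)) / gamma + 1, 1) + 10 / gamma
  brk <- t_jump
  for (k in seq_len(n_pulses)) {
    if (A_post[k] > 1) {
      cross <- t_jump[k] + log(A_post[k]) / gamma
      nxt <- if (k < n_pulses) t_jump[k + 1] else Inf
      if (cross < nxt) brk <- c(brk, cross)
    }
  }
  brk <- sort(unique(c(brk, horizon, t_query)))
  brk <- brk[brk <= horizon + 1e-12]

  A_at <- function(t) {
    lvl <- 0
    for (k in seq_len(n_pulses)) {
      if (t >= t_jump[k]) lvl <- lvl + w * exp(-gamma * (t - t_jump[k]))
    }
    lvl
  }

  G_at_brk <- numeric(length(brk))
  G <- 0
  for (i in seq_along(brk)[-1]) {
    a <- brk[i - 1]; b <- brk[i]
    producing <- A_at((a + b) / 2) >= 1
    dt <- b - a
    G <- if (producing) beta / gamma + (G - beta / gamma) * exp(-gamma * dt)
         else G * exp(-gamma * dt)
    G_at_brk[i] <- G
  }
  list(G = G_at_brk[match(t_query, brk)], breakpoints = brk,
       G_breaks = G_at_brk, A_post = A_post)
}

# Random admissible protocol for the simplified massed-spaced model:
# parameters drawn so the spaced-superiority condition
# log(alpha * dur_on / N) >= gamma * dur_off holds.
draw_admissible_protocol <- function() {
  n <- sample(1:6, 1)
  gamma <- runif(1, 0.005, 0.05)
  w_total <- runif(1, n * 1.5, n * 20)          # alpha * dur_on
  d_max <- log(w_total / n) / gamma
  dur_off <- runif(1, 0.05 * d_max, 0.95 * d_max)
  list(n = n, gamma = gamma, w_total = w_total, dur_off = dur_off,
       beta = runif(1, 0.5, 2))
}

# Reference ODE solution via deSolve (adaptive lsoda restarted at pulse
# edges), an integration route independent of the package's fixed-step
# scheme. Returns the state matrix at the requested times (which must
# include 0 and be sorted).
desolve_trajectory <- function(circuit, params, schedule, times) {
  s <- if (inherits(schedule, "massed_spaced")) to_pulse_train(schedule)
       else schedule
  rhs_pkg <- switch(circuit,
                    habituation = habituation_rhs,
                    sensitization = sensitization_rhs,
                    hybrid = hybrid_rhs,
                    msl = msl_rhs)
  deriv <- function(t, y, parms) {
    list(as.numeric(rhs_pkg(pmax(y, 0), parms$x, params)))
  }
  horizon <- max(times)
  onsets <- pulse_onsets(s)
  edges <- sort(unique(c(onsets, onsets + s$dur_on)))
  edges <- edges[edges > 0 & edges < horizon]
  brk <- c(0, edges, horizon)
  y <- resting_state(circuit, params)
  species <- circuit_species(circuit)
  out <- matrix(NA_real_, nrow = length(times), ncol = length(species),
                dimnames = list(NULL, species))
  out[1, ] <- y
  for (i in seq_along(brk)[-1]) {
    a <- brk[i - 1]; b <- brk[i]
    x_seg <- input_level((a + b) / 2, s)
    inside <- which(times > a & times <= b)
    seg_times <- sort(unique(c(a, times[inside], b)))
    sol <- deSolve::lsoda(y, seg_times, deriv, parms = list(x = x_seg),
                          rtol = 1e-11, atol = 1e-12)
    rows <- match(times[inside], sol[, 1])
    out[inside, ] <- sol[rows, -1, drop = FALSE]
    y <- sol[nrow(sol), -1]
  }
  out
}

# Column-wise bit-identity of two trajectories (ignores metadata
# attributes, whose integer/double storage may differ after JSON I/O).
expect_same_samples <- function(a, b) {
  testthat::expect_identical(names(a), names(b))
  for (nm in names(a)) testthat::expect_identical(a[[nm]], b[[nm]])
}

sched_dur_on <- function(s) {
  if (inherits(s, "massed_spaced")) s$total_on_time / s$n_pulses
  else s$dur_on
}

fig_params <- function(which) {
  switch(which,
    habituation = circuit_params(alpha = 1.5, beta = 5, gamma = 0.01,
                                 lambda = 1, mu = 1),
    sensitization = circuit_params(alpha = 1.5, beta = 5, gamma = 0.01,
                                   lambda = 1, mu = 1, rho = 1.75),
    hybrid = circuit_params(alpha = 1.5, beta = 10, gamma = 0.01,
                            lambda = 1, mu = 1, rho = 1.75, K_out = 1.5),
    msl = circuit_params(alpha = 1, beta = 1, gamma = 0.01, mu = 1))
}
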