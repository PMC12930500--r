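test_that("impulsive memory sums step-gated exponential decays", {
  ip <- impulsive_protocol(pulse_weight = 1.5, decay = 0.01, n_pulses = 3,
                           period = 10)
  # before the first pulse (pulses start at t = period)
  expect_identical(impulsive_memory(5, ip), 0)
  # a pulse arriving exactly at t counts in full (H(0) = 1)
  expect_equal(impulsive_memory(10, ip), 1.5)
  # vanishing decay: all received pulses simply add up
  ip0 <- impulsive_protocol(1.5, decay = 1e-12, n_pulses = 3, period = 10)
  expect_equal(impulsive_memory(35, ip0), 3 * 1.5, tolerance = 1e-9)
  # direct two-pulse evaluation
  expect_equal(impulsive_memory(25, ip),
               1.5 * exp(-0.01 * 15) + 1.5 * exp(-0.01 * 5))
})

test_that("per-cycle memory increment and its critical relaxation agree", {
  expect_equal(memory_increment(1, 1.5, 0.01, 0), 1.5)
  expect_equal(memory_increment(1, 1.5, 0.01, 1e9), -1, tolerance = 1e-6)
  expect_equal(memory_increment(1, 1.5, 0.01, 9), 2.5 * exp(-0.09) - 1)

  expect_equal(critical_relaxation(1, 1.5, 0.01), 100 * log(2.5))
  expect_identical(critical_relaxation(1, 0, 0.01), 0)
  expect_identical(critical_relaxation(0, 1.5, 0.01), Inf)

  # defining identity: increment vanishes exactly at the critical gap
  set.seed(3)
  for (i in 1:20) {
    I0 <- runif(1, 0.05, 20); w <- runif(1, 0.05, 5)
    g <- runif(1, 0.001, 0.1)
    crit <- critical_relaxation(I0, w, g)
    expect_lt(abs(memory_increment(I0, w, g, crit)), 1e-10)
    expect_gt(memory_increment(I0, w, g, 0.99 * crit), 0)
    expect_lt(memory_increment(I0, w, g, 1.01 * crit), 0)
  }
})

test_that("bisection of the increment recovers the critical relaxation to 1e-10", {
  cases <- list(c(1, 1.5, 0.01), c(4, 0.7, 0.02), c(0.3, 2.5, 0.005))
  for (cs in cases) {
    I0 <- cs[1]; w <- cs[2]; g <- cs[3]
    lo <- 0; hi <- 10 / g
    stopifnot(memory_increment(I0, w, g, hi) < 0)
    for (i in 1:80) {
      mid <- (lo + hi) / 2
      if (memory_increment(I0, w, g, mid) > 0) lo <- mid else hi <- mid
    }
    expect_lt(abs((lo + hi) / 2 - critical_relaxation(I0, w, g)), 1e-10)
  }
})

test_that("the periodic envelope is the large-N limit of the pulse sum", {
  ip <- impulsive_protocol(pulse_weight = 1.5, decay = 0.01, n_pulses = 500,
                           period = 10)
  expect_equal(periodic_envelope(0, ip), 1.5 / (1 - exp(-0.1)))
  # pure decay within a cycle
  expect_equal(periodic_envelope(0, ip) / periodic_envelope(10 - 1e-12, ip),
               exp(0.01 * 10), tolerance = 1e-9)
  # no carry-over when a cycle fully clears the memory
  ip_hot <- impulsive_protocol(1.5, decay = 5, n_pulses = 10, period = 10)
  expect_equal(periodic_envelope(0, ip_hot), 1.5, tolerance = 1e-9)

  # convergence: late-cycle pulse-train memory matches the envelope
  for (tau in c(0, 2.5, 7.5)) {
    late <- 450 * ip$period + tau
    expect_equal(impulsive_memory(late, ip), periodic_envelope(tau, ip),
                 tolerance = 1e-6)
  }
})

test_that("post-pulse memory levels follow the geometric accumulation", {
  ip <- impulsive_protocol(pulse_weight = 5, decay = 0.01, n_pulses = 2,
                           period = 50)
  expect_equal(msl_state_after_pulse(0, ip), 5)
  expect_equal(msl_state_after_pulse(1, ip),
               5 * (1 - exp(-1)) / (1 - exp(-0.5)))

  # saturating decay: every pulse starts from scratch
  ip_far <- impulsive_protocol(5, decay = 1, n_pulses = 4, period = 1e4)
  expect_equal(msl_state_after_pulse(0:3, ip_far), rep(5, 4),
               tolerance = 1e-12)
  # zero gap: continuity limit (k + 1) w
  ip0 <- impulsive_protocol(5, decay = 0.01, n_pulses = 3, period = 0)
  expect_equal(msl_state_after_pulse(0:2, ip0), c(5, 10, 15))

  # nondecreasing in k, and matches the explicit jump recursion
  set.seed(5)
  for (i in 1:10) {
    n <- sample(2:6, 1); w <- runif(1, 0.5, 10); g <- runif(1, 0.005, 0.1)
    d <- runif(1, 1, 80)
    ip_r <- impulsive_protocol(w, g, n, d)
    A <- msl_state_after_pulse(0:(n - 1), ip_r)
    expect_true(all(diff(A) >= -1e-12))
    rec <- Reduce(function(prev, k) prev * exp(-g * d) + w, seq_len(n - 1),
                  accumulate = TRUE, init = w)
    expect_equal(A, rec, tolerance = 1e-12)
  }
})

test_that("production windows honor the threshold and the next arrival", {
  # sub-threshold protocol never produces
  ip_low <- impulsive_protocol(pulse_weight = 0.3, decay = 0.01,
                               n_pulses = 3, period = 200)
  expect_true(all(msl_production_windows(ip_low)$window == 0))

  # single strong pulse: window is log(w)/gamma
  ip1 <- impulsive_protocol(10, 0.01, n_pulses = 1, period = 0)
  expect_equal(msl_production_windows(ip1)$window, 100 * log(10))

  # intermediate windows are clipped by the next pulse arrival
  ip2 <- impulsive_protocol(10, 0.01, n_pulses = 2, period = 50)
  win <- msl_production_windows(ip2)
  expect_equal(win$window[1], 50)   # log(10)/0.01 = 230 > gap
  expect_equal(win$window[2], 100 * log(10 * exp(-0.5) + 10))
})

test_that("closed-form output matches the event-driven oracle on random protocols", {
  set.seed(21)
  for (i in 1:30) {
    pr <- draw_admissible_protocol()
    w <- pr$w_total / pr$n
    ip <- impulsive_protocol(w, pr$gamma, pr$n, pr$dur_off)
    win <- msl_production_windows(ip)
    t_query <- sort(unique(c(
      win$t_k + win$window,                        # ends of windows
      seq(0, max(win$t_k) + pr$dur_off + 2 / pr$gamma, length.out = 41))))
    got <- msl_output(t_query, ip, pr$beta)
    ora <- oracle_msl_G(t_query, w, pr$gamma, pr$n, pr$dur_off, pr$beta)
    expect_lt(max(abs(got - ora$G)), 1e-6)
  }
})

test_that("massed and two-pulse closed-form peaks match the output model", {
  p <- fig_params("msl")
  expect_equal(massed_peak(p, dur_on = 10), 90)
  expect_equal(as.numeric(massed_peak(p, dur_on = 1)), 0)
  expect_true(attr(massed_peak(p, dur_on = 1), "below_threshold"))
  # saturation limit beta / gamma
  expect_equal(massed_peak(p, dur_on = 1e9), 100, tolerance = 1e-7)

  expect_equal(two_pulse_peak(p, 10, 50),
               100 * (1 - 2 * exp(-0.5) / (10 * (1 + exp(-0.5)))))
  expect_equal(two_pulse_peak(p, 10, 0), massed_peak(p, 10))
  expect_error(two_pulse_peak(p, 10, 1000), "sustain")

  # peaks of the summed-output model at window ends reproduce both forms
  ip1 <- impulsive_protocol(10, 0.01, n_pulses = 1, period = 0)
  w1 <- msl_production_windows(ip1)
  expect_equal(msl_output(w1$t_k + w1$window, ip1, 1)[1],
               massed_peak(p, 10), tolerance = 1e-9)
  ip2 <- impulsive_protocol(5, 0.01, n_pulses = 2, period = 50)
  w2 <- msl_production_windows(ip2)
  expect_equal(max(msl_output(w2$t_k + w2$window, ip2, 1)),
               two_pulse_peak(p, 10, 50), tolerance = 1e-9)
})

test_that("spacing beats massing whenever the superiority condition holds", {
  p <- fig_params("msl")
  expect_true(spaced_superiority_holds(p, 10, 50, 2))   # ln 5 > 0.5
  expect_false(spaced_superiority_holds(p, 10, 1, 20))  # N > alpha dur_on
  expect_true(spaced_superiority_holds(p, 10, 0, 10))

  # strict improvement of the two-pulse split for any positive gap
  set.seed(13)
  for (i in 1:20) {
    g <- runif(1, 0.002, 0.05); w <- runif(1, 3, 40)
    d <- runif(1, 0.1, 0.95) * log(w / 2) / g
    pp <- circuit_params(alpha = 1, beta = 1, gamma = g)
    expect_gt(two_pulse_peak(pp, w, d), massed_peak(pp, w))
  }

  # numeric check of the general-N claim on admissible protocols
  set.seed(17)
  for (i in 1:15) {
    pr <- draw_admissible_protocol()
    if (pr$n < 2) next
    ip <- impulsive_protocol(pr$w_total / pr$n, pr$gamma, pr$n, pr$dur_off)
    win <- msl_production_windows(ip)
    peak_n <- max(msl_output(win$t_k + win$window, ip, pr$beta))
    pp <- circuit_params(alpha = 1, beta = pr$beta, gamma = pr$gamma)
    expect_gte(peak_n, as.numeric(massed_peak(pp, pr$w_total)) - 1e-9)
  }
})

test_that("impulsive memory approximates the habituation circuit in its regime", {
  # short saturating pulses, memory far from saturation
  p <- circuit_params(alpha = 1.5, beta = 5, gamma = 0.01, lambda = 1,
                      mu = 1)
  sched <- pulse_train(10, dur_on = 1, dur_off = 10, amplitude = 100)
  traj <- simulate_protocol("habituation", p, sched)
  period <- sched$dur_on + sched$dur_off
  ip <- impulsive_protocol(p$alpha * sched$dur_on, p$gamma,
                           sched$n_pulses, period)
  # compare just after each pulse: ODE at the k-th pulse offset vs the
  # pulse sum at its k-th jump
  for (k in seq_len(sched$n_pulses)) {
    t_ode <- (k - 1) * period + sched$dur_on
    i_ode <- traj$I[which.min(abs(traj$time - t_ode))]
    i_imp <- impulsive_memory(k * period, ip)
    expect_lt(abs(i_ode - i_imp) / i_imp, 0.05)
  }
})
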