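#' Kinetic parameters of a learning circuit
#'
#' Collects the nondimensional kinetic constants shared by the four circuit
#' models. Rates are per unit (dimensionless) time:
#'
#' * `alpha` — maximal expression rate of the memory species (I or A).
#' * `beta`  — maximal expression rate of the output reporter G.
#' * `gamma` — slow degradation-dilution rate of untagged (stable) proteins.
#' * `lambda` — fast degradation rate of tagged proteins (habituation,
#'   sensitization and hybrid circuits only; the massed-spaced circuit has
#'   no tagged species).
#' * `mu`    — maximal expression rate of the receptor X.
#' * `rho`   — maximal expression rate of the intermediate repressor R
#'   (sensitization and hybrid circuits only).
#' * `K_out` — half-activation constant of the output repressor curve in
#'   the hybrid circuit; raising it above 1 delays the switch from
#'   sensitization to habituation.
#'
#' The time-scale separation `lambda >> gamma` underpins the memory
#' mechanism: tagged species relax within a pulse period while the memory
#' species persists across pulses. `lambda < gamma` is rejected; a ratio
#' below 10 triggers a warning but remains runnable so that parameter
#' sweeps near the boundary are possible.
#'
#' @param alpha,beta,gamma,mu Positive rates (see above).
#' @param lambda Positive fast degradation rate, or `NULL` for circuits
#'   without tagged species.
#' @param rho Positive rate or `NULL`.
#' @param K_out Positive half-activation constant (default 1).
#' @return A `circuit_params` object.
#' @examples
#' circuit_params(alpha = 1.5, beta = 5, gamma = 0.01, lambda = 1, mu = 1)
#' @export
circuit_params <- function(alpha, beta, gamma, lambda = NULL, mu = 1,
                           rho = NULL, K_out = 1) {
  check_positive_scalar(alpha, "alpha")
  check_positive_scalar(beta, "beta")
  check_positive_scalar(gamma, "gamma")
  check_positive_scalar(mu, "mu")
  check_positive_scalar(K_out, "K_out")
  if (!is.null(lambda)) {
    check_positive_scalar(lambda, "lambda")
    if (lambda < gamma) {
      stop("`lambda` must be >= `gamma`: tagged proteins cannot be more ",
           "stable than untagged ones.", call. = FALSE)
    }
    if (lambda / gamma < 10) {
      warning("lambda / gamma < 10: weak time-scale separation; the memory ",
              "mechanism assumes lambda >> gamma.", call. = FALSE)
    }
  }
  if (!is.null(rho)) check_positive_scalar(rho, "rho")
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma, lambda = lambda,
         mu = mu, rho = rho, K_out = K_out),
    class = "circuit_params"
  )
}

#' @export
print.circuit_params <- function(x, ...) {
  vals <- unlist(Filter(Negate(is.null), unclass(x)))
  cat("<circuit_params> ",
      paste(names(vals), signif(vals, 6), sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

circuit_kinds <- c("habituation", "sensitization", "hybrid", "msl")

check_circuit <- function(circuit) {
  if (!is.character(circuit) || length(circuit) != 1L ||
      !circuit %in% circuit_kinds) {
    stop("`circuit` must be one of: ",
         paste(circuit_kinds, collapse = ", "), call. = FALSE)
  }
  circuit
}

#' State variable names of a circuit
#'
#' @param circuit Circuit kind.
#' @return Character vector of species labels in state-vector order.
#' @export
circuit_species <- function(circuit) {
  switch(check_circuit(circuit),
         habituation = c("X", "I", "G"),
         sensitization = c("X", "I", "R", "G"),
         hybrid = c("X", "I", "R", "G"),
         msl = c("X", "A", "G"))
}

check_params_for <- function(circuit, params) {
  stopifnot(inherits(params, "circuit_params"))
  needs_lambda <- circuit != "msl"
  if (needs_lambda && is.null(params$lambda)) {
    stop(sprintf("circuit '%s' requires `lambda`.", circuit), call. = FALSE)
  }
  if (circuit %in% c("sensitization", "hybrid") && is.null(params$rho)) {
    stop(sprintf("circuit '%s' requires `rho`.", circuit), call. = FALSE)
  }
  invisible(params)
}

check_state <- function(s, circuit) {
  sp <- circuit_species(circuit)
  if (!is.numeric(s) || length(s) != length(sp)) {
    stop(sprintf("state must be numeric of length %d (%s).",
                 length(sp), paste(sp, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("state components must be finite and >= 0.", call. = FALSE)
  }
  s
}

# Ligand-bound receptor complex: instantaneous mass-action product of free
# receptor and input with unit association constant, so the complex level
# driving the activating promoters is X * x.
complex_level <- function(X, x) X * x

#' Circuit right-hand sides
#'
#' Time derivatives of the four circuit models, evaluated at a state and an
#' instantaneous input level. States are named numeric vectors in the order
#' given by [circuit_species()].
#'
#' * Habituation (incoherent feed-forward loop, species X, I, G):
#'   `dX = mu - lambda X`, `dI = alpha theta+(X x) - gamma I`,
#'   `dG = beta theta+(X x) theta-(I) - lambda G`.
#' * Sensitization (double-repression cascade, species X, I, R, G):
#'   `dX = mu theta-(R) - lambda X`, `dI = alpha theta+(X x) - gamma I`,
#'   `dR = rho theta-(I) - lambda R`, `dG = beta theta+(X x) - lambda G`.
#' * Hybrid (sensitization plus the habituation hybrid promoter): as
#'   sensitization but `dG = beta theta+(X x) theta-_K(I) - lambda G`,
#'   with the output repressor curve half-activation `K_out`.
#' * Massed-spaced (linear activator chain, species X, A, G; every species
#'   decays at the slow rate gamma): `dX = mu - gamma X`,
#'   `dA = alpha theta+(X x) - gamma A`, `dG = beta theta+(A) - gamma G`.
#'
#' @param s Nonnegative numeric state vector.
#' @param x Instantaneous input level (>= 0).
#' @param p A `circuit_params` object.
#' @return Named numeric vector of time derivatives.
#' @examples
#' p <- circuit_params(alpha = 1.5, beta = 5, gamma = 0.01, lambda = 1, mu = 1)
#' habituation_rhs(c(X = 1, I = 0, G = 0), x = 1, p)
#' @export
habituation_rhs <- function(s, x, p) {
  check_params_for("habituation", p)
  s <- check_state(s, "habituation")
  act <- theta_plus(complex_level(s[[1]], x))
  c(X = p$mu - p$lambda * s[[1]],
    I = p$alpha * act - p$gamma * s[[2]],
    G = p$beta * act * theta_minus(s[[2]]) - p$lambda * s[[3]])
}

#' @rdname habituation_rhs
#' @export
sensitization_rhs <- function(s, x, p) {
  check_params_for("sensitization", p)
  s <- check_state(s, "sensitization")
  act <- theta_plus(complex_level(s[[1]], x))
  c(X = p$mu * theta_minus(s[[3]]) - p$lambda * s[[1]],
    I = p$alpha * act - p$gamma * s[[2]],
    R = p$rho * theta_minus(s[[2]]) - p$lambda * s[[3]],
    G = p$beta * act - p$lambda * s[[4]])
}

#' @rdname habituation_rhs
#' @export
hybrid_rhs <- function(s, x, p) {
  check_params_for("hybrid", p)
  s <- check_state(s, "hybrid")
  act <- theta_plus(complex_level(s[[1]], x))
  c(X = p$mu * theta_minus(s[[3]]) - p$lambda * s[[1]],
    I = p$alpha * act - p$gamma * s[[2]],
    R = p$rho * theta_minus(s[[2]]) - p$lambda * s[[3]],
    G = p$beta * act * theta_minus(s[[2]], p$K_out) - p$lambda * s[[4]])
}

#' @rdname habituation_rhs
#' @export
msl_rhs <- function(s, x, p) {
  check_params_for("msl", p)
  s <- check_state(s, "msl")
  c(X = p$mu - p$gamma * s[[1]],
    A = p$alpha * theta_plus(complex_level(s[[1]], x)) - p$gamma * s[[2]],
    G = p$beta * theta_plus(s[[2]]) - p$gamma * s[[3]])
}

circuit_rhs <- function(circuit) {
  switch(circuit,
         habituation = habituation_rhs,
         sensitization = sensitization_rhs,
         hybrid = hybrid_rhs,
         msl = msl_rhs)
}

# Fast internal RHS used by the integrator: no validation, positional
# arguments, same math as the exported *_rhs functions.
circuit_rhs_fast <- function(circuit, p) {
  switch(circuit,
    habituation = function(s, x) {
      cx2 <- (s[1L] * x)^2
      act <- cx2 / (1 + cx2)
      c(p$mu - p$lambda * s[1L],
        p$alpha * act - p$gamma * s[2L],
        p$beta * act / (1 + s[2L]^2) - p$lambda * s[3L])
    },
    sensitization = function(s, x) {
      cx2 <- (s[1L] * x)^2
      act <- cx2 / (1 + cx2)
      c(p$mu / (1 + s[3L]^2) - p$lambda * s[1L],
        p$alpha * act - p$gamma * s[2L],
        p$rho / (1 + s[2L]^2) - p$lambda * s[3L],
        p$beta * act - p$lambda * s[4L])
    },
    hybrid = function(s, x) {
      cx2 <- (s[1L] * x)^2
      act <- cx2 / (1 + cx2)
      c(p$mu / (1 + s[3L]^2) - p$lambda * s[1L],
        p$alpha * act - p$gamma * s[2L],
        p$rho / (1 + s[2L]^2) - p$lambda * s[3L],
        p$beta * act / (1 + (s[2L] / p$K_out)^2) - p$lambda * s[4L])
    },
    msl = function(s, x) {
      cx2 <- (s[1L] * x)^2
      a2 <- s[2L]^2
      c(p$mu - p$gamma * s[1L],
        p$alpha * cx2 / (1 + cx2) - p$gamma * s[2L],
        p$beta * a2 / (1 + a2) - p$gamma * s[3L])
    })
}

#' Resting state of a circuit
#'
#' The no-input fixed point used as the initial condition of every
#' simulation, available in closed form for all four circuits:
#'
#' * habituation: `X = mu / lambda`, `I = 0`, `G = 0`;
#' * sensitization and hybrid: `I = 0`, `R = rho / lambda`,
#'   `X = (mu / lambda) theta-(rho / lambda)`, `G = 0`;
#' * massed-spaced: `X = mu / gamma`, `A = 0`, `G = 0`.
#'
#' @param circuit Circuit kind.
#' @param params A `circuit_params` object.
#' @return Named numeric state vector at which the zero-input RHS vanishes.
#' @examples
#' p <- circuit_params(alpha = 1.5, beta = 5, gamma = 0.01, lambda = 1,
#'                     mu = 1, rho = 1.75)
#' resting_state("sensitization", p)
#' @export
resting_state <- function(circuit, params) {
  circuit <- check_circuit(circuit)
  check_params_for(circuit, params)
  p <- params
  switch(circuit,
    habituation = c(X = p$mu / p$lambda, I = 0, G = 0),
    sensitization = ,
    hybrid = {
      R0 <- p$rho / p$lambda
      c(X = (p$mu / p$lambda) * theta_minus(R0), I = 0, R = R0, G = 0)
    },
    msl = c(X = p$mu / p$gamma, A = 0, G = 0))
}
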