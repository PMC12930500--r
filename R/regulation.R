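#' Promoter transfer functions
#'
#' Normalized Hill-type promoter responses used by every circuit in the
#' package. `theta_plus()` is the activating form
#' \eqn{\theta^+(c) = c^2 / (K^2 + c^2)} and `theta_minus()` the repressing
#' form \eqn{\theta^-(c) = 1 / (1 + (c/K)^2)}, where `K` is the
#' half-activation concentration. The Hill exponent is fixed at 2: every
#' circuit in this package uses squared Hill forms, so the exponent is not
#' exposed as a tuning knob.
#'
#' Both functions map nonnegative concentrations to the unit interval, equal
#' 1/2 at `c = K`, and are complementary for a common `K`:
#' `theta_plus(c, K) + theta_minus(c, K) == 1`.
#'
#' @param c Nonnegative dimensionless concentration (vectorized).
#' @param half_activation Half-activation constant `K` (> 0). Default 1,
#'   the normalized value used throughout the circuit models.
#' @return A numeric vector of promoter activities in `[0, 1]`.
#' @examples
#' theta_plus(1)            # 0.5 at half-activation
#' theta_minus(2)           # 1 / (1 + 4) = 0.2
#' theta_plus(3) + theta_minus(3)
#' @export
theta_plus <- function(c, half_activation = 1) {
  check_concentration(c)
  check_positive_scalar(half_activation, "half_activation")
  r2 <- (c / half_activation)^2
  r2 / (1 + r2)
}

#' @rdname theta_plus
#' @export
theta_minus <- function(c, half_activation = 1) {
  check_concentration(c)
  check_positive_scalar(half_activation, "half_activation")
  1 / (1 + (c / half_activation)^2)
}

#' Heaviside step function with H(0) = 1
#'
#' Unit step returning 0 for strictly negative arguments and 1 otherwise.
#' Note the convention at the origin: `heaviside(0)` is 1, matching the
#' gating used in the impulsive memory approximation (a pulse arriving
#' exactly at the evaluation time counts in full). Many numerical libraries
#' instead use H(0) = 1/2; this package deliberately does not.
#'
#' @param v Finite numeric vector.
#' @return Numeric vector of 0s and 1s.
#' @examples
#' heaviside(c(-2, 0, 3))   # 0 1 1
#' @export
heaviside <- function(v) {
  if (!is.numeric(v) || any(!is.finite(v))) {
    stop("`v` must be finite numeric (no NA/NaN/Inf).", call. = FALSE)
  }
  as.numeric(v >= 0)
}

check_concentration <- function(c) {
  if (!is.numeric(c) || any(is.na(c)) || any(c < 0)) {
    stop("concentrations must be numeric and >= 0.", call. = FALSE)
  }
  invisible(c)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number.", name),
         call. = FALSE)
  }
  invisible(x)
}
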