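#' Predator parameters with exponential learning curves
#'
#' Bundles the learning-curve parameters of a predator whose attack rate
#' `a` rises and whose handling time `h` falls with foraging experience
#' (cumulative prey consumed, `N`):
#' \deqn{a(N) = a_m - (a_m - a_0) e^{-l_a N}}
#' \deqn{h(N) = h_m + (h_0 - h_m) e^{-l_h N}}
#' The distances \eqn{\Delta_a = a_m - a_0} and \eqn{\Delta_h = h_0 - h_m}
#' are the learning amplitudes; if an amplitude or its learning rate is
#' zero that channel does not learn and the model collapses to the Holling
#' type II disk equation.
#'
#' @param a0 initial attack rate (per time per unit prey density),
#'   `0 < a0 <= am`.
#' @param am asymptotic (maximum) attack rate, `am <= 1`.
#' @param la learning rate of the attack rate per consumed prey, in
#'   `[0, 1]`.
#' @param h0 initial handling time (time per prey), `h0 >= hm`.
#' @param hm asymptotic (minimum) handling time, `hm >= 0`.
#' @param lh learning rate of the handling time per consumed prey, in
#'   `[0, 1]`.
#'
#' @return An object of class `fr_predator`: a list with components
#'   `a0`, `am`, `la`, `h0`, `hm`, `lh`.
#' @examples
#' p <- fr_predator(a0 = 0.2, am = 1, la = 0.5, h0 = 0.1, hm = 0.1, lh = 0)
#' attack_rate(p, 0:5)
#' @export
fr_predator <- function(a0, am = 1, la = 0, h0 = 1, hm = h0, lh = 0) {
  for (nm in c("a0", "am", "la", "h0", "hm", "lh")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (a0 <= 0) stop("'a0' must be > 0", call. = FALSE)
  if (a0 > am) stop("'a0' must not exceed 'am'", call. = FALSE)
  if (am > 1) stop("'am' must be <= 1", call. = FALSE)
  if (la < 0 || la > 1) stop("'la' must be in [0, 1]", call. = FALSE)
  if (hm < 0) stop("'hm' must be >= 0", call. = FALSE)
  if (hm > h0) stop("'hm' must not exceed 'h0'", call. = FALSE)
  if (lh < 0 || lh > 1) stop("'lh' must be in [0, 1]", call. = FALSE)
  structure(list(a0 = a0, am = am, la = la, h0 = h0, hm = hm, lh = lh),
            class = "fr_predator")
}

#' @export
print.fr_predator <- function(x, ...) {
  amp <- learning_amplitudes(x)
  cat("Predator with exponential learning curves\n")
  cat(sprintf("  attack rate : a0 = %g -> am = %g  (la = %g, amplitude %g)\n",
              x$a0, x$am, x$la, amp[["delta_a"]]))
  cat(sprintf("  handling    : h0 = %g -> hm = %g  (lh = %g, amplitude %g)\n",
              x$h0, x$hm, x$lh, amp[["delta_h"]]))
  if (amp[["delta_a"]] * x$la == 0 && amp[["delta_h"]] * x$lh == 0)
    cat("  no learning: reduces to the Holling type II disk equation\n")
  invisible(x)
}

#' Attack rate after a given foraging experience
#'
#' Evaluates the exponential learning curve
#' \eqn{a(N) = a_m - (a_m - a_0) e^{-l_a N}}: the attack rate rises
#' monotonically from `a0` at `N = 0` toward the asymptote `am`.
#'
#' @param p an [fr_predator] object.
#' @param n_consumed cumulative prey consumed (nonnegative; vectorised).
#' @return Attack rate(s) in `[a0, am]`.
#' @export
attack_rate <- function(p, n_consumed) {
  stopifnot(inherits(p, "fr_predator"))
  if (any(n_consumed < 0)) stop("'n_consumed' must be >= 0", call. = FALSE)
  p$am - (p$am - p$a0) * exp(-p$la * n_consumed)
}

#' Handling time after a given foraging experience
#'
#' Evaluates the exponential learning curve
#' \eqn{h(N) = h_m + (h_0 - h_m) e^{-l_h N}}: the handling time falls
#' monotonically from `h0` at `N = 0` toward the asymptote `hm`.
#'
#' @inheritParams attack_rate
#' @return Handling time(s) in `[hm, h0]`.
#' @export
handling_time <- function(p, n_consumed) {
  stopifnot(inherits(p, "fr_predator"))
  if (any(n_consumed < 0)) stop("'n_consumed' must be >= 0", call. = FALSE)
  p$hm + (p$h0 - p$hm) * exp(-p$lh * n_consumed)
}

#' Instantaneous Holling disk-equation intake rate
#'
#' Prey consumed per unit time at attack rate `a`, handling time `h` and
#' prey density `D`: \eqn{aD / (1 + ahD)}. Increasing in `D` and bounded
#' above by `1/h` when `h > 0`; linear (type I form) when `h = 0`.
#'
#' @param a attack rate, `> 0`.
#' @param h handling time, `>= 0`.
#' @param D prey density, `>= 0`. Vectorised over all three arguments.
#' @return Intake rate(s), nonnegative.
#' @export
intake_rate <- function(a, h, D) {
  if (any(a <= 0)) stop("'a' must be > 0", call. = FALSE)
  if (any(h < 0)) stop("'h' must be >= 0", call. = FALSE)
  if (any(D < 0)) stop("'D' must be >= 0", call. = FALSE)
  a * D / (1 + a * h * D)
}

#' Learning amplitudes of a predator
#'
#' The amplitudes \eqn{\Delta_a = a_m - a_0} and
#' \eqn{\Delta_h = h_0 - h_m} measure how much each parameter can improve.
#' Both zero means the predator cannot learn and its functional response
#' is the plain disk equation.
#'
#' @param p an [fr_predator] object.
#' @return Named numeric vector `c(delta_a, delta_h)`.
#' @export
learning_amplitudes <- function(p) {
  stopifnot(inherits(p, "fr_predator"))
  c(delta_a = p$am - p$a0, delta_h = p$h0 - p$hm)
}

#' Simulation settings for the consumption-learning dynamics
#'
#' @param t_max experiment length in time units (default 1).
#' @param dt fixed Runge-Kutta step (default 1/1024). `t_max` must be an
#'   integer multiple of `dt` (within 1e-12 relative) so the final step is
#'   never fractional.
#' @param depletion logical; `FALSE` holds prey density constant during
#'   the trial (Holling setting), `TRUE` removes consumed prey from a
#'   fixed pool without replacement (Rogers random-predator setting).
#' @return An object of class `fr_config` with components `t_max`, `dt`,
#'   `depletion` and the implied integer `n_steps`.
#' @export
fr_config <- function(t_max = 1, dt = 1 / 1024, depletion = FALSE) {
  if (!is.numeric(t_max) || length(t_max) != 1L || !is.finite(t_max) ||
      t_max <= 0)
    stop("'t_max' must be a single positive number", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0 ||
      dt > t_max)
    stop("'dt' must satisfy 0 < dt <= t_max", call. = FALSE)
  n_steps <- round(t_max / dt)
  if (abs(n_steps * dt - t_max) > 1e-12 * t_max)
    stop("'t_max' must be an integer multiple of 'dt'", call. = FALSE)
  if (!is.logical(depletion) || length(depletion) != 1L || is.na(depletion))
    stop("'depletion' must be TRUE or FALSE", call. = FALSE)
  structure(list(t_max = t_max, dt = dt, depletion = depletion,
                 n_steps = as.integer(n_steps)),
            class = "fr_config")
}

#' @export
print.fr_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: t_max = %g, dt = 1/%g (%d RK4 steps), %s\n",
    x$t_max, 1 / x$dt, x$n_steps,
    if (x$depletion) "prey depletion (Rogers)" else
      "constant density (Holling)"))
  invisible(x)
}
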