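#' Holling disk equation (closed form)
#'
#' Total prey consumed in a trial of length `T` at constant prey density
#' `D` with fixed attack rate `a` and handling time `h`:
#' \deqn{N = aDT / (1 + ahD)}
#' This is the no-learning limit of the simulator and the analytic oracle
#' for the constant-density integrator.
#'
#' @param a attack rate, `> 0`.
#' @param h handling time, `>= 0`.
#' @param D prey density, `>= 0` (vectorised).
#' @param T_ trial length, `> 0`.
#' @return Consumed prey (same length as `D`).
#' @export
holling_closed_form <- function(a, h, D, T_ = 1) {
  if (any(a <= 0)) stop("'a' must be > 0", call. = FALSE)
  if (any(h < 0)) stop("'h' must be >= 0", call. = FALSE)
  if (any(D < 0)) stop("'D' must be >= 0", call. = FALSE)
  if (any(T_ <= 0)) stop("'T_' must be > 0", call. = FALSE)
  a * D * T_ / (1 + a * h * D)
}

#' Rogers random-predator equation (implicit solution)
#'
#' Total prey consumed from a fixed pool of `N0` prey removed without
#' replacement, with fixed attack rate `a` and handling time `h`. The
#' consumption `N` satisfies the classic implicit equation
#' \deqn{N = N_0 (1 - e^{-a(T - hN)})}
#' solved here by bracketed root-finding on `[0, N0]`, polished by Newton
#' steps to `|f(N)| < 1e-12`. For `h = 0` the explicit form
#' `N0 (1 - exp(-aT))` is returned directly.
#'
#' @param a attack rate, `> 0`.
#' @param h handling time, `>= 0`.
#' @param N0 initial prey count, `>= 0` (vectorised).
#' @param T_ trial length, `> 0`.
#' @return Consumed prey in `[0, N0]` (same length as `N0`).
#' @export
rogers_closed_form <- function(a, h, N0, T_ = 1) {
  if (any(a <= 0)) stop("'a' must be > 0", call. = FALSE)
  if (any(h < 0)) stop("'h' must be >= 0", call. = FALSE)
  if (any(N0 < 0)) stop("'N0' must be >= 0", call. = FALSE)
  if (any(T_ <= 0)) stop("'T_' must be > 0", call. = FALSE)
  vapply(N0, function(n0) .rogers_one(a, h, n0, T_), numeric(1))
}

.rogers_one <- function(a, h, N0, T_) {
  if (N0 == 0) return(0)
  if (h == 0) return(N0 * (1 - exp(-a * T_)))
  f <- function(N) N - N0 * (1 - exp(-a * (T_ - h * N)))
  # f(0) < 0 and f(N0) = N0 * exp(-a(T - h N0)) > 0: the root is bracketed
  root <- stats::uniroot(f, c(0, N0), tol = .Machine$double.eps^0.75)$root
  # Newton polish; fprime = 1 + N0 a h exp(-a(T - hN)) >= 1, so steps are safe
  for (i in 1:5) {
    fx <- f(root)
    if (abs(fx) < 1e-13) break
    fp <- 1 + N0 * a * h * exp(-a * (T_ - h * root))
    root <- root - fx / fp
  }
  if (abs(f(root)) >= 1e-12)
    stop("Rogers root-finding failed to converge", call. = FALSE)
  root
}
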