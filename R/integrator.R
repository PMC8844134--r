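#' @useDynLib frlearn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Right-hand sides for the deSolve route. Two equivalent formulations:
# "substitution" integrates the single scalar ODE with a(N), h(N)
# substituted in closed form (the default; an exact consequence of the
# learning curves); "coupled" evolves a and h as extra state variables via
# da/dN = +la (am - a), dh/dN = -lh (h - hm) chain-ruled through dN/dt,
# and is kept as a cross-check on the sign convention.
.rhs_fixed_subst <- function(t, y, parms) {
  a <- attack_rate(parms$p, y[[1L]])
  h <- handling_time(parms$p, y[[1L]])
  list(a * parms$D / (1 + a * h * parms$D))
}

.rhs_fixed_coupled <- function(t, y, parms) {
  p <- parms$p
  dN <- y[["a"]] * parms$D / (1 + y[["a"]] * y[["h"]] * parms$D)
  list(c(dN,
         p$la * (p$am - y[["a"]]) * dN,
         -p$lh * (y[["h"]] - p$hm) * dN))
}

.rhs_depl_subst <- function(t, y, parms) {
  Na <- max(y[[1L]], 0)
  N <- parms$N0 - Na
  a <- attack_rate(parms$p, N)
  h <- handling_time(parms$p, N)
  list(-a * Na / (1 + a * h * Na))
}

.rhs_depl_coupled <- function(t, y, parms) {
  p <- parms$p
  Na <- max(y[["Na"]], 0)
  dNa <- -y[["a"]] * Na / (1 + y[["a"]] * y[["h"]] * Na)
  list(c(dNa,
         -p$la * (p$am - y[["a"]]) * dNa,
         p$lh * (y[["h"]] - p$hm) * dNa))
}

.check_finite <- function(out) {
  bad <- which(!is.finite(out))
  if (length(bad)) {
    row <- ((bad[1L] - 1L) %% nrow(out)) + 1L
    stop("non-finite state at integration step ", row - 1L, call. = FALSE)
  }
}

.trajectory <- function(df) structure(df, class = c("fr_trajectory",
                                                    "data.frame"))

#' Simulate consumption at constant prey density (Holling setting)
#'
#' Integrates the cumulative consumed prey \eqn{N(t)} under
#' \deqn{dN/dt = a(N) D / (1 + a(N) h(N) D)}
#' by fixed-step fourth-order Runge-Kutta, with the learning curves
#' `a(N)`, `h(N)` evaluated at every internal Runge-Kutta stage. Prey
#' density `D` is held constant throughout the trial (consumed prey do
#' not deplete the arena).
#'
#' @param p an [fr_predator] object.
#' @param D prey density, `>= 0`.
#' @param cfg an [fr_config] with `depletion = FALSE`.
#' @param formulation `"substitution"` (default) substitutes the
#'   closed-form learning curves into a single scalar ODE; `"coupled"`
#'   evolves `a` and `h` as additional state variables (cross-check).
#' @return An `fr_trajectory` data frame with columns `t`, `n_consumed`,
#'   `a`, `h`. The final `n_consumed` is the headline output.
#' @examples
#' p <- fr_predator(a0 = 0.1, am = 0.1, h0 = 0.1, hm = 0.1)
#' tail(simulate_fixed_density(p, D = 100, fr_config()), 1)  # = 5 (Eq. oracle)
#' @export
simulate_fixed_density <- function(p, D, cfg = fr_config(),
                                   formulation = c("substitution",
                                                   "coupled")) {
  stopifnot(inherits(p, "fr_predator"), inherits(cfg, "fr_config"))
  formulation <- match.arg(formulation)
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D < 0)
    stop("'D' must be a single nonnegative number", call. = FALSE)
  if (cfg$depletion)
    stop("constant-density simulation requires a config with ",
         "depletion = FALSE", call. = FALSE)
  times <- seq(0, by = cfg$dt, length.out = cfg$n_steps + 1L)
  parms <- list(p = p, D = D)
  if (formulation == "substitution") {
    out <- deSolve::rk4(c(N = 0), times, .rhs_fixed_subst, parms)
    .check_finite(out)
    n <- out[, "N"]
  } else {
    y0 <- c(N = 0, a = p$a0, h = p$h0)
    out <- deSolve::rk4(y0, times, .rhs_fixed_coupled, parms)
    .check_finite(out)
    n <- out[, "N"]
  }
  .trajectory(data.frame(t = times, n_consumed = n,
                         a = attack_rate(p, n), h = handling_time(p, n)))
}

#' Simulate consumption with prey depletion (Rogers setting)
#'
#' Integrates the available prey \eqn{N_a(t)} under
#' \deqn{dN_a/dt = -a(N) N_a / (1 + a(N) h(N) N_a), \quad N = N_0 - N_a}
#' by fixed-step fourth-order Runge-Kutta: prey form a fixed pool of `N0`
#' individuals removed without replacement, so learning opportunities
#' shrink as the arena empties.
#'
#' @param p an [fr_predator] object.
#' @param N0 initial prey count, `>= 0`.
#' @param cfg an [fr_config] with `depletion = TRUE`.
#' @inheritParams simulate_fixed_density
#' @return An `fr_trajectory` data frame with columns `t`, `n_consumed`,
#'   `a`, `h`, `n_available`.
#' @export
simulate_depletion <- function(p, N0, cfg = fr_config(depletion = TRUE),
                               formulation = c("substitution", "coupled")) {
  stopifnot(inherits(p, "fr_predator"), inherits(cfg, "fr_config"))
  formulation <- match.arg(formulation)
  if (!is.numeric(N0) || length(N0) != 1L || !is.finite(N0) || N0 < 0)
    stop("'N0' must be a single nonnegative number", call. = FALSE)
  if (!cfg$depletion)
    stop("depletion simulation requires a config with depletion = TRUE",
         call. = FALSE)
  times <- seq(0, by = cfg$dt, length.out = cfg$n_steps + 1L)
  parms <- list(p = p, N0 = N0)
  if (formulation == "substitution") {
    out <- deSolve::rk4(c(Na = N0), times, .rhs_depl_subst, parms)
  } else {
    out <- deSolve::rk4(c(Na = N0, a = p$a0, h = p$h0), times,
                        .rhs_depl_coupled, parms)
  }
  .check_finite(out)
  na <- out[, "Na"]
  bad <- which(na < -1e-9)
  if (length(bad))
    stop("available prey fell below zero at integration step ",
         bad[1L] - 1L, call. = FALSE)
  na <- pmax(na, 0)
  n <- N0 - na
  .trajectory(data.frame(t = times, n_consumed = n,
                         a = attack_rate(p, n), h = handling_time(p, n),
                         n_available = na))
}

#' Functional response curve over a grid of offered prey
#'
#' Runs one independent trial per offered value — prey density in the
#' constant-density (Holling) setting, initial prey count in the
#' depletion (Rogers) setting, per `cfg$depletion` — and returns total
#' prey consumed aligned with the grid. The grid must be uniformly spaced
#' (the downstream finite-difference scheme requires it) and have at
#' least 7 points.
#'
#' @param p an [fr_predator] object.
#' @param offered uniformly spaced, strictly increasing numeric grid of
#'   prey densities (or initial prey counts), length `>= 7`.
#' @param cfg an [fr_config]; its `depletion` flag selects the setting.
#' @param engine `"compiled"` (default) uses the vectorised Runge-Kutta
#'   kernel; `"desolve"` runs one deSolve integration per grid value
#'   (identical scheme, used for cross-checking).
#' @return An [fr_curve] object.
#' @examples
#' p <- fr_predator(a0 = 0.2, am = 1, la = 0.2, h0 = 0.1, hm = 0.1)
#' rc <- response_curve(p, seq(1, 200, by = 1), fr_config())
#' classify_response(finite_differences(rc))
#' @export
response_curve <- function(p, offered, cfg = fr_config(),
                           engine = c("compiled", "desolve")) {
  stopifnot(inherits(p, "fr_predator"), inherits(cfg, "fr_config"))
  engine <- match.arg(engine)
  .check_offered_grid(offered)
  if (engine == "compiled") {
    consumed <- .rk4_consumed_grid(p$a0, p$am, p$la, p$h0, p$hm, p$lh,
                                   offered, cfg$dt, cfg$n_steps,
                                   cfg$depletion)
  } else {
    consumed <- vapply(offered, function(x) {
      tr <- if (cfg$depletion) simulate_depletion(p, x, cfg)
            else simulate_fixed_density(p, x, cfg)
      tr$n_consumed[nrow(tr)]
    }, numeric(1))
  }
  fr_curve(offered, consumed, depletion = cfg$depletion)
}

.check_offered_grid <- function(offered) {
  if (!is.numeric(offered) || length(offered) < 7L)
    stop("'offered' must be a numeric grid of length >= 7", call. = FALSE)
  d <- diff(offered)
  if (any(d <= 0))
    stop("'offered' must be strictly increasing", call. = FALSE)
  if (max(abs(d - d[1L])) > 1e-9 * abs(d[1L]))
    stop("'offered' must be uniformly spaced", call. = FALSE)
  invisible(TRUE)
}

#' Response-curve container
#'
#' Holds total prey consumed as a function of prey offered on a uniform
#' grid — the per-trial functional response. Constructed by
#' [response_curve()] or directly from tabulated (offered, consumed)
#' data, e.g. an empirical curve read from CSV.
#'
#' @param offered uniform, strictly increasing grid (length >= 7).
#' @param consumed consumed prey aligned with `offered`; finite, `>= 0`.
#' @param depletion logical label: was the trial run with prey depletion?
#'   (Affects labelling only.)
#' @return An object of class `fr_curve`: a data frame with columns
#'   `offered` and `consumed`, plus a `depletion` attribute.
#' @export
fr_curve <- function(offered, consumed, depletion = FALSE) {
  .check_offered_grid(offered)
  if (length(consumed) != length(offered))
    stop("'offered' and 'consumed' must have equal length", call. = FALSE)
  if (any(!is.finite(consumed)) || any(consumed < 0))
    stop("'consumed' must be finite and >= 0", call. = FALSE)
  structure(data.frame(offered = as.numeric(offered),
                       consumed = as.numeric(consumed)),
            depletion = isTRUE(depletion),
            class = c("fr_curve", "data.frame"))
}

#' @export
print.fr_curve <- function(x, ...) {
  cat(sprintf(
    "Functional response curve (%s): %d offered values in [%g, %g], ",
    if (attr(x, "depletion")) "prey depletion" else "constant density",
    nrow(x), x$offered[1L], x$offered[nrow(x)]))
  cat(sprintf("consumed in [%g, %g]\n", min(x$consumed), max(x$consumed)))
  invisible(x)
}
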