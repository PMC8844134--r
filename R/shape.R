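#' Finite-difference derivative profile of a response curve
#'
#' Second-order central differences on the uniform offered grid:
#' \deqn{d1_i = (y_{i+1} - y_{i-1}) / (2\Delta), \quad
#'       d2_i = (y_{i+1} - 2 y_i + y_{i-1}) / \Delta^2}
#' evaluated at interior points only. Alongside the raw derivatives, the
#' same scheme is applied to the curve after affinely rescaling offered
#' and consumed each to `[0, 1]`, giving a scale-free second derivative
#' used by the shape classifier (the raw one is what the curvature maps
#' report). Curves from the integrator are noiseless, so no smoothing is
#' applied; see [smooth_curve()] for empirical data.
#'
#' @param curve an [fr_curve].
#' @return An object of class `fr_derivatives`: a list with `offered`
#'   (interior grid), `d1`, `d2`, `normalized_d2`, and the `offered` /
#'   `consumed` ranges used for rescaling.
#' @export
finite_differences <- function(curve) {
  stopifnot(inherits(curve, "fr_curve"))
  x <- curve$offered
  y <- curve$consumed
  n <- length(x)
  delta <- x[2L] - x[1L]
  i <- 2L:(n - 1L)
  d1 <- (y[i + 1L] - y[i - 1L]) / (2 * delta)
  d2 <- (y[i + 1L] - 2 * y[i] + y[i - 1L]) / delta^2
  # rescaled curve: x' in [0,1], y' in [0,1]; for a constant curve the
  # consumed range is 0 and the rescaled curve is identically 0
  rx <- x[n] - x[1L]
  ry <- max(y) - min(y)
  g <- if (ry > 0) d2 * rx^2 / ry else rep(0, length(d2))
  structure(list(offered = x[i], d1 = d1, d2 = d2, normalized_d2 = g,
                 offered_range = rx, consumed_range = ry),
            class = "fr_derivatives")
}

#' @export
print.fr_derivatives <- function(x, ...) {
  cat(sprintf(
    "Derivative profile: %d interior points; max d2 = %.4g, max normalized d2 = %.4g\n",
    length(x$offered), max(x$d2), max(x$normalized_d2)))
  invisible(x)
}

#' Moving-average smoother for empirical response curves
#'
#' Centered moving average of the consumed values over an odd window;
#' endpoints where the window does not fit keep their original values.
#' Intended for user-supplied (noisy) curves — simulated curves are
#' noiseless and are classified unsmoothed.
#'
#' @param curve an [fr_curve].
#' @param window odd integer window width, `>= 3`.
#' @return A smoothed [fr_curve] on the same grid.
#' @export
smooth_curve <- function(curve, window = 5L) {
  stopifnot(inherits(curve, "fr_curve"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("'window' must be an odd integer >= 3", call. = FALSE)
  if (window >= nrow(curve))
    stop("'window' must be smaller than the curve length", call. = FALSE)
  sm <- stats::filter(curve$consumed, rep(1 / window, window), sides = 2)
  sm <- as.numeric(sm)
  keep <- is.na(sm)
  sm[keep] <- curve$consumed[keep]
  fr_curve(curve$offered, pmax(sm, 0), depletion = attr(curve, "depletion"))
}

#' Locate the inflection point of a response curve
#'
#' Finds the first persistent positive-to-negative sign change of the
#' second derivative — the type III diagnostic: convex (accelerating)
#' below the inflection, concave (handling-limited) above it. A change is
#' persistent when the second derivative is strictly positive for at
#' least `k` consecutive points before the crossing and strictly negative
#' for at least `k` after it; this suppresses single-point sign flips
#' from floating-point noise. The crossing location is linearly
#' interpolated between the bracketing grid points. If several persistent
#' crossings exist the first (lowest offered value) is reported.
#'
#' @param profile an `fr_derivatives` object from [finite_differences()].
#' @param k persistence requirement in grid points (default 5).
#' @return The offered value of the inflection, or `NA_real_` when no
#'   persistent crossing exists (a valid result: the type II signature).
#' @export
find_inflection <- function(profile, k = 5L) {
  stopifnot(inherits(profile, "fr_derivatives"))
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1", call. = FALSE)
  g <- profile$d2
  x <- profile$offered
  n <- length(g)
  if (n < 2L) return(NA_real_)
  # run length of g > 0 ending at i, and of g < 0 starting at i
  pos_end <- integer(n)
  neg_start <- integer(n)
  pos_end[1L] <- as.integer(g[1L] > 0)
  for (i in 2:n)
    pos_end[i] <- if (g[i] > 0) pos_end[i - 1L] + 1L else 0L
  neg_start[n] <- as.integer(g[n] < 0)
  for (i in (n - 1L):1L)
    neg_start[i] <- if (g[i] < 0) neg_start[i + 1L] + 1L else 0L
  for (i in 1:(n - 1L)) {
    if (pos_end[i] < k) next
    j <- i + 1L
    while (j <= n && g[j] == 0) j <- j + 1L  # an exact zero at the crossing
    if (j > n || g[j] > 0 || neg_start[j] < k) next
    frac <- g[i] / (g[i] - g[j])
    return(x[i] + frac * (x[j] - x[i]))
  }
  NA_real_
}

#' Classify the shape of a functional response curve
#'
#' Decision procedure on the scale-free (normalized) second derivative
#' `g` of the response curve, reproducing the field's shape taxonomy:
#' type I (linear), type II (saturating, `g < 0` everywhere), type III
#' (sigmoid with a persistent positive-to-negative crossing of `g`), and
#' the intermediate near-type II / near-type I categories whose
#' second-derivative signatures are too small to be visually
#' distinguishable. In order:
#' 1. `max |g| < eps_lin` — TYPE_I;
#' 2. a persistent crossing exists and `max g >= eps_pos` — TYPE_III;
#' 3. a persistent crossing exists and `0 < max g < eps_pos` —
#'    NEAR_TYPE_II;
#' 4. `g <= 0` everywhere (within `eps_lin / 10`) and
#'    `min g < -eps_lin` — TYPE_II;
#' 5. otherwise (small-magnitude `g` turning positive at higher offered
#'    values without a type III signature) — NEAR_TYPE_I.
#'
#' The thresholds are calibration constants: the boundary between
#' "near-zero" and "noticeable" curvature is not sharp, so both are
#' exposed.
#'
#' @param profile an `fr_derivatives` object from [finite_differences()].
#' @param eps_lin linearity threshold on `|g|` (default 0.02).
#' @param eps_pos positive-curvature threshold on `max g` separating
#'   type III from near-type II (default 0.05); must exceed `eps_lin`.
#' @param k persistence requirement passed to [find_inflection()].
#' @return An object of class `fr_classification`: a list with `shape`
#'   (one of `"TYPE_I"`, `"NEAR_TYPE_I"`, `"TYPE_II"`, `"NEAR_TYPE_II"`,
#'   `"TYPE_III"`), `inflection_offered` (`NA` when absent), `max_d2`,
#'   `max_normalized_d2`, and the thresholds used.
#' @export
classify_response <- function(profile, eps_lin = 0.02, eps_pos = 0.05,
                              k = 5L) {
  stopifnot(inherits(profile, "fr_derivatives"))
  if (!is.numeric(eps_lin) || eps_lin <= 0 || !is.numeric(eps_pos) ||
      eps_pos <= eps_lin)
    stop("thresholds must satisfy 0 < eps_lin < eps_pos", call. = FALSE)
  g <- profile$normalized_d2
  inflection <- find_inflection(profile, k = k)
  gmax <- max(g)
  shape <-
    if (max(abs(g)) < eps_lin) "TYPE_I"
    else if (!is.na(inflection) && gmax >= eps_pos) "TYPE_III"
    else if (!is.na(inflection) && gmax > 0) "NEAR_TYPE_II"
    else if (all(g <= eps_lin / 10) && min(g) < -eps_lin) "TYPE_II"
    else "NEAR_TYPE_I"
  structure(list(shape = shape,
                 inflection_offered = inflection,
                 max_d2 = max(profile$d2),
                 max_normalized_d2 = gmax,
                 eps_lin = eps_lin, eps_pos = eps_pos, k = as.integer(k)),
            class = "fr_classification")
}

#' @export
print.fr_classification <- function(x, ...) {
  cat("Functional response shape:", x$shape, "\n")
  if (!is.na(x$inflection_offered))
    cat(sprintf("  inflection at offered = %.4g\n", x$inflection_offered))
  cat(sprintf("  max d2 = %.4g (raw), %.4g (normalized)\n",
              x$max_d2, x$max_normalized_d2))
  invisible(x)
}

#' One-call shape classification of a response curve
#'
#' Convenience wrapper: [finite_differences()] then [classify_response()].
#'
#' @param curve an [fr_curve].
#' @inheritParams classify_response
#' @return An `fr_classification` object.
#' @export
classify_curve <- function(curve, eps_lin = 0.02, eps_pos = 0.05, k = 5L) {
  classify_response(finite_differences(curve), eps_lin = eps_lin,
                    eps_pos = eps_pos, k = k)
}
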