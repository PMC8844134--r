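#' Uniform grid specification for parameter sweeps
#'
#' @param name axis name (e.g. `"a0"`, `"la"`, `"hm"`, `"lh"`).
#' @param min,max range endpoints, `min < max` (or `min == max` with
#'   `n = 1`).
#' @param n number of uniformly spaced points, endpoints included.
#' @return An object of class `fr_grid` with a `values` component.
#' @export
fr_grid <- function(name, min, max, n) {
  n <- as.integer(n)
  if (!is.character(name) || length(name) != 1L)
    stop("'name' must be a single string", call. = FALSE)
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  if (n == 1L) {
    if (min != max) stop("n = 1 requires min == max", call. = FALSE)
    values <- min
  } else {
    if (!(min < max)) stop("'min' must be < 'max'", call. = FALSE)
    values <- seq(min, max, length.out = n)
  }
  structure(list(name = name, min = min, max = max, n = n,
                 values = values),
            class = "fr_grid")
}

.default_offered <- function(step = 0.01) seq(1, 200, by = step)

.sweep_cells <- function(xg, yg, make_predator, cfg, offered, eps_lin,
                        eps_pos, k) {
  grid <- expand.grid(x = xg$values, y = yg$values,
                      KEEP.OUT.ATTRS = FALSE)
  n_cell <- nrow(grid)
  shape <- character(n_cell)
  inflection <- max_d2 <- max_g <- consumed_max <- numeric(n_cell)
  for (i in seq_len(n_cell)) {
    xi <- grid$x[i]; yi <- grid$y[i]
    res <- tryCatch({
      p <- make_predator(xi, yi)
      curve <- response_curve(p, offered, cfg)
      prof <- finite_differences(curve)
      cls <- classify_response(prof, eps_lin = eps_lin,
                               eps_pos = eps_pos, k = k)
      list(cls = cls, cmax = curve$consumed[nrow(curve)])
    }, error = function(e) {
      stop(sprintf("sweep cell (%s = %g, %s = %g) failed: %s",
                   xg$name, xi, yg$name, yi, conditionMessage(e)),
           call. = FALSE)
    })
    shape[i] <- res$cls$shape
    inflection[i] <- res$cls$inflection_offered
    max_d2[i] <- res$cls$max_d2
    max_g[i] <- res$cls$max_normalized_d2
    consumed_max[i] <- res$cmax
  }
  data.frame(x = grid$x, y = grid$y, shape = shape,
             inflection_offered = inflection, max_d2 = max_d2,
             max_normalized_d2 = max_g, consumed_max = consumed_max)
}

.fr_sweep <- function(cells, xg, yg, fixed, cfg, offered, eps_lin,
                      eps_pos, k, mode) {
  structure(list(
    x = xg$values, y = yg$values,
    x_name = xg$name, y_name = yg$name,
    cells = cells,
    metadata = list(mode = mode, fixed = fixed,
                    t_max = cfg$t_max, dt = cfg$dt,
                    depletion = cfg$depletion,
                    offered_min = offered[1L],
                    offered_max = offered[length(offered)],
                    offered_step = offered[2L] - offered[1L],
                    eps_lin = eps_lin, eps_pos = eps_pos, k = k)),
    class = "fr_sweep")
}

#' @export
print.fr_sweep <- function(x, ...) {
  cat(sprintf("Parameter sweep (%s): %d x %d cells over %s x %s, %s\n",
              x$metadata$mode, length(x$x), length(x$y), x$x_name,
              x$y_name,
              if (x$metadata$depletion) "prey depletion (Rogers)"
              else "constant density (Holling)"))
  print(table(shape = x$cells$shape))
  invisible(x)
}

#' Sweep attack-rate learning parameters
#'
#' Maps functional-response shape over the (initial attack rate `a0`,
#' attack learning rate `la`) plane with the handling channel frozen:
#' each cell builds a predator with `am = 1`, `h0 = hm = fixed_h`,
#' `lh = 0`, simulates its response curve over the offered grid, and
#' classifies the shape.
#'
#' @param a0_grid,la_grid [fr_grid] specifications for the two axes.
#' @param fixed_h constant handling time, `>= 0` (default 0.1).
#' @param cfg an [fr_config]; `cfg$depletion` selects the Holling or
#'   Rogers variant of the sweep.
#' @param offered offered-prey grid (default 1 to 200; the `step`
#'   controls resolution — classification is grid-stable away from
#'   region boundaries, so coarse steps are adequate for maps).
#' @param eps_lin,eps_pos,k classifier settings, see
#'   [classify_response()].
#' @return An `fr_sweep` object; `$cells` is a long-format data frame
#'   with one row per `(a0, la)` cell.
#' @export
sweep_attack_learning <- function(a0_grid, la_grid, fixed_h = 0.1,
                                  cfg = fr_config(),
                                  offered = .default_offered(0.5),
                                  eps_lin = 0.02, eps_pos = 0.05,
                                  k = 5L) {
  stopifnot(inherits(a0_grid, "fr_grid"), inherits(la_grid, "fr_grid"))
  if (fixed_h < 0) stop("'fixed_h' must be >= 0", call. = FALSE)
  cells <- .sweep_cells(
    a0_grid, la_grid,
    function(a0, la) fr_predator(a0 = a0, am = 1, la = la,
                                 h0 = fixed_h, hm = fixed_h, lh = 0),
    cfg, offered, eps_lin, eps_pos, k)
  .fr_sweep(cells, a0_grid, la_grid,
            fixed = list(am = 1, h = fixed_h, lh = 0),
            cfg, offered, eps_lin, eps_pos, k, mode = "attack")
}

#' Sweep handling-time learning parameters
#'
#' Maps functional-response shape over the (minimum handling time `hm`,
#' handling learning rate `lh`) plane with the attack channel frozen:
#' each cell builds a predator with `a0 = am = fixed_a`, `la = 0`,
#' `h0 = 1`, simulates its response curve, and classifies the shape.
#'
#' @param hm_grid,lh_grid [fr_grid] specifications for the two axes.
#' @param fixed_a constant attack rate in `(0, 1]` (default 0.1).
#' @inheritParams sweep_attack_learning
#' @return An `fr_sweep` object; `$cells` has one row per `(hm, lh)`
#'   cell.
#' @export
sweep_handling_learning <- function(hm_grid, lh_grid, fixed_a = 0.1,
                                    cfg = fr_config(),
                                    offered = .default_offered(0.5),
                                    eps_lin = 0.02, eps_pos = 0.05,
                                    k = 5L) {
  stopifnot(inherits(hm_grid, "fr_grid"), inherits(lh_grid, "fr_grid"))
  if (fixed_a <= 0 || fixed_a > 1)
    stop("'fixed_a' must be in (0, 1]", call. = FALSE)
  cells <- .sweep_cells(
    hm_grid, lh_grid,
    function(hm, lh) fr_predator(a0 = fixed_a, am = fixed_a, la = 0,
                                 h0 = 1, hm = hm, lh = lh),
    cfg, offered, eps_lin, eps_pos, k)
  .fr_sweep(cells, hm_grid, lh_grid,
            fixed = list(a = fixed_a, la = 0, h0 = 1),
            cfg, offered, eps_lin, eps_pos, k, mode = "handling")
}

#' Scan one parameter axis for a shape-class boundary
#'
#' Classifies the response curve at each value of a one-parameter scan
#' and reports the smallest (default) or largest value whose shape
#' equals `predicate`. Operationalizes boundary statements like "type
#' III appears for initial attack rates below some a0* at this learning
#' rate".
#'
#' @param values numeric vector of axis values, scanned in order.
#' @param make_predator function of one axis value returning an
#'   [fr_predator].
#' @param predicate target shape class, one of the five classifier
#'   labels.
#' @param cfg an [fr_config].
#' @param offered offered-prey grid.
#' @param largest if `TRUE`, report the largest matching value instead
#'   of the smallest.
#' @inheritParams sweep_attack_learning
#' @return A list with `value` (the boundary axis value, or `NA` if the
#'   predicate class never occurs), `found` (logical), and `shapes` (the
#'   classification at every scanned value).
#' @export
threshold_scan <- function(values, make_predator, predicate,
                           cfg = fr_config(),
                           offered = .default_offered(0.5),
                           largest = FALSE, eps_lin = 0.02,
                           eps_pos = 0.05, k = 5L) {
  stopifnot(is.numeric(values), is.function(make_predator))
  shapes <- vapply(values, function(v) {
    classify_curve(response_curve(make_predator(v), offered, cfg),
                   eps_lin = eps_lin, eps_pos = eps_pos, k = k)$shape
  }, character(1))
  hits <- which(shapes == predicate)
  if (!length(hits))
    return(list(value = NA_real_, found = FALSE, shapes = shapes))
  idx <- if (largest) max(hits) else min(hits)
  list(value = values[idx], found = TRUE, shapes = shapes)
}
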