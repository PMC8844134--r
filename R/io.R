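# CSV dialect: comma-separated, '.' decimal, header row, no index
# column, LF line endings; numbers at 17 significant digits so values
# round-trip bit-for-bit.
.fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
}

.write_csv17 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], .fmt_num)
  con <- file(path, open = "wb")  # binary: LF endings on every platform
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con, sep = "\n")
  lines <- do.call(paste, c(unname(as.list(out)), sep = ","))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Write a response curve to CSV
#'
#' Columns `offered,consumed`; deterministic, byte-identical output for
#' identical input.
#'
#' @param curve an [fr_curve].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "fr_curve"))
  .write_csv17(as.data.frame(curve), path)
  invisible(path)
}

#' Read a response curve from CSV
#'
#' Expects columns `offered` and `consumed`; the grid must be uniform,
#' strictly increasing and of length >= 7 (validated by [fr_curve()]).
#'
#' @param path CSV file path.
#' @param depletion logical label attached to the curve.
#' @return An [fr_curve].
#' @export
read_curve_csv <- function(path, depletion = FALSE) {
  df <- utils::read.csv(path)
  if (!all(c("offered", "consumed") %in% names(df)))
    stop("curve CSV must have columns 'offered' and 'consumed'",
         call. = FALSE)
  fr_curve(df$offered, df$consumed, depletion = depletion)
}

#' Write a trajectory to CSV
#'
#' @param trajectory an `fr_trajectory` from [simulate_fixed_density()]
#'   or [simulate_depletion()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "fr_trajectory"))
  .write_csv17(as.data.frame(trajectory), path)
  invisible(path)
}

#' Write a shape classification to JSON
#'
#' Keys: `shape`, `inflection_offered` (null when absent), `max_d2`,
#' `max_normalized_d2`, and the thresholds used.
#'
#' @param cls an `fr_classification` from [classify_response()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_classification_json <- function(cls, path) {
  stopifnot(inherits(cls, "fr_classification"))
  obj <- list(shape = cls$shape,
              inflection_offered =
                if (is.na(cls$inflection_offered)) NULL
                else cls$inflection_offered,
              max_d2 = cls$max_d2,
              max_normalized_d2 = cls$max_normalized_d2,
              thresholds = list(eps_lin = cls$eps_lin,
                                eps_pos = cls$eps_pos, k = cls$k))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write a parameter sweep to long-format CSV with a JSON sidecar
#'
#' The CSV has columns `x_name,y_name,x,y,shape,inflection_offered,
#' max_d2,max_normalized_d2`; the sidecar (`<path>.json`) records every
#' fixed parameter and simulation setting so the sweep can be re-run
#' identically.
#'
#' @param sweep an `fr_sweep`.
#' @param path output CSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "fr_sweep"))
  df <- data.frame(x_name = sweep$x_name, y_name = sweep$y_name,
                   x = sweep$cells$x, y = sweep$cells$y,
                   shape = sweep$cells$shape,
                   inflection_offered = sweep$cells$inflection_offered,
                   max_d2 = sweep$cells$max_d2,
                   max_normalized_d2 = sweep$cells$max_normalized_d2)
  .write_csv17(df, path)
  jsonlite::write_json(sweep$metadata, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a key = value configuration file
#'
#' Flat plain-text format: one `key = value` pair per line; blank lines
#' and lines starting with `#` are ignored. Values are parsed as
#' numbers where possible, `true`/`false` as logicals, anything else as
#' strings. Command-line flags override file values in the CLI.
#'
#' @param path configuration file path.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L)
      stop("malformed config line: '", ln, "'", call. = FALSE)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    parsed <- suppressWarnings(as.numeric(val))
    out[[key]] <-
      if (!is.na(parsed)) parsed
      else if (tolower(val) %in% c("true", "false"))
        tolower(val) == "true"
      else val
  }
  out
}

#' Simulate a response curve and write it to CSV
#'
#' High-level driver behind the `curve` CLI subcommand.
#'
#' @param a0,am,la,h0,hm,lh predator learning-curve parameters, see
#'   [fr_predator()].
#' @param t_max,dt,depletion simulation settings, see [fr_config()].
#' @param dmin,dmax,dstep offered-prey grid: `seq(dmin, dmax, by =
#'   dstep)`.
#' @param out output CSV path.
#' @param trajectory_out optional path: also write the full trajectory
#'   at the largest offered value.
#' @return The [fr_curve], invisibly.
#' @export
run_curve <- function(a0 = 0.1, am = 1, la = 0, h0 = 0.1, hm = h0,
                      lh = 0, t_max = 1, dt = 1 / 1024,
                      depletion = FALSE, dmin = 1, dmax = 200,
                      dstep = 0.01, out, trajectory_out = NULL) {
  p <- fr_predator(a0 = a0, am = am, la = la, h0 = h0, hm = hm, lh = lh)
  cfg <- fr_config(t_max = t_max, dt = dt, depletion = depletion)
  offered <- seq(dmin, dmax, by = dstep)
  curve <- response_curve(p, offered, cfg)
  write_curve_csv(curve, out)
  if (!is.null(trajectory_out)) {
    tr <- if (depletion) simulate_depletion(p, dmax, cfg)
          else simulate_fixed_density(p, dmax, cfg)
    write_trajectory_csv(tr, trajectory_out)
  }
  invisible(curve)
}

#' Classify a stored response curve and write the result to JSON
#'
#' High-level driver behind the `classify` CLI subcommand: reads a
#' curve CSV (simulated or empirical), optionally smooths it, and
#' writes the shape classification.
#'
#' @param path curve CSV path (columns `offered,consumed`).
#' @param out output JSON path.
#' @param eps_lin,eps_pos,k classifier settings, see
#'   [classify_response()].
#' @param smooth_window optional odd window for [smooth_curve()]
#'   (empirical curves only).
#' @return The `fr_classification`, invisibly.
#' @export
run_classify <- function(path, out, eps_lin = 0.02, eps_pos = 0.05,
                         k = 5L, smooth_window = NULL) {
  curve <- read_curve_csv(path)
  if (!is.null(smooth_window))
    curve <- smooth_curve(curve, smooth_window)
  cls <- classify_curve(curve, eps_lin = eps_lin, eps_pos = eps_pos,
                        k = k)
  write_classification_json(cls, out)
  invisible(cls)
}

#' Run a learning-parameter sweep and write it to CSV
#'
#' High-level driver behind the `sweep` CLI subcommand.
#'
#' @param mode `"attack"` sweeps `a0` x `la` with handling fixed;
#'   `"handling"` sweeps `hm` x `lh` with attack fixed.
#' @param nx,ny grid point counts for the two axes.
#' @param fixed_h constant handling time for attack sweeps.
#' @param fixed_a constant attack rate for handling sweeps.
#' @inheritParams run_curve
#' @inheritParams run_classify
#' @param out output CSV path (sidecar at `<out>.json`).
#' @return The `fr_sweep`, invisibly.
#' @export
run_sweep <- function(mode = c("attack", "handling"), nx = 101,
                      ny = 101, fixed_h = 0.1, fixed_a = 0.1,
                      t_max = 1, dt = 1 / 1024, depletion = FALSE,
                      dmin = 1, dmax = 200, dstep = 0.5,
                      eps_lin = 0.02, eps_pos = 0.05, k = 5L, out) {
  mode <- match.arg(mode)
  cfg <- fr_config(t_max = t_max, dt = dt, depletion = depletion)
  offered <- seq(dmin, dmax, by = dstep)
  sweep <- if (mode == "attack") {
    sweep_attack_learning(fr_grid("a0", 0.01, 1, nx),
                          fr_grid("la", 0, 1, ny),
                          fixed_h = fixed_h, cfg = cfg,
                          offered = offered, eps_lin = eps_lin,
                          eps_pos = eps_pos, k = k)
  } else {
    sweep_handling_learning(fr_grid("hm", 0, 0.1, nx),
                            fr_grid("lh", 0, 1, ny),
                            fixed_a = fixed_a, cfg = cfg,
                            offered = offered, eps_lin = eps_lin,
                            eps_pos = eps_pos, k = k)
  }
  write_sweep_csv(sweep, out)
  invisible(sweep)
}
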