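#' Default simulation configuration
#'
#' Returns the full parameter set of the biceps brachii reference simulation:
#' arm bounding box and tissue conductivities, electrode spacing, motor-unit
#' pool statistics, acetylcholine release constants, per-type muscle-fiber
#' parameter distributions, conduction-velocity range, neuromuscular-junction
#' placement, and the fixed membrane-model constants (A, B, alpha, C).
#'
#' Two scales are provided. `"desk"` (the default) keeps every per-fiber and
#' per-unit physiological distribution identical to `"full"` but shrinks the
#' population to ~2,000 fibers in ~50 motor units so that a complete
#' contraction simulates in minutes on one CPU; coefficients of variation of
#' the motor-unit size and count distributions are preserved. `"full"` is the
#' literature-scale population (200k fibers, 1000 +/- 250 motor units of
#' 300 +/- 100 fibers).
#'
#' @param scale `"desk"` or `"full"`.
#' @return nested list of class `semg_config`.
#' @export
default_config <- function(scale = c("desk", "full")) {
  scale <- match.arg(scale)
  cfg <- list(
    fs = 2000,
    scale = scale,
    table1 = list(
      arm = list(x = c(-50, 50), y = c(-50, 50), z = c(0, 150)),  # mm
      conductivity = c(air = 0, fat_skin = 4.07e-2, muscle = 0.30,
                       cortical_bone = 2.00e-2, cancellous_bone = 7.56e-2),  # S/m
      electrode_spacing_mm = 15,
      n_fib     = if (scale == "full") 200000L else 2000L,
      mu_size   = if (scale == "full") c(avg = 300, std = 100) else c(avg = 40, std = 40 / 3),
      mu_number = if (scale == "full") c(avg = 1000, std = 250) else c(avg = 50, std = 12.5),
      R_range      = c(4, 40),   # dispersion radius, % of muscle cross-section area
      lambda_range = c(20, 50),  # dispersion std, % of R
      ach = list(Am = 1, kr = 0.45, kd = 30),  # mM, s^-1, s^-1
      fiber = list(
        I   = list(r = c(20, 5),     sigma_ic = c(0.35, 0.25), thr = c(0.45, 0.15),
                   F_base = c(65, 15),  tau_up = c(37, 12), tau_down = c(50, 14)),
        IIa = list(r = c(27.5, 7.5), sigma_ic = c(0.50, 0.50), thr = c(0.60, 0.20),
                   F_base = c(75, 20),  tau_up = c(15, 5),  tau_down = c(20, 7)),
        IIx = list(r = c(30, 10),    sigma_ic = c(0.70, 0.50), thr = c(0.90, 0.30),
                   F_base = c(100, 25), tau_up = c(7, 3),   tau_down = c(10, 4))
      ),
      nmj_pos  = c(avg = 40, std = 5),  # % of fiber length from the upper tendon
      cv_range = c(3, 5),               # m/s, mapped from r * sigma_ic
      fixed = c(A = 96, B = 90, alpha = 550, C = 1500)
    ),
    fiber_type_pct = c(I = 50, IIa = 28, IIx = 22),  # configuration 1
    rate_grid = 8:42,        # firing-rate grid, Hz
    thr_scale = 1,           # global multiplier on printed ACh thresholds
    ramp_length_mm = NULL    # NULL -> (3 + sqrt(3)) / alpha
  )
  class(cfg) <- c("semg_config", "list")
  cfg
}

#' Predefined fiber-type distributions
#'
#' The three reference fiber-type configurations: 1 = literature biceps
#' average (50/28/22), 2 = slow-twitch dominant (70/15/15), 3 = fast-twitch
#' dominant (30/20/50).
#'
#' @param i configuration number 1, 2 or 3.
#' @return named percentage vector (I, IIa, IIx) summing to 100.
#' @export
fiber_type_configuration <- function(i) {
  tab <- list(c(I = 50, IIa = 28, IIx = 22),
              c(I = 70, IIa = 15, IIx = 15),
              c(I = 30, IIa = 20, IIx = 50))
  stopifnot(length(i) == 1L, i %in% 1:3)
  tab[[i]]
}

#' Read / write a configuration as YAML
#'
#' The YAML mirrors the structure of [default_config()], with a `table1`
#' block holding all tabulated simulation parameters. Missing fields fall
#' back to defaults.
#'
#' @param path file path.
#' @param cfg a `semg_config` (for writing).
#' @return `read_config` returns a `semg_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config(scale = raw$scale %||% "desk")
  cfg <- utils::modifyList(cfg, raw)
  # yaml drops names on some vectors; restore the ones code indexes by name
  nm <- function(x, names) { x <- unlist(x); names(x) <- names; x }
  cfg$table1$conductivity <- nm(cfg$table1$conductivity,
                                c("air", "fat_skin", "muscle", "cortical_bone", "cancellous_bone"))
  cfg$table1$fixed <- nm(cfg$table1$fixed, c("A", "B", "alpha", "C"))
  cfg$fiber_type_pct <- nm(cfg$fiber_type_pct, c("I", "IIa", "IIx"))
  class(cfg) <- c("semg_config", "list")
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.semg_config <- function(x, ...) {
  cat(sprintf("<semg_config> scale = %s, fs = %g Hz, %d fibers / ~%g motor units\n",
              x$scale, x$fs, x$table1$n_fib, x$table1$mu_number[["avg"]]))
  cat(sprintf("  fiber types %% (I/IIa/IIx): %s\n",
              paste(x$fiber_type_pct, collapse = "/")))
  invisible(x)
}

ramp_length_default <- function(cfg) {
  cfg$ramp_length_mm %||% ((3 + sqrt(3)) / cfg$table1$fixed[["alpha"]])
}
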