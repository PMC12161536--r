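#' Layered cylindrical arm phantom specification
#'
#' Concentric tissue cylinders (cancellous bone core, cortical bone shell,
#' muscle, fat/skin) inside the reference arm bounding box (x, y in
#' [-50, 50] mm, z in [0, 150] mm), plus an angular-sector/radial-band biceps
#' region that carries the muscle-fiber cross-section stack.
#'
#' @param radii strictly increasing outer radii (mm) of cancellous bone,
#'   cortical bone, muscle, and skin.
#' @param length axial extent (mm).
#' @param voxel_mm isotropic voxel size (mm).
#' @param n_fib fibers (points per slice) in the biceps region.
#' @param n_layers number of cross-section slices.
#' @param sector angular extent of the biceps region (radians, two values).
#' @param band radial extent of the biceps region (mm, two values); must lie
#'   inside the muscle annulus.
#' @param z_span axial extent of the fiber paths (mm, two values).
#' @param taper fractional fusiform narrowing of end slices relative to the
#'   mid-belly slice.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(radii = c(cancellous = 7, cortical = 12,
                                   muscle = 40, skin = 45),
                         length = 150, voxel_mm = 4,
                         n_fib = 2000L, n_layers = 3L,
                         sector = c(40, 140) * pi / 180,
                         band = c(16, 36),
                         z_span = c(10, 140), taper = 0.1) {
  if (any(diff(radii) <= 0)) stop("phantom radii must be strictly increasing")
  if (band[1] <= radii[[2]] || band[2] >= radii[[3]])
    stop("biceps region must lie inside the muscle annulus")
  structure(list(radii = radii, length = length, voxel_mm = voxel_mm,
                 n_fib = as.integer(n_fib), n_layers = as.integer(n_layers),
                 sector = sector, band = band, z_span = z_span, taper = taper),
            class = "phantom_spec")
}

# deterministic area-uniform fill of an annular sector (golden-angle spiral)
sector_points <- function(n, band, sector) {
  i <- seq_len(n)
  u <- (i - 0.5) / n
  r <- sqrt(band[1]^2 + u * (band[2]^2 - band[1]^2))
  phi <- (i * (sqrt(5) - 1) / 2) %% 1
  th <- sector[1] + phi * diff(sector)
  cbind(x = r * cos(th), y = r * sin(th))
}

#' Generate the arm phantom
#'
#' Builds the tissue-label voxel grid (labels: 0 air, 1 fat/skin, 2 muscle,
#' 3 cortical bone, 4 cancellous bone, classified by the radius of each voxel
#' center) with the tabulated tissue conductivities, and the biceps fiber
#' cross-section stack: `n_fib` deterministically placed, near-uniform points
#' filling the annular-sector region at each slice, with a slight fusiform
#' taper of the end slices toward the region centroid. Both outputs are
#' deterministic functions of the spec.
#'
#' @param spec a [phantom_spec()].
#' @param cfg a [default_config()] (for conductivities and the bounding box).
#' @return list with `grid` (a [volume_grid()]) and `stack`
#'   (a [cross_section_stack()]).
#' @export
make_phantom <- function(spec = phantom_spec(), cfg = default_config()) {
  t1 <- cfg$table1
  v <- spec$voxel_mm
  ax <- list(x = seq(t1$arm$x[1], t1$arm$x[2], by = v),
             y = seq(t1$arm$y[1], t1$arm$y[2], by = v),
             z = seq(0, spec$length, by = v))
  r2 <- outer(ax$x^2, ax$y^2, `+`)
  sec <- matrix(0L, length(ax$x), length(ax$y))
  rr <- sqrt(r2)
  sec[rr <= spec$radii[[4]]] <- 1L
  sec[rr <= spec$radii[[3]]] <- 2L
  sec[rr <= spec$radii[[2]]] <- 3L
  sec[rr <= spec$radii[[1]]] <- 4L
  labels <- array(sec, dim = c(length(ax$x), length(ax$y), length(ax$z)))
  grid <- volume_grid(ax$x, ax$y, ax$z, labels, t1$conductivity)

  base <- sector_points(spec$n_fib, spec$band, spec$sector)
  ctr <- colMeans(base)
  zs <- seq(spec$z_span[1], spec$z_span[2], length.out = spec$n_layers)
  zmid <- mean(spec$z_span)
  half <- diff(spec$z_span) / 2
  layers <- lapply(zs, function(z) {
    s <- 1 - spec$taper * ((z - zmid) / half)^2
    sweep(sweep(base, 2L, ctr, `-`) * s, 2L, ctr, `+`)
  })
  list(grid = grid, stack = cross_section_stack(layers, zs))
}

#' Reference force-profile specification
#'
#' @param task `"isometric"` (smoothed trapezoid plateaus) or `"isotonic"`
#'   (bell-shaped bursts).
#' @param level target force level, % of MVC, in (0, 100].
#' @param reps number of repetitions.
#' @param rep_s duration of one repetition (s).
#' @param rest_s rest between repetitions (s).
#' @param rate sampling rate of the raw profile (Hz).
#' @param ramp_s rise/fall time of the isometric trapezoid (s).
#' @return list of class `force_profile_spec`.
#' @export
force_profile_spec <- function(task = c("isometric", "isotonic"),
                               level = 30, reps = 1L, rep_s = 5,
                               rest_s = 2, rate = 100, ramp_s = 0.5) {
  task <- match.arg(task)
  if (level < 0 || level > 100) stop("level must be in [0, 100] %MVC")
  if (rep_s <= 0 || rest_s < 0) stop("durations must be positive")
  structure(list(task = task, level = level, reps = as.integer(reps),
                 rep_s = rep_s, rest_s = rest_s, rate = rate, ramp_s = ramp_s),
            class = "force_profile_spec")
}

#' Generate a raw reference force profile
#'
#' Emulates the recorded torque tasks: isometric repetitions are smoothed
#' trapezoids holding `level` %MVC for the repetition duration; isotonic
#' repetitions are bell-shaped (Hann) bursts peaking at `level` %MVC.
#' Repetitions are separated by rest at zero force. The output is the raw
#' profile at the spec's rate, to be conditioned by
#' [prepare_reference_force()].
#'
#' @param spec a [force_profile_spec()].
#' @param mvc maximum voluntary contraction force (mN or model force units).
#' @return list of class `raw_force`: `force` (vector), `rate` (Hz),
#'   `mvc`, `spec`.
#' @export
make_force_profile <- function(spec, mvc) {
  if (mvc <= 0) stop("mvc must be positive")
  dtr <- 1 / spec$rate
  n_rep <- round(spec$rep_s * spec$rate)
  n_rest <- round(spec$rest_s * spec$rate)
  peak <- spec$level / 100 * mvc
  one <- if (spec$task == "isometric") {
    n_ramp <- min(round(spec$ramp_s * spec$rate), n_rep %/% 2)
    c(seq(0, 1, length.out = n_ramp),
      rep(1, n_rep - 2 * n_ramp),
      seq(1, 0, length.out = n_ramp)) * peak
  } else {
    0.5 * (1 - cos(2 * pi * (seq_len(n_rep) - 1) / (n_rep - 1))) * peak
  }
  force <- c(rep(0, n_rest %/% 2),
             rep(c(one, rep(0, n_rest)), spec$reps))
  structure(list(force = force, rate = spec$rate, mvc = mvc, spec = spec),
            class = "raw_force")
}

#' Write / read a raw force profile as delimited text
#'
#' Two-column CSV (`time_s`, `force`) with a comment header declaring the
#' sampling rate and MVC.
#'
#' @param raw a [make_force_profile()] result.
#' @param path CSV path.
#' @return `read_force_profile` returns a `raw_force`.
#' @export
write_force_profile <- function(raw, path) {
  con <- file(path, "w")
  writeLines(sprintf("# rate_hz=%g mvc=%g", raw$rate, raw$mvc), con)
  utils::write.csv(data.frame(time_s = (seq_along(raw$force) - 1) / raw$rate,
                              force = raw$force),
                   con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_force_profile
#' @export
read_force_profile <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("rate_hz=([0-9.eE+-]+) mvc=([0-9.eE+-]+)", hdr))[[1]]
  if (length(m) != 3L) stop("missing '# rate_hz=... mvc=...' header in ", path)
  d <- utils::read.csv(path, comment.char = "#")
  structure(list(force = d$force, rate = as.numeric(m[2]),
                 mvc = as.numeric(m[3]), spec = NULL), class = "raw_force")
}
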