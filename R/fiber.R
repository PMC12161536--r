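#' Rosenfalck intracellular action potential
#'
#' Membrane voltage along the fiber, `Vm(z) = A (alpha z)^3 exp(-alpha z) - B`,
#' with `z = 0` at the wavefront origin. `A` is the action-potential amplitude
#' (mV), `B` the resting potential (mV) and `alpha` a spatial scale factor
#' (1/mm) that sets the bandwidth of the simulated sEMG.
#'
#' @param z distance along the fiber membrane (mm), `z >= 0`; vectorized.
#' @param p list/vector with `A`, `B`, `alpha`.
#' @return membrane voltage in mV.
#' @export
rosenfalck_vm <- function(z, p) {
  if (any(z < 0)) stop("rosenfalck_vm: z must be non-negative")
  A <- p[["A"]]; B <- p[["B"]]; alpha <- p[["alpha"]]
  stopifnot(A > 0, B > 0, alpha > 0)
  u <- alpha * z
  A * u^3 * exp(-u) - B
}

# second derivative of Vm w.r.t. z: A * alpha^2 * g(alpha z),
# g(u) = exp(-u) (u^3 - 6 u^2 + 6 u); sign lobes split at u = 0, 3 +/- sqrt(3)
rosenfalck_d2 <- function(z, p) {
  u <- p[["alpha"]] * z
  p[["A"]] * p[["alpha"]]^2 * exp(-u) * (u^3 - 6 * u^2 + 6 * u)
}

# exact antiderivatives used for lobe integration (dimensionless u-space):
#   int g(u) du           = exp(-u) (3 u^2 - u^3)
#   int u g(u) du         = -exp(-u) u^3 (u - 2)
g_int  <- function(u) exp(-u) * (3 * u^2 - u^3)
ug_int <- function(u) -exp(-u) * u^3 * (u - 2)

#' Tripole decomposition of the membrane current
#'
#' The transmembrane current `Im = C sigma_ic pi r^2 Vm''(z)` is triphasic:
#' its second derivative has three sign lobes with analytic zero crossings at
#' `alpha z = 0, 3 - sqrt(3), 3 + sqrt(3)`. Each lobe is integrated (in closed
#' form) to a point charge placed at the lobe's charge centroid, giving three
#' balanced traveling point sources. The middle charge is set to
#' `-(first + last)` so the net charge is exactly zero.
#'
#' @param p Rosenfalck parameters (`A`, `B`, `alpha`, `C`).
#' @param sigma_ic intracellular conductivity (S/m).
#' @param r fiber radius (um).
#' @return object of class `tripole`: `charges` (3, model units, summing to 0)
#'   and `offsets` (3, mm, strictly increasing distances behind the wavefront).
#' @export
tripole_decompose <- function(p, sigma_ic, r) {
  stopifnot(sigma_ic > 0, r > 0)
  alpha <- p[["alpha"]]
  u_lo <- 3 - sqrt(3); u_hi <- 3 + sqrt(3)
  bounds <- c(0, u_lo, u_hi, Inf)
  q_u <- c(g_int(u_lo) - g_int(0),
           g_int(u_hi) - g_int(u_lo),
           0 - g_int(u_hi))            # g_int(Inf) = 0
  m_u <- c(ug_int(u_lo) - ug_int(0),
           ug_int(u_hi) - ug_int(u_lo),
           0 - ug_int(u_hi))
  centroids_u <- m_u / q_u
  # Im integrated over z: C sigma pi r^2 A alpha * int g(u) du
  scale <- p[["C"]] * sigma_ic * pi * r^2 * p[["A"]] * alpha
  charges <- scale * q_u
  charges[2] <- -(charges[1] + charges[3])  # enforce exact balance
  structure(list(charges = charges, offsets = centroids_u / alpha,
                 bounds_u = bounds), class = "tripole")
}

#' Propagate the mirrored tripole pair along a fiber
#'
#' On innervation, two mirrored tripole trains are spawned at the
#' neuromuscular junction and advance by `cv * dt` of arc length per sample
#' toward opposite tendons (the ends of the fiber polyline). Within a
#' generation region of length `ramp_mm` around the junction, amplitudes grow
#' linearly from zero to full; within an extinction region of the same length
#' ending at each tendon, they shrink linearly back to zero. A train is
#' removed once its wavefront reaches the tendon. All three poles of a
#' tripole are scaled jointly, so the summed amplitude of each train is zero
#' at every step.
#'
#' @param fiber a row-list from [sample_fiber_parameters()] (needs `fib_pos`,
#'   `nmj_arc`, `cv`) or any list with those fields.
#' @param tripole a [tripole_decompose()] result.
#' @param t_innerv innervation time (s); snapped to the nearest sample.
#' @param clock a [semg_clock()].
#' @param ramp_mm generation/extinction region length (mm).
#' @return object of class `pole_train`: matrix `poles` with columns
#'   `step` (0-based, relative to the snapped innervation sample), `x`, `y`,
#'   `z` (mm), `amp`, `dir` (+1 toward the upper tendon), `pole` (1:3);
#'   plus `t0` (snapped innervation time, s) and `fs`.
#' @export
propagate_poles <- function(fiber, tripole, t_innerv, clock, ramp_mm) {
  pts <- fiber$fib_pos
  cs <- polyline_arclength(pts)
  L <- cs[length(cs)]
  s0 <- fiber$nmj_arc
  if (s0 < -1e-9 || s0 > L + 1e-9) stop("propagate_poles: NMJ not on the fiber polyline")
  s0 <- min(max(s0, 0), L)
  cv_mm <- fiber$cv * 1000        # m/s -> mm/s
  step_mm <- cv_mm * clock$dt
  t0 <- round(t_innerv * clock$fs) / clock$fs

  one_dir <- function(dir) {
    reach <- if (dir > 0) L - s0 else s0
    if (reach <= 0) return(NULL)
    ksteps <- 0:floor(reach / step_mm)
    front <- ksteps * step_mm
    scale <- pmin(front / ramp_mm, 1) * pmin((reach - front) / ramp_mm, 1)
    # pole arc positions: behind the front by the tripole offsets, never
    # crossing back over the junction
    n_k <- length(ksteps)
    s <- s0 + dir * pmax(rep(front, each = 3) -
                           rep(tripole$offsets, times = n_k), 0)
    xyz <- polyline_point(pts, s)
    cbind(step = rep(ksteps, each = 3),
          xyz,
          amp = rep(tripole$charges, times = n_k) * rep(scale, each = 3),
          dir = dir,
          pole = rep(1:3, times = n_k))
  }
  poles <- rbind(one_dir(+1L), one_dir(-1L))
  colnames(poles) <- c("step", "x", "y", "z", "amp", "dir", "pole")
  structure(list(poles = poles, t0 = t0, fs = clock$fs,
                 fiber_id = fiber$id %||% NA_integer_), class = "pole_train")
}

#' Export a pole train to CSV
#'
#' Debug/visualization dump of the traveling poles (one row per pole per
#' sample: t, x, y, z, amplitude, fiber id).
#' @param train a `pole_train`.
#' @param path output CSV path.
#' @export
write_pole_train <- function(train, path) {
  p <- as.data.frame(train$poles)
  p$t <- train$t0 + p$step / train$fs
  p$fiber_id <- train$fiber_id
  utils::write.csv(p[, c("t", "x", "y", "z", "amp", "fiber_id")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Single-twitch force of a muscle fiber
#'
#' Force response to one innervation:
#' `F(t) = F_base (1 - exp(-t/tau_up)) d^2 exp(-t/tau_down)`, and exactly 0
#' for `t < 0` (causality). `d = 2r` is the fiber diameter in um; `tau_up`
#' and `tau_down` (ms) set the rise and decay. The peak occurs at
#' `t* = tau_up * log(1 + tau_down/tau_up)`.
#'
#' @param t time since innervation (ms); vectorized.
#' @param p list with `F_base` (mN), `tau_up`, `tau_down` (ms), `d` (um).
#' @return force (model units: mN scaled by d^2).
#' @export
single_twitch_force <- function(t, p) {
  stopifnot(p$F_base > 0, p$tau_up > 0, p$tau_down > 0, p$d > 0)
  out <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  out[pos] <- p$F_base * (1 - exp(-tp / p$tau_up)) * p$d^2 * exp(-tp / p$tau_down)
  out
}

# closed-form definite integral of the single twitch over [a, b] ms
# (vectorized; bounds clamped at 0)
twitch_integral <- function(p, a, b) {
  a <- pmax(a, 0); b <- pmax(b, 0)
  k <- 1 / p$tau_up + 1 / p$tau_down
  anti <- function(t) -p$tau_down * exp(-t / p$tau_down) + exp(-k * t) / k
  p$F_base * p$d^2 * (anti(b) - anti(a))
}

#' Force profile of a fiber from a train of innervations
#'
#' Linear superposition of single twitches shifted to each innervation
#' instant (snapped to the simulation clock).
#'
#' @param impulse_times innervation times (s), sorted.
#' @param p twitch parameters as in [single_twitch_force()].
#' @param clock a [semg_clock()].
#' @param n_samples output length; defaults to covering the last impulse plus
#'   five rise+decay time constants.
#' @return numeric force series of length `n_samples` starting at t = 0.
#' @export
fiber_force_profile <- function(impulse_times, p, clock, n_samples = NULL) {
  if (is.unsorted(impulse_times)) stop("impulse times must be sorted")
  # twitch support truncated where the decay envelope is ~6e-6 of full
  tail_ms <- 12 * max(p$tau_up, p$tau_down)
  if (is.null(n_samples)) {
    t_end <- if (length(impulse_times)) max(impulse_times) + tail_ms / 1000 else 0
    n_samples <- as.integer(ceiling(t_end * clock$fs)) + 1L
  }
  out <- numeric(n_samples)
  if (length(impulse_times) == 0L) return(out)
  tmpl <- single_twitch_force((seq_len(ceiling(tail_ms / 1000 * clock$fs) + 1L) - 1L) /
                                clock$fs * 1000, p)
  for (ti in impulse_times) {
    i0 <- as.integer(round(ti * clock$fs)) + 1L
    if (i0 > n_samples) next
    i1 <- min(i0 + length(tmpl) - 1L, n_samples)
    idx <- i0:i1
    out[idx] <- out[idx] + tmpl[seq_along(idx)]
  }
  out
}
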