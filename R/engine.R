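# Per-fiber single-innervation electrode template: the mirrored tripole
# trains for one discharge at t = 0, pushed through the lead field. Because
# geometry is static and the volume conductor is linear and time-invariant,
# the full sEMG of a fiber is this template superposed at each innervation
# instant.
fiber_voltage_template <- function(fiber, p_fixed, lead, clock, ramp_mm) {
  tri <- tripole_decompose(p_fixed, fiber$sigma_ic, fiber$r)
  train <- propagate_poles(fiber, tri, 0, clock, ramp_mm)
  n_t <- max(train$poles[, "step"]) + 1L
  superpose_potentials(lead, train, n_t)
}

# scatter-add of a channels x T template at given sample offsets
scatter_template <- function(acc, tmpl, at_samples) {
  n <- ncol(acc); Tt <- ncol(tmpl)
  for (s in at_samples) {
    if (s > n) next
    e <- min(s + Tt - 1L, n)
    acc[, s:e] <- acc[, s:e] + tmpl[, seq_len(e - s + 1L), drop = FALSE]
  }
  acc
}

#' Simulate a full muscle contraction
#'
#' Runs the complete chain for one reference force profile: recruitment
#' selection against M_ref, per-unit spike trains, acetylcholine-threshold
#' innervation of individual fibers, tripole propagation of every discharge
#' through the lead field, and twitch-force summation. Monopolar sEMG is
#' the sum of motor-unit voltages per electrode; bipolar channels are the
#' configured electrode-pair differences; the force output is the sum of
#' all motor-unit force profiles.
#'
#' @param anatomy an [build_anatomy()] result.
#' @param mref the matching [build_mref()].
#' @param lead a [solve_lead_field()] result for the electrode array.
#' @param ref a [prepare_reference_force()] result.
#' @param cfg a [default_config()].
#' @param seed RNG seed for spike-train generation.
#' @param mu_subset optional vector of motor-unit ids to include (all
#'   others are silenced); used for linearity audits.
#' @param keep_mu if TRUE, per-unit voltage/force series are retained.
#' @return object of class `sim_result`: `semg_mono` (electrodes x samples),
#'   `semg_bipolar` (pairs x samples), `force` (samples), `fs`, `seed`,
#'   `plan`, `innervations` (count per fiber), optional `per_mu`.
#' @export
simulate_contraction <- function(anatomy, mref, lead, ref, cfg = default_config(),
                                 seed = 1L, mu_subset = NULL, keep_mu = FALSE) {
  clock <- semg_clock(cfg$fs)
  if (!is.null(ref$fs) && abs(ref$fs - clock$fs) > 1e-9)
    stop("reference force and configuration clocks disagree")
  plan <- select_recruitment(ref, mref)
  trains <- generate_spike_trains(plan, mref, seed = seed)
  f <- anatomy$fibers
  n_samples <- length(ref$force)
  n_elec <- dim(lead$h)[4]
  p_fixed <- cfg$table1$fixed
  ramp_mm <- ramp_length_default(cfg)
  bip <- lead$electrodes$bipolar

  mono <- matrix(0, n_elec, n_samples)
  force <- numeric(n_samples)
  innerv_count <- integer(nrow(f))
  per_mu <- if (keep_mu) list() else NULL

  mu_ids <- mref$mu_order
  if (!is.null(mu_subset)) mu_ids <- intersect(mu_ids, mu_subset)
  for (mu in mu_ids) {
    spikes <- trains[[as.character(mu)]]
    if (length(spikes) == 0L) next
    rows <- which(f$mu_id == mu)
    neuron <- motor_neuron(mu, f$id[rows], f$thr[rows], cfg$table1$ach, spikes)
    innervs <- transmit_and_trigger(neuron, clock, n_samples = n_samples,
                                    thr_scale = mref$thr_scale)
    mu_v <- matrix(0, n_elec, n_samples)
    mu_f <- numeric(n_samples)
    for (ri in seq_along(rows)) {
      ev <- innervs[[ri]]
      if (length(ev) == 0L) next
      fi <- rows[ri]
      innerv_count[fi] <- length(ev)
      fib <- c(as.list(f[fi, ]), list(fib_pos = anatomy$paths[[fi]]))
      vt <- fiber_voltage_template(fib, p_fixed, lead, clock, ramp_mm)
      at <- as.integer(round(ev * clock$fs)) + 1L
      mu_v <- scatter_template(mu_v, vt, at)
      tw <- list(F_base = f$F_base[fi], tau_up = f$tau_up[fi],
                 tau_down = f$tau_down[fi], d = f$d[fi])
      mu_f <- mu_f + fiber_force_profile(ev, tw, clock, n_samples = n_samples)
    }
    mono <- mono + mu_v
    force <- force + mu_f
    if (keep_mu) per_mu[[as.character(mu)]] <- list(voltage = mu_v, force = mu_f)
  }
  bipolar <- if (!is.null(bip))
    mono[bip[, 1], , drop = FALSE] - mono[bip[, 2], , drop = FALSE]
  else matrix(0, 0, n_samples)
  structure(list(semg_mono = mono, semg_bipolar = bipolar, force = force,
                 fs = clock$fs, seed = seed, plan = plan,
                 innervations = innerv_count, per_mu = per_mu),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(paste0("<sim_result> %d monopolar + %d bipolar channels, ",
                     "%d samples @ %g Hz\n"),
              nrow(x$semg_mono), nrow(x$semg_bipolar), ncol(x$semg_mono), x$fs))
  cat(sprintf("  %d fibers discharged; peak force %.4g mN\n",
              sum(x$innervations > 0), max(x$force)))
  invisible(x)
}

#' Persist / load a simulation result
#'
#' Writes the signal matrices and metadata as plain text under a directory
#' (per-channel CSV columns, full float precision) so that a read-back
#' reproduces the arrays to text-format precision.
#'
#' @param res a [simulate_contraction()] result.
#' @param dir output directory.
#' @return `read_result` returns a `sim_result` (without plan/per-unit
#'   internals).
#' @export
write_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, name) {
    d <- as.data.frame(t(m))
    names(d) <- paste0("ch", seq_len(ncol(d)))
    d[] <- lapply(d, function(col) format(col, digits = 17, trim = TRUE))
    utils::write.csv(d, file.path(dir, name), row.names = FALSE, quote = FALSE)
  }
  wr(res$semg_mono, "semg_mono.csv")
  wr(res$semg_bipolar, "semg_bipolar.csv")
  wr(matrix(res$force, nrow = 1), "force.csv")
  jsonlite::write_json(list(fs = res$fs, seed = res$seed,
                            n_samples = ncol(res$semg_mono)),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_result
#' @export
read_result <- function(dir) {
  rd <- function(name) t(as.matrix(utils::read.csv(file.path(dir, name))))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  structure(list(semg_mono = unname(rd("semg_mono.csv")),
                 semg_bipolar = unname(rd("semg_bipolar.csv")),
                 force = as.numeric(rd("force.csv")),
                 fs = meta$fs, seed = meta$seed, plan = NULL,
                 innervations = NULL, per_mu = NULL),
            class = "sim_result")
}
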