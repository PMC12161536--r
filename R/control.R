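#' Build the motor-unit force-response matrix and cumulative M_ref
#'
#' For every motor unit and every firing rate in the grid, a steady periodic
#' spike train is pushed through acetylcholine triggering and twitch
#' summation over a calibration window, and the window-average force (over
#' the final `avg_window` seconds, once summation has settled) is stored in
#' an N x M matrix (rows = motor units, columns = rates). Motor units are
#' then sorted ascending by size (Henneman's size principle) and rows are
#' cumulatively summed, so `mref[n, m]` is the mean force of the n smallest
#' units all firing at rate m. Window averages use the closed-form twitch
#' integral, so no per-sample force series is materialized.
#'
#' @param anatomy an [build_anatomy()] result.
#' @param cfg a [default_config()].
#' @param clock a [semg_clock()].
#' @param rate_grid firing rates (Hz), strictly increasing.
#' @param window calibration train duration (s).
#' @param avg_window averaging span at the end of the window (s).
#' @param thr_scale global ACh threshold multiplier (see
#'   [ach_threshold_scale()]).
#' @return object of class `mref`: `force_matrix` (N x M, unit order =
#'   anatomy order), `cumulative` (N x M in Henneman order), `mu_order`,
#'   `rates`, `model_mvc` (= cumulative[N, M]), `thr_scale`.
#' @export
build_mref <- function(anatomy, cfg = default_config(), clock = semg_clock(cfg$fs),
                       rate_grid = cfg$rate_grid, window = 2, avg_window = 1.5,
                       thr_scale = cfg$thr_scale) {
  if (length(rate_grid) == 0L) stop("empty rate grid")
  if (is.unsorted(rate_grid, strictly = TRUE)) stop("rate grid must be strictly increasing")
  f <- anatomy$fibers
  mus <- sort(unique(f$mu_id))
  N <- length(mus); M <- length(rate_grid)
  n_samples <- as.integer(window * clock$fs)
  a <- window - avg_window; b <- window
  fm <- matrix(0, N, M)
  for (m in seq_len(M)) {
    spikes <- seq(0, window - 1e-9, by = 1 / rate_grid[m])
    sp_idx <- unique(as.integer(round(spikes * clock$fs)) + 1L)
    sp_idx <- sp_idx[sp_idx <= n_samples]
    Mx <- ach_suffix_max(sp_idx, n_samples, cfg$table1$ach, clock)
    for (u in seq_len(N)) {
      rows <- which(f$mu_id == mus[u])
      tot <- 0
      for (fi in rows) {
        ev <- trigger_fiber(Mx, sp_idx, f$thr[fi] * thr_scale)
        if (length(ev) == 0L) next
        tv <- (ev - 1L) / clock$fs
        p <- list(F_base = f$F_base[fi], tau_up = f$tau_up[fi],
                  tau_down = f$tau_down[fi], d = f$d[fi])
        tot <- tot + sum(twitch_integral(p, (a - tv) * 1000, (b - tv) * 1000))
      }
      fm[u, m] <- tot / (avg_window * 1000)  # mN
    }
  }
  sizes <- as.numeric(table(factor(f$mu_id, levels = mus)))
  ord <- order(sizes, mus)
  cum <- apply(fm[ord, , drop = FALSE], 2L, cumsum)
  if (N == 1L) cum <- matrix(cum, nrow = 1L)
  structure(list(force_matrix = fm, cumulative = cum, mu_order = mus[ord],
                 mu_sizes = sizes[ord], rates = rate_grid,
                 model_mvc = cum[N, M], thr_scale = thr_scale),
            class = "mref")
}

#' @export
print.mref <- function(x, ...) {
  cat(sprintf("<mref> %d motor units x %d rates (%g-%g Hz); model MVC = %.4g mN\n",
              nrow(x$cumulative), length(x$rates), min(x$rates), max(x$rates),
              x$model_mvc))
  invisible(x)
}

#' Select per-sample recruitment from M_ref
#'
#' For each reference-force sample `f`, the candidate set is every
#' `(n, m)` with `0.99 f < mref[n, m] < 1.01 f` (the one-percent force
#' window). Among candidates, the pair closest (perpendicular distance in
#' the normalized index space `(n/N, m/M)`) to the diagonal from (0, 0) to
#' (MUmax, FRmax) is selected; ties prefer fewer units, then lower rate. If
#' the window is empty, the entry nearest the target force is used; forces
#' above the model maximum saturate at (MUmax, FRmax), and `f <= 0` recruits
#' nothing.
#'
#' @param ref a [prepare_reference_force()] result (or any list with `force`
#'   and `fs`).
#' @param mref a [build_mref()] result.
#' @return object of class `recruitment_plan`: data.frame `plan` with
#'   columns `n` (recruited units), `m_idx`, `rate_hz`, `rate_std_hz`
#'   (10 Hz scaled by the recruited fraction), one row per sample, plus the
#'   rate grid and Henneman unit order.
#' @export
select_recruitment <- function(ref, mref) {
  cum <- mref$cumulative
  if (length(cum) == 0L) stop("empty M_ref")
  N <- nrow(cum); M <- ncol(cum)
  nn <- rep(seq_len(N), times = M)
  mm <- rep(seq_len(M), each = N)
  v <- as.vector(cum)
  dist_diag <- abs(nn / N - mm / M) / sqrt(2)
  rank_diag <- integer(N * M)
  rank_diag[order(dist_diag, nn, mm)] <- seq_len(N * M)  # precedence under ties
  f <- ref$force
  n_out <- integer(length(f)); m_out <- integer(length(f))
  cmax <- max(v)
  # hysteresis: the previous entry is kept while it stays in-window, so
  # steady segments keep stable spike trains instead of flapping between
  # equivalent table entries
  prev <- 0L
  for (s in seq_along(f)) {
    fs_ <- f[s]
    if (fs_ <= 0) { n_out[s] <- 0L; m_out[s] <- 0L; prev <- 0L; next }
    if (fs_ >= cmax) { n_out[s] <- N; m_out[s] <- M; prev <- N * M; next }
    if (prev > 0L && v[prev] > 0.99 * fs_ && v[prev] < 1.01 * fs_) {
      n_out[s] <- nn[prev]; m_out[s] <- mm[prev]; next
    }
    cand <- which(v > 0.99 * fs_ & v < 1.01 * fs_)
    if (length(cand) == 0L) cand <- which.min(abs(v - fs_))
    best <- cand[which.min(rank_diag[cand])]
    n_out[s] <- nn[best]; m_out[s] <- mm[best]
    prev <- best
  }
  plan <- data.frame(
    n = n_out, m_idx = m_out,
    rate_hz = ifelse(m_out > 0L, mref$rates[pmax(m_out, 1L)], 0),
    rate_std_hz = 10 * n_out / N)
  structure(list(plan = plan, rates = mref$rates, mu_order = mref$mu_order,
                 fs = ref$fs, N = N), class = "recruitment_plan")
}

#' Generate per-unit spike trains from a recruitment plan
#'
#' The plan is split into segments of constant `(n, m)`. At each segment
#' start every active unit (the `n` smallest, in Henneman order) draws a
#' firing rate from `Gaussian(mean = m, sd = rate_std)` clamped to the rate
#' grid, and emits strictly periodic spikes at that rate from a uniformly
#' random initial phase until the segment ends; de-recruited units stop
#' firing. The rate dispersion grows linearly from 0 to 10 Hz with the
#' recruited fraction, emulating the lower, tighter rates of early-recruited
#' units.
#'
#' @param plan a [select_recruitment()] result.
#' @param mref the matching [build_mref()].
#' @param seed RNG seed.
#' @return named list (by motor-unit id) of spike time vectors (s).
#' @export
generate_spike_trains <- function(plan, mref, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- plan$plan
  fs <- plan$fs
  rmin <- min(mref$rates); rmax <- max(mref$rates)
  mu_order <- plan$mu_order
  trains <- stats::setNames(rep(list(numeric()), length(mu_order)),
                            as.character(mu_order))
  if (nrow(p) == 0L) return(trains)
  key <- paste(p$n, p$m_idx)
  seg_start <- which(c(TRUE, key[-1] != key[-length(key)]))
  seg_end <- c(seg_start[-1] - 1L, nrow(p))
  for (s in seq_along(seg_start)) {
    n <- p$n[seg_start[s]]
    if (n == 0L) next
    t0 <- (seg_start[s] - 1L) / fs
    t1 <- (seg_end[s]) / fs
    mean_rate <- p$rate_hz[seg_start[s]]
    sd_rate <- p$rate_std_hz[seg_start[s]]
    for (u in seq_len(n)) {
      rate <- min(max(stats::rnorm(1, mean_rate, sd_rate), rmin), rmax)
      phase <- stats::runif(1) / rate
      if (t0 + phase <= t1) {
        sp <- seq(t0 + phase, t1, by = 1 / rate)
        trains[[u]] <- c(trains[[u]], sp)
      }
    }
  }
  lapply(trains, sort)
}

#' Condition a raw reference force profile for simulation
#'
#' Resamples the raw series (typically 100 Hz recorded torque) to the
#' simulation clock by band-limited polyphase resampling (linear
#' interpolation optionally), divides by the participant's maximum voluntary
#' contraction, and multiplies by the model's MVC (the maximum entry of
#' M_ref), so the requested forces are expressed in the model's own force
#' units.
#'
#' @param raw a [make_force_profile()]/[read_force_profile()] result.
#' @param participant_mvc MVC of the recorded participant (same units as
#'   `raw$force`).
#' @param model_mvc MVC of the model (mN), usually `mref$model_mvc`.
#' @param clock a [semg_clock()].
#' @param method `"polyphase"` (signal::resample) or `"linear"`.
#' @return object of class `reference_force`: `force` (mN at fs), `fs`,
#'   and provenance fields.
#' @export
prepare_reference_force <- function(raw, participant_mvc, model_mvc,
                                    clock = semg_clock(),
                                    method = c("polyphase", "linear")) {
  method <- match.arg(method)
  if (participant_mvc <= 0 || model_mvc <= 0) stop("MVC values must be positive")
  x <- raw$force
  up <- clock$fs; dn <- raw$rate
  g <- gcd_int(round(up), round(dn))
  if (method == "polyphase") {
    y <- signal::resample(x, round(up) / g, round(dn) / g)
  } else {
    n_out <- round(length(x) * up / dn)
    y <- stats::approx(seq_along(x), x, xout = seq(1, length(x),
                                                   length.out = n_out))$y
  }
  n_out <- round(length(x) * up / dn)
  y <- y[seq_len(min(n_out, length(y)))]
  if (length(y) < n_out) y <- c(y, rep(y[length(y)], n_out - length(y)))
  structure(list(force = y / participant_mvc * model_mvc, fs = clock$fs,
                 raw_rate = raw$rate, participant_mvc = participant_mvc,
                 model_mvc = model_mvc), class = "reference_force")
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Export a recruitment plan to CSV
#'
#' @param plan a [select_recruitment()] result.
#' @param path CSV path.
#' @export
write_recruitment_plan <- function(plan, path) {
  d <- plan$plan
  d$t <- (seq_len(nrow(d)) - 1L) / plan$fs
  utils::write.csv(d[, c("t", "n", "m_idx", "rate_hz", "rate_std_hz")],
                   path, row.names = FALSE)
  invisible(path)
}
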