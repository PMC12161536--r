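# Shared small-scale fixtures, built once per test run on first use.
# Everything is generated in code; sizes are chosen so the whole suite runs
# in minutes on one CPU while exercising every code path.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# desk-scale configuration shrunk further for tests
tiny_config <- function() {
  cfg <- default_config()
  cfg$table1$n_fib <- 300L
  cfg$table1$mu_number <- c(avg = 8, std = 2)
  cfg$table1$mu_size <- c(avg = 38, std = 12)
  cfg$rate_grid <- seq(8, 42, by = 2)
  cfg$thr_scale <- fixture("thr_scale", function() ach_threshold_scale(cfg))
  cfg
}

tiny_phantom <- function() fixture("phantom", function() {
  make_phantom(phantom_spec(n_fib = 300L, n_layers = 3L, voxel_mm = 5),
               tiny_config())
})

tiny_anatomy <- function() fixture("anatomy", function() {
  build_anatomy(tiny_phantom()$stack, tiny_config(), seed = 11L)
})

tiny_lead <- function() fixture("lead", function() {
  ph <- tiny_phantom()
  el <- place_electrodes(ph$grid)
  solve_lead_field(ph$grid, el)
})

tiny_mref <- function() fixture("mref", function() {
  cfg <- tiny_config()
  build_mref(tiny_anatomy(), cfg, thr_scale = cfg$thr_scale)
})

tiny_reference <- function(level = 30, rep_s = 4, rest_s = 1) {
  raw <- make_force_profile(
    force_profile_spec("isometric", level = level, rep_s = rep_s,
                       rest_s = rest_s), mvc = 100)
  prepare_reference_force(raw, 100, tiny_mref()$model_mvc)
}

tiny_sim <- function() fixture("sim", function() {
  simulate_contraction(tiny_anatomy(), tiny_mref(), tiny_lead(),
                       tiny_reference(), tiny_config(), seed = 7L)
})

# independent brute-force innervation oracle: per sample, sums the ACh
# profiles of all spikes since the last reset directly from the formula
brute_trigger <- function(spikes, thr, ach, fs, n) {
  sp_idx <- as.integer(round(spikes * fs)) + 1L
  events <- numeric()
  last_spike_gate <- 0L  # spikes at samples <= gate are discarded by reuptake
  for (s in seq_len(n)) {
    act <- sp_idx[sp_idx > last_spike_gate & sp_idx <= s]
    if (length(act) == 0L) next
    tt <- (s - act) / fs
    val <- sum(ach$Am * (1 - exp(-ach$kr * tt)) * exp(-ach$kd * tt))
    if (val >= thr) {
      events <- c(events, (s - 1L) / fs)
      last_spike_gate <- s
    }
  }
  events
}
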