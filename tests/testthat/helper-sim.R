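# Shared fixtures built in code.

# Noiseless logistic quench trace on a uniform grid (10 s default sampling).
logistic_trace <- function(midpoint, f0 = 1000, quench = 0.4, tau = 0.4,
                           dt = 1 / 6, duration = 20, well = "A1") {
  p <- sim_params(f0 = f0, quench_frac = quench, tau = tau,
                  t_intercept = midpoint, sigma_tt = 0, sigma_f = 0,
                  drift = 0, sample_interval = dt, duration = duration)
  simulate_well_trace(p, detected_copies = 1, rng_seed = 0, well_id = well)$trace
}

flat_trace <- function(f0 = 1000, dt = 1 / 6, duration = 15, well = "A1",
                       sigma_f = 0, drift = 0, seed = 0) {
  p <- sim_params(f0 = f0, sigma_f = sigma_f, drift = drift,
                  sample_interval = dt, duration = duration)
  simulate_well_trace(p, detected_copies = 0, rng_seed = seed,
                      well_id = well)$trace
}

# Trace set for a full chip: wells in `pos_wells` get a clean quench at
# tt_min, every other layout well a clean flat baseline.
make_chip_traces <- function(layout, pos_wells, tt = 8, duration = 15) {
  wells <- names(layout$wells)[layout$wells != "UNUSED"]
  traces <- lapply(wells, function(w) {
    if (w %in% pos_wells) logistic_trace(tt, duration = duration, well = w)
    else flat_trace(duration = duration, well = w)
  })
  names(traces) <- wells
  traces
}

# Independent brute-force oracle for the all-negative-run LoD rule:
# scan the pooled ladder from the top; the first concentration showing a
# 0-positive run triggers, and the LoD is the concentration scanned just
# before it.
lod_oracle <- function(grid) {
  ladder <- sort(unique(grid$conc), decreasing = TRUE)
  for (i in seq_along(ladder)) {
    runs <- grid$positive_wells[grid$conc == ladder[i]]
    if (any(runs == 0L)) {
      if (i == 1L) return(list(bound = "ABOVE_RANGE", lod = NA_real_))
      return(list(bound = "EXACT_STEP", lod = ladder[i - 1L]))
    }
  }
  list(bound = "BELOW_RANGE", lod = min(ladder))
}

# Random small replicate grid for property tests.
random_grid <- function(n_conc = 5, runs = 3, n_wells = 5) {
  ladder <- sort(round(stats::runif(n_conc, 0.3, 20), 2), decreasing = TRUE)
  ladder <- unique(ladder)
  rec <- expand.grid(conc = ladder, run = seq_len(runs))
  rec$series <- 1L
  rec$n_wells <- n_wells
  # positivity loosely increasing with concentration, occasional zeros
  p <- 1 - exp(-0.4 * rec$conc)
  rec$positive_wells <- stats::rbinom(nrow(rec), n_wells, p)
  dilution_grid("X", rec)
}

# Numeric ranking of an LoD estimate for monotonicity comparisons.
lod_rank <- function(est) {
  switch(est$bound,
         BELOW_RANGE = -Inf,
         EXACT_STEP = est$lod_cps_per_well,
         ABOVE_RANGE = Inf)
}
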