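# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a deterministic sub-seed from a master seed and a string key
#'
#' A stable 31-bit polynomial string hash (base 31 over the key's UTF-8
#' bytes, modulo the Mersenne prime 2^31 - 1, seeded with the master
#' seed). Used to give every simulated well its own RNG stream, so adding
#' wells to a run never perturbs the draws of existing wells.
#'
#' @param master_seed integer master seed.
#' @param key character string (e.g. a well address).
#' @return Integer sub-seed in `[0, 2^31 - 2]`.
#' @export
derive_subseed <- function(master_seed, key) {
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(master_seed) %% m
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% m
  as.integer(h)
}

#' Parameters of the generative trace model
#'
#' The simulator emulates a QProbe-read LAMP reaction: fluorescence starts
#' at a baseline `f0` and, if the well amplifies, drops by a fraction
#' `quench_frac` along a logistic transition centred at the well's true Tt.
#' The kinetic law ties Tt to template load: `Tt = t_intercept -
#' slope_per_doubling * log2(detected copies) + jitter`, floored at 1 min.
#' Instrument noise is additive Gaussian plus a slow linear drift. All
#' kinetic and noise values are package conventions chosen to produce
#' realistic-looking traces within the 15/20-minute reaction windows; none
#' are instrument calibrations.
#'
#' @param f0 baseline fluorescence, AU. Default 1000.
#' @param quench_frac total fractional quench amplitude in (0,1).
#'   Default 0.40.
#' @param tau logistic transition time constant, minutes. Default 0.4.
#' @param t_intercept mean Tt at 1 detected copy, minutes. Default 10.
#' @param slope_per_doubling Tt decrease per doubling of detected copies,
#'   minutes. Default 0.75.
#' @param sigma_tt Tt jitter s.d., minutes. Default 0.3.
#' @param sigma_f additive fluorescence noise s.d., AU. Default 5.
#' @param drift linear baseline drift, AU/min. Default 0.2.
#' @param sample_interval sampling period, minutes. Default 1/6 (10 s).
#' @param duration run length, minutes: 15 for swab panels, 20 for sputum.
#'   Default 15.
#' @param p_det per-copy detection probability. Default 1.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(f0 = 1000, quench_frac = 0.40, tau = 0.4,
                       t_intercept = 10, slope_per_doubling = 0.75,
                       sigma_tt = 0.3, sigma_f = 5, drift = 0.2,
                       sample_interval = 1 / 6, duration = 15, p_det = 1) {
  if (f0 <= 0) stop("f0 must be > 0", call. = FALSE)
  if (quench_frac <= 0 || quench_frac >= 1)
    stop("quench_frac must be in (0,1)", call. = FALSE)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (sample_interval <= 0) stop("sample_interval must be > 0", call. = FALSE)
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (sigma_tt < 0 || sigma_f < 0) stop("noise s.d. must be >= 0", call. = FALSE)
  if (p_det <= 0 || p_det > 1) stop("p_det must be in (0, 1]", call. = FALSE)
  structure(list(f0 = f0, quench_frac = quench_frac, tau = tau,
                 t_intercept = t_intercept,
                 slope_per_doubling = slope_per_doubling,
                 sigma_tt = sigma_tt, sigma_f = sigma_f, drift = drift,
                 sample_interval = sample_interval, duration = duration,
                 p_det = p_det),
            class = "sim_params")
}

#' Simulate one well's fluorescence trace
#'
#' With zero detected copies the trace is baseline plus drift and noise and
#' carries no Tt. Otherwise the true Tt follows the kinetic law of
#' [sim_params()] and the trace is
#' `F(t) = f0 * (1 - quench_frac / (1 + exp(-(t - Tt)/tau))) + drift*t +
#' noise`, sampled on the uniform grid `0, dt, ..., duration`.
#'
#' @param params a [sim_params].
#' @param detected_copies non-negative integer.
#' @param rng_seed integer seed; the caller's RNG state is untouched.
#' @param well_id well address for the returned trace. Default `"A1"`.
#' @return List with `trace` (a [fluor_trace]) and `true_tt` (minutes, or
#'   `NA` when `detected_copies = 0`).
#' @export
simulate_well_trace <- function(params, detected_copies, rng_seed,
                                well_id = "A1") {
  stopifnot(inherits(params, "sim_params"), detected_copies >= 0)
  times <- seq(0, params$duration, by = params$sample_interval)
  with_seed(rng_seed, {
    noise <- stats::rnorm(length(times), 0, params$sigma_f)
    if (detected_copies == 0) {
      vals <- params$f0 + params$drift * times + noise
      true_tt <- NA_real_
    } else {
      true_tt <- max(1.0, params$t_intercept -
                       params$slope_per_doubling * log2(detected_copies) +
                       stats::rnorm(1, 0, params$sigma_tt))
      quench <- params$quench_frac / (1 + exp(-(times - true_tt) / params$tau))
      vals <- params$f0 * (1 - quench) + params$drift * times + noise
    }
    list(trace = fluor_trace(well_id, times, vals), true_tt = true_tt)
  })
}

#' Simulate a full 25-well chip run
#'
#' Per well: template copies are drawn Poisson with the item's
#' concentration (UNUSED wells receive none), thinned by the per-copy
#' detection probability, and a trace is generated. Every well uses an
#' independent sub-seed derived from the master seed and the well address
#' ([derive_subseed()]), so results per well are stable under layout
#' extension.
#'
#' @param layout a [panel_layout].
#' @param item_conc named numeric vector: cps/well for every layout item
#'   (control included).
#' @param params a [sim_params].
#' @param rng_seed integer master seed.
#' @return List with `traces` (named list of [fluor_trace]) and `truth`
#'   (data.frame: well, item, copies, detected_copies, amplified, true_tt).
#' @export
simulate_chip_run <- function(layout, item_conc, params = sim_params(),
                              rng_seed = 1L) {
  stopifnot(inherits(layout, "panel_layout"), inherits(params, "sim_params"))
  needed <- setdiff(unique(layout$wells), "UNUSED")
  missing <- setdiff(needed, names(item_conc))
  if (length(missing))
    stop("configuration error: no concentration for item(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  wells <- names(layout$wells)
  traces <- vector("list", length(wells))
  names(traces) <- wells
  truth <- vector("list", length(wells))
  for (i in seq_along(wells)) {
    w <- wells[i]
    it <- layout$wells[[w]]
    seed_w <- derive_subseed(rng_seed, w)
    lam <- if (it == "UNUSED") 0 else item_conc[[it]]
    copies <- with_seed(seed_w, {
      k <- stats::rpois(1, lam)
      det <- if (params$p_det < 1) stats::rbinom(1, k, params$p_det) else k
      c(k, det)
    })
    sim <- simulate_well_trace(params, copies[2L],
                               rng_seed = derive_subseed(seed_w, "trace"),
                               well_id = w)
    traces[[w]] <- sim$trace
    truth[[i]] <- data.frame(well = w, item = it, copies = copies[1L],
                             detected_copies = copies[2L],
                             amplified = copies[2L] >= 1L,
                             true_tt = sim$true_tt)
  }
  list(traces = traces, truth = do.call(rbind, truth))
}

#' Simulate a dilution-series experiment end to end
#'
#' For each ladder concentration and run, simulates `n_wells` wells
#' (Poisson copies, thinning, trace generation), calls every trace through
#' the Tt caller, classifies against the cutoff, and records the
#' positive-well count. The output is a [dilution_grid] consumable by
#' [estimate_lod()].
#'
#' @param item item label for the grid.
#' @param ladder numeric vector of concentrations, cps/well.
#' @param runs_per_conc runs at each concentration (>= 1).
#' @param n_wells wells per run. Default 5.
#' @param params a [sim_params].
#' @param caller_params a [caller_params].
#' @param cutoff Tt cutoff in minutes. Default 15.
#' @param rng_seed integer master seed.
#' @return A [dilution_grid] (single series).
#' @export
simulate_dilution_experiment <- function(item, ladder, runs_per_conc,
                                         n_wells = 5L,
                                         params = sim_params(),
                                         caller_params = lampanel::caller_params(),
                                         cutoff = 15, rng_seed = 1L) {
  stopifnot(length(ladder) >= 1L, runs_per_conc >= 1L)
  rows <- list()
  for (conc in ladder) {
    for (run in seq_len(runs_per_conc)) {
      npos <- 0L
      for (w in seq_len(n_wells)) {
        key <- sprintf("c%g.r%d.w%d", conc, run, w)
        seed_w <- derive_subseed(rng_seed, key)
        copies <- with_seed(seed_w, {
          k <- stats::rpois(1, conc)
          if (params$p_det < 1) stats::rbinom(1, k, params$p_det) else k
        })
        sim <- simulate_well_trace(params, copies,
                                   rng_seed = derive_subseed(seed_w, "trace"))
        cl <- call_tt(sim$trace, caller_params)
        if (classify_well(cl, cutoff) == "POSITIVE") npos <- npos + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(series = 1L, conc = conc,
                                              run = run,
                                              positive_wells = npos,
                                              n_wells = n_wells)
    }
  }
  dilution_grid(item, do.call(rbind, rows))
}
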