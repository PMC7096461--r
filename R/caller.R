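#' Parameters for the Tt caller
#'
#' Controls baseline normalization, Savitzky-Golay smoothing, and the
#' thresholds that separate a real quench event from noise. The quenching
#' probe (QProbe) chemistry means amplification DECREASES fluorescence, so
#' the amplification time Tt is located at the MINIMUM of the differentiated
#' normalized curve; the caller never auto-detects signal direction.
#'
#' @param baseline_window_min duration in minutes from the first sample used
#'   for baseline estimation (median). Default 2.0.
#' @param smooth_window odd integer, samples in the Savitzky-Golay window.
#'   Default 9 (1.5 min at the default 10 s sampling).
#' @param smooth_order polynomial order of the smoother, must be smaller
#'   than `smooth_window`. Default 2.
#' @param min_drop_frac minimum total normalized fluorescence drop
#'   (1 - min normalized value) required to call amplification, in (0,1).
#'   Default 0.10.
#' @param min_slope_mag minimum magnitude of the derivative minimum, per
#'   minute. Default 0.05.
#' @param edge_exclude samples excluded at each end of the derivative when
#'   locating the minimum. Default 3.
#' @return An object of class `caller_params`.
#' @export
caller_params <- function(baseline_window_min = 2.0, smooth_window = 9L,
                          smooth_order = 2L, min_drop_frac = 0.10,
                          min_slope_mag = 0.05, edge_exclude = 3L) {
  smooth_window <- as.integer(smooth_window)
  smooth_order <- as.integer(smooth_order)
  edge_exclude <- as.integer(edge_exclude)
  if (baseline_window_min <= 0) stop("baseline_window_min must be > 0", call. = FALSE)
  if (smooth_window %% 2L != 1L) stop("smooth_window must be odd", call. = FALSE)
  if (smooth_window <= smooth_order)
    stop("smooth_window must exceed smooth_order", call. = FALSE)
  if (min_drop_frac <= 0 || min_drop_frac >= 1)
    stop("min_drop_frac must be in (0,1)", call. = FALSE)
  if (min_slope_mag <= 0) stop("min_slope_mag must be > 0", call. = FALSE)
  if (edge_exclude < 0L) stop("edge_exclude must be >= 0", call. = FALSE)
  structure(list(baseline_window_min = baseline_window_min,
                 smooth_window = smooth_window, smooth_order = smooth_order,
                 min_drop_frac = min_drop_frac, min_slope_mag = min_slope_mag,
                 edge_exclude = edge_exclude),
            class = "caller_params")
}

#' Normalize a trace to its early baseline
#'
#' Divides all fluorescence values by the median of the readings within the
#' baseline window (`[t0, t0 + baseline_window_min]`). On a quench trace the
#' normalized baseline sits near 1 and the curve decreases below 1 as the
#' probe quenches.
#'
#' @param trace a [fluor_trace].
#' @param params a [caller_params].
#' @return The normalized [fluor_trace].
#' @export
normalize_trace <- function(trace, params = caller_params()) {
  stopifnot(inherits(trace, "fluor_trace"))
  in_win <- trace$times <= trace$times[1L] + params$baseline_window_min
  if (sum(in_win) < 3L)
    stop("invalid trace (well ", trace$well_id,
         "): baseline window holds fewer than 3 samples", call. = FALSE)
  base <- stats::median(trace$values[in_win])
  if (!is.finite(base) || base <= 0)
    stop("invalid trace (well ", trace$well_id,
         "): non-positive baseline median", call. = FALSE)
  fluor_trace(trace$well_id, trace$times, trace$values / base)
}

#' Smooth a normalized trace and differentiate it in time
#'
#' Applies Savitzky-Golay (local least-squares polynomial) smoothing, then
#' central-difference differentiation with respect to time; the endpoints
#' use one-sided differences. Units of the derivative are per minute.
#'
#' @inheritParams normalize_trace
#' @return A list with `times`, `smoothed` (normalized units) and `deriv`
#'   (min^-1), all on the input time grid.
#' @export
smooth_and_differentiate <- function(trace, params = caller_params()) {
  stopifnot(inherits(trace, "fluor_trace"))
  n <- length(trace$values)
  if (n < params$smooth_window)
    stop("invalid trace (well ", trace$well_id, "): ", n,
         " samples is shorter than the smoothing window (",
         params$smooth_window, ")", call. = FALSE)
  sm <- signal::sgolayfilt(trace$values, p = params$smooth_order,
                           n = params$smooth_window)
  t <- trace$times
  d <- numeric(n)
  d[1L] <- (sm[2L] - sm[1L]) / (t[2L] - t[1L])
  d[n] <- (sm[n] - sm[n - 1L]) / (t[n] - t[n - 1L])
  i <- 2:(n - 1L)
  d[i] <- (sm[i + 1L] - sm[i - 1L]) / (t[i + 1L] - t[i - 1L])
  list(times = t, smoothed = sm, deriv = d)
}

#' Call the amplification time (Tt) of one well
#'
#' Normalizes the trace, smooths and differentiates it, and locates the
#' global minimum of the derivative over the interior region (excluding
#' `edge_exclude` samples at each end; ties broken toward the earliest
#' time). The well is called amplified iff both the derivative minimum
#' magnitude reaches `min_slope_mag` and the total normalized drop reaches
#' `min_drop_frac`; Tt is reported at the grid point of the minimum (no
#' sub-sample interpolation).
#'
#' @inheritParams normalize_trace
#' @return An object of class `well_call`: list with `well_id`, `amplified`
#'   (logical), `tt_min` (minutes; `NA` when not amplified), `drop_frac`,
#'   and `min_slope` (min^-1).
#' @examples
#' p <- sim_params(sigma_f = 0, sigma_tt = 0, drift = 0)
#' tr <- simulate_well_trace(p, detected_copies = 1, rng_seed = 1)$trace
#' call_tt(tr)  # Tt at the kinetic model's intercept, 10 min
#' @export
call_tt <- function(trace, params = caller_params()) {
  norm <- normalize_trace(trace, params)
  sd <- smooth_and_differentiate(norm, params)
  n <- length(sd$deriv)
  lo <- params$edge_exclude + 1L
  hi <- n - params$edge_exclude
  if (lo > hi)
    stop("invalid trace (well ", trace$well_id,
         "): edge_exclude leaves no interior samples", call. = FALSE)
  interior <- lo:hi
  k <- interior[which.min(sd$deriv[interior])]
  min_slope <- sd$deriv[k]
  drop_frac <- 1 - min(sd$smoothed)
  amplified <- (abs(min_slope) >= params$min_slope_mag) &&
    (min_slope < 0) && (drop_frac >= params$min_drop_frac)
  structure(list(well_id = trace$well_id, amplified = amplified,
                 tt_min = if (amplified) sd$times[k] else NA_real_,
                 drop_frac = drop_frac, min_slope = min_slope),
            class = "well_call")
}

#' @export
print.well_call <- function(x, ...) {
  if (x$amplified)
    cat(sprintf("<well_call> %s: amplified, Tt = %.2f min (drop %.1f%%, min slope %.3f/min)\n",
                x$well_id, x$tt_min, 100 * x$drop_frac, x$min_slope))
  else
    cat(sprintf("<well_call> %s: not amplified (drop %.1f%%, min slope %.3f/min)\n",
                x$well_id, 100 * x$drop_frac, x$min_slope))
  invisible(x)
}

#' Classify a well call against a Tt cutoff
#'
#' A well is POSITIVE iff it amplified and its Tt is within the cutoff
#' (swab panels use 15 min, sputum panels 20 min by default).
#'
#' @param call a [well_call].
#' @param cutoff_min cutoff in minutes, > 0.
#' @return `"POSITIVE"` or `"NEGATIVE"`.
#' @export
classify_well <- function(call, cutoff_min) {
  stopifnot(inherits(call, "well_call"))
  if (!is.numeric(cutoff_min) || length(cutoff_min) != 1L || cutoff_min <= 0)
    stop("cutoff_min must be a single positive number", call. = FALSE)
  if (isTRUE(call$amplified) && call$tt_min <= cutoff_min) "POSITIVE" else "NEGATIVE"
}
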