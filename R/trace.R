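#' Construct a fluorescence trace
#'
#' A `fluor_trace` holds one well's fluorescence signal sampled over reaction
#' time. Times are in minutes, fluorescence in arbitrary units (AU).
#'
#' @param well_id single character string, the well address (e.g. `"A1"`).
#' @param times numeric vector of sample times in minutes, strictly
#'   increasing, starting at or after 0, length >= 8.
#' @param values numeric vector of fluorescence readings, same length as
#'   `times`, all finite.
#'
#' @return An object of class `fluor_trace`: a list with elements `well_id`,
#'   `times`, `values`.
#' @examples
#' tr <- fluor_trace("A1", seq(0, 15, by = 1/6), rep(1000, 91))
#' tr
#' @export
fluor_trace <- function(well_id, times, values) {
  if (!is.character(well_id) || length(well_id) != 1L || is.na(well_id))
    stop("well_id must be a single character string", call. = FALSE)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) < 8L)
    stop("trace for well ", well_id, " has fewer than 8 samples", call. = FALSE)
  if (length(values) != length(times))
    stop("times and values differ in length for well ", well_id, call. = FALSE)
  if (anyNA(times) || any(!is.finite(times)) || times[1L] < 0)
    stop("times must be finite and start at >= 0 (well ", well_id, ")", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing (well ", well_id, ")", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("values must all be finite (well ", well_id, ")", call. = FALSE)
  structure(list(well_id = well_id, times = times, values = values),
            class = "fluor_trace")
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat("<fluor_trace> well", x$well_id, "-", length(x$times), "samples,",
      sprintf("t = [%.2f, %.2f] min,", x$times[1L], x$times[length(x$times)]),
      sprintf("F = [%.1f, %.1f] AU\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.fluor_trace <- function(x, ...) {
  plot(x$times, x$values, type = "l", xlab = "time (min)",
       ylab = "fluorescence (AU)", main = paste("well", x$well_id), ...)
  invisible(x)
}

#' Read per-well fluorescence traces from a long-format CSV
#'
#' The file must have header `time_min,well,fluorescence`, one row per
#' sample. Per-well times are validated to be strictly increasing; duplicate
#' `(well, time)` rows are rejected.
#'
#' @param path path to the CSV file.
#' @return A named list of [fluor_trace] objects, in lexicographic well
#'   order.
#' @seealso [write_traces()]
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "well", "fluorescence")
  if (!all(need %in% names(df)))
    stop("trace CSV must have header time_min,well,fluorescence", call. = FALSE)
  if (nrow(df) == 0L) stop("trace CSV is empty", call. = FALSE)
  if (!is.numeric(df$time_min) || !is.numeric(df$fluorescence)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$time_min))) |
                   is.na(suppressWarnings(as.numeric(df$fluorescence))))[1L]
    stop("non-numeric value in trace CSV at data line ", bad, call. = FALSE)
  }
  if (anyNA(df$time_min) || anyNA(df$fluorescence)) {
    bad <- which(is.na(df$time_min) | is.na(df$fluorescence))[1L]
    stop("missing value in trace CSV at data line ", bad, call. = FALSE)
  }
  wells <- sort(unique(df$well))
  out <- vector("list", length(wells))
  names(out) <- wells
  for (w in wells) {
    sub <- df[df$well == w, , drop = FALSE]
    if (anyDuplicated(sub$time_min)) {
      dup <- sub$time_min[duplicated(sub$time_min)][1L]
      stop("duplicated (well, time) row: well ", w, ", time ", dup, call. = FALSE)
    }
    if (is.unsorted(sub$time_min, strictly = TRUE))
      stop("non-monotone time for well ", w, call. = FALSE)
    out[[w]] <- fluor_trace(w, sub$time_min, sub$fluorescence)
  }
  out
}

#' Write traces to a long-format CSV
#'
#' @param traces a list of [fluor_trace] objects.
#' @param path output path.
#' @param wide if `TRUE`, write a wide matrix instead (first column
#'   `time_min`, one column per well); wells must then share a time grid.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, wide = FALSE) {
  stopifnot(length(traces) >= 1L)
  traces <- traces[order(vapply(traces, `[[`, "", "well_id"))]
  if (wide) {
    t0 <- traces[[1L]]$times
    for (tr in traces)
      if (!isTRUE(all.equal(tr$times, t0)))
        stop("wide export requires a shared time grid", call. = FALSE)
    m <- data.frame(time_min = t0)
    for (tr in traces) m[[tr$well_id]] <- tr$values
    utils::write.csv(m, path, row.names = FALSE)
  } else {
    df <- do.call(rbind, lapply(traces, function(tr)
      data.frame(time_min = tr$times, well = tr$well_id,
                 fluorescence = tr$values)))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
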