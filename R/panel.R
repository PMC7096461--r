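well_addresses <- function() {
  as.vector(outer(LETTERS[1:5], 1:5, paste0))
}

#' Define a 25-well panel layout
#'
#' A layout maps each of the chip's 25 wells (addresses A1-E5) to an item
#' label or to `"UNUSED"`, optionally designates one item as the run
#' control, and carries the per-sample-type Tt cutoffs in minutes.
#'
#' @param wells named character vector: names are the 25 well addresses,
#'   values are item labels or `"UNUSED"`.
#' @param control_item item label of the run control, or `NULL` if the
#'   panel has none.
#' @param cutoffs named numeric vector of positive Tt cutoffs (minutes),
#'   one per sample type.
#' @return An object of class `panel_layout` with elements `wells`,
#'   `items` (named list: item -> member well addresses), `control_item`,
#'   `cutoffs`.
#' @seealso [default_layout()], [read_layout()]
#' @export
panel_layout <- function(wells, control_item = NULL,
                         cutoffs = c(swab = 15, sputum = 20)) {
  addr <- well_addresses()
  if (!is.character(wells) || is.null(names(wells)))
    stop("wells must be a named character vector", call. = FALSE)
  if (length(wells) != 25L || !setequal(names(wells), addr))
    stop("layout must assign exactly the 25 well addresses A1-E5", call. = FALSE)
  if (anyDuplicated(names(wells)))
    stop("duplicated well address in layout", call. = FALSE)
  wells <- wells[addr]  # canonical order
  item_labels <- setdiff(unique(wells), "UNUSED")
  if (length(item_labels) == 0L)
    stop("layout has no items", call. = FALSE)
  if (!is.null(control_item)) {
    stopifnot(is.character(control_item), length(control_item) == 1L)
    if (!control_item %in% item_labels)
      stop("control_item ", control_item, " has no wells in the layout", call. = FALSE)
  }
  if (!is.numeric(cutoffs) || is.null(names(cutoffs)) || any(cutoffs <= 0))
    stop("cutoffs must be a named numeric vector of positive minutes", call. = FALSE)
  items <- lapply(item_labels, function(it) names(wells)[wells == it])
  names(items) <- item_labels
  structure(list(wells = wells, items = items, control_item = control_item,
                 cutoffs = cutoffs),
            class = "panel_layout")
}

#' Default respiratory panel layout
#'
#' Four bacterial items (BP = B. pertussis, MP = M. pneumoniae,
#' CP = C. pneumoniae, LP = L. pneumophila) occupy five wells each, one
#' well column per item, with the fifth column given to the internal
#' control IC. The geometric arrangement (which wells hold which item) is
#' a package convention, not an instrument map.
#'
#' @return A [panel_layout].
#' @export
default_layout <- function() {
  wells <- character(25L)
  names(wells) <- well_addresses()
  cols <- c("BP", "MP", "CP", "LP", "IC")
  for (j in 1:5) wells[paste0(LETTERS[1:5], j)] <- cols[j]
  panel_layout(wells, control_item = "IC")
}

#' Read a panel layout from JSON
#'
#' Expected schema:
#' `{"wells": {"A1": "BP", ...}, "control_item": "IC",
#'   "cutoffs": {"swab": 15, "sputum": 20}}`.
#' `control_item` may be omitted.
#'
#' @param path path to the JSON file.
#' @return A validated [panel_layout].
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("wells", "control_item", "cutoffs")
  extra <- setdiff(names(j), known)
  if (length(extra))
    stop("unknown layout keys: ", paste(extra, collapse = ", "), call. = FALSE)
  if (is.null(j$wells) || is.null(j$cutoffs))
    stop("layout JSON needs 'wells' and 'cutoffs'", call. = FALSE)
  panel_layout(unlist(j$wells), control_item = j$control_item,
               cutoffs = unlist(j$cutoffs))
}

#' Write a panel layout to JSON
#'
#' @param layout a [panel_layout].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "panel_layout"))
  obj <- list(wells = as.list(layout$wells), cutoffs = as.list(layout$cutoffs))
  if (!is.null(layout$control_item)) obj$control_item <- layout$control_item
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.panel_layout <- function(x, ...) {
  cat("<panel_layout> 25 wells,", length(x$items), "items:",
      paste(sprintf("%s(%d)", names(x$items), lengths(x$items)), collapse = " "),
      "\n")
  if (!is.null(x$control_item)) cat("  control item:", x$control_item, "\n")
  cat("  cutoffs:", paste(sprintf("%s=%g min", names(x$cutoffs), x$cutoffs),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Call a full chip run at item level
#'
#' Tt-calls every layout well, classifies each against the sample type's
#' cutoff, and aggregates: an item is POSITIVE iff at least one of its
#' member wells is positive (the chip's multi-well sensitivity rule), and
#' the co-infection flag is raised iff two or more non-control items are
#' simultaneously positive. Run validity is then assessed via
#' [validate_run()].
#'
#' @param traces named list of [fluor_trace] objects covering every
#'   non-UNUSED layout well (names or `well_id`s are the addresses).
#' @param layout a [panel_layout].
#' @param sample_type sample-type label, must be a name of
#'   `layout$cutoffs` (e.g. `"swab"` or `"sputum"`).
#' @param caller_params a [caller_params].
#' @param strict_control passed to [validate_run()].
#' @return An object of class `panel_result`.
#' @export
call_panel <- function(traces, layout, sample_type,
                       caller_params = lampanel::caller_params(),
                       strict_control = FALSE) {
  stopifnot(inherits(layout, "panel_layout"))
  if (!sample_type %in% names(layout$cutoffs))
    stop("configuration error: unknown sample_type '", sample_type,
         "' (cutoffs defined for: ",
         paste(names(layout$cutoffs), collapse = ", "), ")", call. = FALSE)
  cutoff <- layout$cutoffs[[sample_type]]
  ids <- vapply(traces, `[[`, "", "well_id")
  names(traces) <- ids
  needed <- names(layout$wells)[layout$wells != "UNUSED"]
  missing <- setdiff(needed, ids)
  if (length(missing))
    stop("incomplete run: no trace for well(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  item_results <- lapply(names(layout$items), function(it) {
    calls <- lapply(layout$items[[it]], function(w) call_tt(traces[[w]], caller_params))
    status <- vapply(calls, classify_well, "", cutoff_min = cutoff)
    npos <- sum(status == "POSITIVE")
    list(status = if (npos >= 1L) "POSITIVE" else "NEGATIVE",
         positive_well_count = npos, well_calls = calls)
  })
  names(item_results) <- names(layout$items)
  targets <- setdiff(names(item_results), layout$control_item)
  n_pos_targets <- sum(vapply(item_results[targets], `[[`, "", "status") == "POSITIVE")
  res <- structure(list(run_valid = NA, sample_type = sample_type,
                        cutoff_min = cutoff, item_results = item_results,
                        coinfection = n_pos_targets >= 2L),
                   class = "panel_result")
  validate_run(res, layout, strict = strict_control)
}

#' Validate a panel result against its run control
#'
#' Default rule: if the layout names a control item, the run is valid when
#' the control fired OR any non-control item fired (target amplification
#' itself evidences a working reaction); with `strict = TRUE` the control
#' must fire unconditionally. Layouts without a control are always valid.
#' An invalid run keeps its item statuses but is flagged INVALID for
#' reporting.
#'
#' @param result a `panel_result` from [call_panel()].
#' @param layout the [panel_layout] used for the run.
#' @param strict require the control item itself to be POSITIVE.
#' @return The `panel_result` with `run_valid` set.
#' @export
validate_run <- function(result, layout, strict = FALSE) {
  stopifnot(inherits(result, "panel_result"), inherits(layout, "panel_layout"))
  if (is.null(layout$control_item)) {
    result$run_valid <- TRUE
    return(result)
  }
  statuses <- vapply(result$item_results, `[[`, "", "status")
  control_pos <- identical(statuses[[layout$control_item]], "POSITIVE")
  target_pos <- any(statuses[setdiff(names(statuses), layout$control_item)] == "POSITIVE")
  result$run_valid <- if (strict) control_pos else control_pos || target_pos
  result
}

#' @export
print.panel_result <- function(x, ...) {
  cat("<panel_result>", if (isTRUE(x$run_valid)) "VALID" else "INVALID",
      "run, sample type", x$sample_type,
      sprintf("(cutoff %g min)\n", x$cutoff_min))
  for (it in names(x$item_results)) {
    r <- x$item_results[[it]]
    n <- length(r$well_calls)
    cat(sprintf("  %-4s %-8s %d/%d wells positive\n", it, r$status,
                r$positive_well_count, n))
  }
  if (isTRUE(x$coinfection)) cat("  co-infection flag raised\n")
  invisible(x)
}

#' @export
summary.panel_result <- function(object, ...) {
  rows <- lapply(names(object$item_results), function(it) {
    r <- object$item_results[[it]]
    tts <- vapply(r$well_calls, `[[`, 0, "tt_min")
    data.frame(item = it, status = r$status,
               positive_wells = r$positive_well_count,
               n_wells = length(r$well_calls),
               median_tt_min = stats::median(tts, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  attr(out, "run_valid") <- object$run_valid
  attr(out, "coinfection") <- object$coinfection
  out
}

#' Flatten a panel result for export
#'
#' @param x a `panel_result`.
#' @param ... unused.
#' @return data.frame with one row per well: item, well, status, Tt and
#'   quality metrics.
#' @export
as.data.frame.panel_result <- function(x, ...) {
  rows <- list()
  for (it in names(x$item_results)) {
    r <- x$item_results[[it]]
    for (wc in r$well_calls) {
      rows[[length(rows) + 1L]] <- data.frame(
        item = it, well = wc$well_id, amplified = wc$amplified,
        tt_min = wc$tt_min, drop_frac = wc$drop_frac,
        min_slope = wc$min_slope,
        status = if (wc$amplified && wc$tt_min <= x$cutoff_min) "POSITIVE" else "NEGATIVE")
    }
  }
  do.call(rbind, rows)
}

#' Write a panel result to JSON (and optionally TSV)
#'
#' The JSON carries run metadata (validity, sample type, cutoff,
#' co-infection flag), per-item statuses and the per-well Tt table; the
#' TSV holds the per-well table only.
#'
#' @param result a `panel_result`.
#' @param path output JSON path.
#' @param tsv_path optional TSV path for the per-well table.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path, tsv_path = NULL) {
  stopifnot(inherits(result, "panel_result"))
  wells <- as.data.frame(result)
  obj <- list(
    tool = "lampanel",
    tool_version = as.character(utils::packageVersion("lampanel")),
    run_valid = result$run_valid,
    sample_type = result$sample_type,
    cutoff_min = result$cutoff_min,
    coinfection = result$coinfection,
    items = lapply(result$item_results, function(r)
      list(status = r$status, positive_well_count = r$positive_well_count)),
    wells = wells)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  if (!is.null(tsv_path))
    utils::write.table(wells, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
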