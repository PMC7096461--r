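#' Construct a dilution-series replicate grid
#'
#' A `dilution_grid` records, for one item, how many of an item's wells
#' amplified in each repeated run of a dilution ladder: one row per
#' (series, concentration, run), with `positive_wells` out of `n_wells`.
#' Concentrations are template copies per well (cps/well).
#'
#' @param item item label.
#' @param records data.frame with columns `series`, `conc`, `run`,
#'   `positive_wells`, `n_wells`.
#' @return An object of class `dilution_grid` (a validated data.frame with
#'   attribute `item`).
#' @export
dilution_grid <- function(item, records) {
  stopifnot(is.character(item), length(item) == 1L)
  need <- c("series", "conc", "run", "positive_wells", "n_wells")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("records needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(records) == 0L) stop("empty dilution grid", call. = FALSE)
  rec <- records[, need]
  if (any(rec$conc <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (any(rec$n_wells < 1L)) stop("n_wells must be >= 1", call. = FALSE)
  if (any(rec$positive_wells < 0L | rec$positive_wells > rec$n_wells))
    stop("positive_wells must lie in [0, n_wells]", call. = FALSE)
  if (anyDuplicated(rec[, c("series", "conc", "run")]))
    stop("duplicated (series, conc, run) record", call. = FALSE)
  structure(rec, item = item, class = c("dilution_grid", "data.frame"))
}

#' @export
print.dilution_grid <- function(x, ...) {
  cat("<dilution_grid>", attr(x, "item"), "-", nrow(x), "records,",
      length(unique(x$series)), "series,",
      length(unique(x$conc)), "concentrations",
      sprintf("[%.2f, %.2f] cps/well\n", min(x$conc), max(x$conc)))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("  ...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' Pooled concentration ladder of a grid
#'
#' The distinct tested concentrations across ALL dilution series, sorted
#' descending. With the packaged respiratory-panel fixture this is the
#' 15-value ladder 15.00, 12.50, 10.00, ..., 0.63 cps/well.
#'
#' @param grid a [dilution_grid].
#' @return Numeric vector of concentrations, descending.
#' @export
pooled_ladder <- function(grid) {
  stopifnot(inherits(grid, "dilution_grid"))
  sort(unique(grid$conc), decreasing = TRUE)
}

#' Estimate the limit of detection by the all-negative-run step rule
#'
#' A run with `positive_wells = 0` is an "all-negative run". The rule finds
#' the HIGHEST concentration showing any all-negative run (the triggering
#' concentration) and reports the LoD as the next concentration ABOVE it on
#' the ladder — i.e. one concentration step back up from the first failure.
#' If no run anywhere was all-negative, the LoD is below the tested range
#' and is reported as "< min(ladder)"; if the top concentration itself has
#' an all-negative run, the LoD is not determinable within the range.
#'
#' By default the step is taken on the POOLED ladder (union of all series'
#' concentrations); `mode = "within-series"` instead steps within the
#' ladder of a series that produced the triggering run (when several did,
#' the smallest such step is used).
#'
#' @param grid a [dilution_grid].
#' @param mode `"pooled"` (default) or `"within-series"`.
#' @return An object of class `lod_estimate`: list with `item`,
#'   `lod_cps_per_well`, `bound` (one of `"EXACT_STEP"`, `"BELOW_RANGE"`,
#'   `"ABOVE_RANGE"`) and `triggering_conc` (`NA` when `bound =
#'   "BELOW_RANGE"`).
#' @examples
#' grids <- load_fixture_table1()
#' estimate_lod(grids$BP)   # 1.56 cps/well
#' estimate_lod(grids$MP)   # < 0.63 cps/well
#' @export
estimate_lod <- function(grid, mode = c("pooled", "within-series")) {
  stopifnot(inherits(grid, "dilution_grid"))
  mode <- match.arg(mode)
  item <- attr(grid, "item")
  ladder <- pooled_ladder(grid)
  zero_runs <- grid[grid$positive_wells == 0L, , drop = FALSE]
  if (nrow(zero_runs) == 0L) {
    return(structure(list(item = item, lod_cps_per_well = min(ladder),
                          bound = "BELOW_RANGE", triggering_conc = NA_real_),
                     class = "lod_estimate"))
  }
  trig <- max(zero_runs$conc)
  if (trig >= max(ladder)) {
    return(structure(list(item = item, lod_cps_per_well = NA_real_,
                          bound = "ABOVE_RANGE", triggering_conc = trig),
                     class = "lod_estimate"))
  }
  lod <- if (mode == "pooled") {
    min(ladder[ladder > trig])
  } else {
    trig_series <- unique(zero_runs$series[zero_runs$conc == trig])
    steps <- vapply(trig_series, function(s) {
      lad_s <- sort(unique(grid$conc[grid$series == s]), decreasing = TRUE)
      above <- lad_s[lad_s > trig]
      if (length(above)) min(above) else NA_real_
    }, 0)
    if (all(is.na(steps))) {
      # triggering conc tops its own series; fall back to the pooled step
      min(ladder[ladder > trig])
    } else min(steps, na.rm = TRUE)
  }
  structure(list(item = item, lod_cps_per_well = lod, bound = "EXACT_STEP",
                 triggering_conc = trig),
            class = "lod_estimate")
}

#' @export
print.lod_estimate <- function(x, ...) {
  cat("<lod_estimate>", x$item, "LoD:", format(x), "\n")
  if (x$bound == "EXACT_STEP")
    cat(sprintf("  triggering concentration (highest with an all-negative run): %.2f cps/well\n",
                x$triggering_conc))
  invisible(x)
}

#' @export
format.lod_estimate <- function(x, ...) {
  switch(x$bound,
         EXACT_STEP = sprintf("%.2f cps/well", x$lod_cps_per_well),
         BELOW_RANGE = sprintf("< %.2f cps/well", x$lod_cps_per_well),
         ABOVE_RANGE = sprintf("> %.2f cps/well (not determinable in tested range)",
                               x$triggering_conc))
}

#' Per-concentration hit-rate summary
#'
#' Pools wells across series and runs at each tested concentration.
#'
#' @param grid a [dilution_grid].
#' @return data.frame with columns `conc`, `runs`, `total_wells`,
#'   `positive_wells`, `hit_rate`, sorted by descending concentration.
#' @export
hit_rate_summary <- function(grid) {
  stopifnot(inherits(grid, "dilution_grid"))
  concs <- pooled_ladder(grid)
  rows <- lapply(concs, function(cc) {
    sub <- grid[grid$conc == cc, , drop = FALSE]
    tot <- sum(sub$n_wells)
    pos <- sum(sub$positive_wells)
    data.frame(conc = cc, runs = nrow(sub), total_wells = tot,
               positive_wells = pos, hit_rate = pos / tot)
  })
  do.call(rbind, rows)
}

#' Fit a per-copy detection-efficiency model to a dilution grid
#'
#' Models the per-well positivity probability as `p(lambda) = 1 -
#' exp(-e * lambda)` — Poisson-distributed copies per well, each detected
#' independently with probability `e` — and fits `e` by maximum likelihood
#' to the binomial well counts. `lod95 = -ln(0.05)/e` is the concentration
#' with 95% per-well detection.
#'
#' @param grid a [dilution_grid].
#' @return An object of class `det_eff_fit`: list with `efficiency`,
#'   `lod95`, `loglik`, `n_records`.
#' @export
fit_detection_efficiency <- function(grid) {
  stopifnot(inherits(grid, "dilution_grid"))
  pos <- grid$positive_wells
  n <- grid$n_wells
  lam <- grid$conc
  if (all(pos == n) || all(pos == 0L))
    stop("non-identifiable: hit rate is ",
         if (all(pos == 0L)) "0" else "1", " at every record", call. = FALSE)
  nll <- function(log_e) {
    p <- -expm1(-exp(log_e) * lam)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)  # keep the likelihood finite at the edges
    -sum(stats::dbinom(pos, n, p, log = TRUE))
  }
  opt <- stats::optimize(nll, interval = c(log(1e-6), log(1e4)))
  e <- exp(opt$minimum)
  structure(list(efficiency = e, lod95 = -log(0.05) / e,
                 loglik = -opt$objective, n_records = nrow(grid)),
            class = "det_eff_fit")
}

#' @export
print.det_eff_fit <- function(x, ...) {
  cat(sprintf("<det_eff_fit> per-copy detection efficiency e = %.3f\n", x$efficiency))
  cat(sprintf("  lod95 (95%% per-well detection) = %.3f cps/well\n", x$lod95))
  cat(sprintf("  log-likelihood %.2f over %d records\n", x$loglik, x$n_records))
  invisible(x)
}

#' Read a dilution grid CSV
#'
#' Header: `item,series,conc_cps_per_well,run,positive_wells,n_wells`. The
#' file may hold several items; one grid is returned per item.
#'
#' @param path CSV path.
#' @return Named list of [dilution_grid] objects.
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("grid file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item", "series", "conc_cps_per_well", "run", "positive_wells", "n_wells")
  if (!all(need %in% names(df)))
    stop("grid CSV must have header ", paste(need, collapse = ","), call. = FALSE)
  items <- unique(df$item)
  out <- lapply(items, function(it) {
    sub <- df[df$item == it, , drop = FALSE]
    dilution_grid(it, data.frame(series = sub$series,
                                 conc = sub$conc_cps_per_well,
                                 run = sub$run,
                                 positive_wells = sub$positive_wells,
                                 n_wells = sub$n_wells))
  })
  names(out) <- items
  out
}

#' Write dilution grids to CSV
#'
#' @param grids a [dilution_grid] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grids, path) {
  if (inherits(grids, "dilution_grid")) grids <- list(grids)
  df <- do.call(rbind, lapply(grids, function(g)
    data.frame(item = attr(g, "item"), series = g$series,
               conc_cps_per_well = g$conc, run = g$run,
               positive_wells = g$positive_wells, n_wells = g$n_wells)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Load the packaged respiratory-panel limit-of-detection fixture
#'
#' A transcription of the published dilution-replicate table for the
#' four-bacterium respiratory panel: for each item (BP, MP, CP, LP), three
#' dilution series of five concentrations, each tested in five runs of five
#' wells, recorded as positive wells out of five. Structural integrity
#' (record counts, ranges, known anchor cells) is verified on load.
#'
#' @return Named list of four [dilution_grid] objects (BP, MP, CP, LP).
#' @export
load_fixture_table1 <- function() {
  path <- system.file("extdata", "table1_respiratory_panel.csv",
                      package = "lampanel", mustWork = TRUE)
  grids <- read_grid(path)
  ok <- setequal(names(grids), c("BP", "MP", "CP", "LP")) &&
    all(vapply(grids, nrow, 0L) == 75L) &&
    all(vapply(grids, function(g) all(g$n_wells == 5L), NA)) &&
    all(vapply(grids, function(g) length(pooled_ladder(g)) == 15L, NA)) &&
    all(grids$BP$positive_wells[grids$BP$conc == 15] == 5L) &&
    all(grids$MP$positive_wells > 0L)
  if (!ok)
    stop("integrity error: packaged fixture failed structural validation",
         call. = FALSE)
  grids
}
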