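#' Poisson occupancy model of template partitioning
#'
#' At concentrations near the limit of detection the handful of template
#' copies in the eluate lands unevenly across an item's wells. The model:
#' copies per well ~ Poisson(lambda), each copy detected independently with
#' probability `p_det`, a well is positive iff it holds at least one
#' detected copy, and an item of `n_wells` wells is positive iff at least
#' one well is.
#'
#' @param lambda_cps_per_well mean template copies per well (>= 0).
#' @param p_det per-copy detection probability in (0, 1]. Default 1
#'   (single-copy detection).
#' @param n_wells wells per item (>= 1). Default 5.
#' @return An object of class `occupancy_model`.
#' @examples
#' m <- occupancy_model(0.94)
#' p_well_positive(m)   # 1 - exp(-0.94) = 0.609
#' p_item_positive(m)   # 1 - exp(-4.7)  = 0.991
#' @export
occupancy_model <- function(lambda_cps_per_well, p_det = 1, n_wells = 5L) {
  if (!is.numeric(lambda_cps_per_well) || lambda_cps_per_well < 0)
    stop("lambda must be >= 0", call. = FALSE)
  if (p_det <= 0 || p_det > 1) stop("p_det must be in (0, 1]", call. = FALSE)
  n_wells <- as.integer(n_wells)
  if (n_wells < 1L) stop("n_wells must be >= 1", call. = FALSE)
  structure(list(lambda = lambda_cps_per_well, p_det = p_det,
                 n_wells = n_wells),
            class = "occupancy_model")
}

#' @export
print.occupancy_model <- function(x, ...) {
  cat(sprintf("<occupancy_model> lambda = %g cps/well, p_det = %g, n = %d wells\n",
              x$lambda, x$p_det, x$n_wells))
  cat(sprintf("  P(well positive) = %.4f, P(item positive) = %.4f\n",
              p_well_positive(x), p_item_positive(x)))
  invisible(x)
}

#' Probability that one well is positive
#'
#' `1 - exp(-lambda * p_det)`: a well fails only if every copy it received
#' goes undetected, and thinned Poisson arrivals have rate `lambda * p_det`.
#'
#' @param model an [occupancy_model].
#' @return Probability in `[0, 1)`.
#' @export
p_well_positive <- function(model) {
  stopifnot(inherits(model, "occupancy_model"))
  -expm1(-model$lambda * model$p_det)
}

#' Distribution of the number of positive wells
#'
#' With independent wells, the positive-well count K over an item's
#' `n_wells` wells is Binomial(n_wells, p_well_positive).
#'
#' @param model an [occupancy_model].
#' @return Named numeric vector: `P(K = k)` for `k = 0..n_wells`.
#' @export
pmf_positive_wells <- function(model) {
  stopifnot(inherits(model, "occupancy_model"))
  k <- 0:model$n_wells
  stats::setNames(stats::dbinom(k, model$n_wells, p_well_positive(model)),
                  as.character(k))
}

#' Probability that the item is positive
#'
#' At least one of `n_wells` wells positive: `1 - (1 - p_well)^n`. This is
#' the sensitivity gain the multi-well design buys at low copy number.
#'
#' @param model an [occupancy_model].
#' @return Probability in `[0, 1)`.
#' @export
p_item_positive <- function(model) {
  stopifnot(inherits(model, "occupancy_model"))
  1 - (1 - p_well_positive(model))^model$n_wells
}

#' Monte-Carlo occupancy simulation
#'
#' Draws copies ~ Poisson(lambda) per well, thins each well's copies with
#' `p_det`, and counts wells with at least one detected copy; the empirical
#' distribution of that count is returned. Reproducible under a fixed seed.
#'
#' @param model an [occupancy_model].
#' @param reps number of simulated items (>= 1).
#' @param seed integer RNG seed.
#' @return Named numeric vector: empirical `P(K = k)` for `k = 0..n_wells`.
#' @export
simulate_occupancy <- function(model, reps, seed) {
  stopifnot(inherits(model, "occupancy_model"), reps >= 1L)
  with_seed(seed, {
    copies <- matrix(stats::rpois(reps * model$n_wells, model$lambda),
                     nrow = reps)
    detected <- if (model$p_det < 1) {
      matrix(stats::rbinom(length(copies), copies, model$p_det),
             nrow = reps)
    } else copies
    k <- rowSums(detected >= 1L)
    tab <- tabulate(k + 1L, nbins = model$n_wells + 1L)
    stats::setNames(tab / reps, as.character(0:model$n_wells))
  })
}
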