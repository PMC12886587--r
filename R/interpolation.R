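#' Interpolation grid specification
#'
#' Defines the uniform time grid all scans are standardised to before any
#' network is built. The default spans 14 to 2416 seconds post-injection
#' with 240 equally spaced points, i.e. roughly 40 minutes sampled about
#' every 10 seconds; scans acquired with different frame schedules are
#' linearly interpolated onto this grid.
#'
#' @param t_start,t_end Grid endpoints in seconds (`t_start < t_end`).
#' @param n_points Number of grid points (at least 2).
#' @return An object of class `interpolation_spec` with a `grid` element
#'   `t_start + i * (t_end - t_start) / (n_points - 1)`, `i = 0 .. n_points-1`.
#' @export
interpolation_spec <- function(t_start = 14, t_end = 2416, n_points = 240) {
  stopifnot(t_start < t_end, n_points >= 2)
  n_points <- as.integer(n_points)
  grid <- t_start + (seq_len(n_points) - 1L) * (t_end - t_start) /
    (n_points - 1L)
  structure(list(t_start = t_start, t_end = t_end, n_points = n_points,
                 grid = grid),
            class = "interpolation_spec")
}

#' Linearly interpolate a raw TAC onto a standard grid
#'
#' Piecewise-linear interpolation of an irregularly sampled time-activity
#' curve onto the uniform grid of `spec`. Linear interpolation is used so the
#' curve is not smoothed; raw samples that coincide with grid points are
#' reproduced exactly. No extrapolation is performed: the raw samples must
#' cover the full grid span.
#'
#' @param raw_times Strictly increasing sample times in seconds (length >= 2).
#' @param raw_values SUV values at `raw_times`.
#' @param spec An [interpolation_spec()].
#' @return Numeric vector of SUV values on `spec$grid`.
#' @export
interpolate_tac <- function(raw_times, raw_values,
                            spec = interpolation_spec()) {
  stopifnot(length(raw_times) == length(raw_values), length(raw_times) >= 2)
  if (is.unsorted(raw_times, strictly = TRUE))
    stop("raw_times must be strictly increasing")
  if (raw_times[1L] > spec$t_start ||
      raw_times[length(raw_times)] < spec$t_end)
    stop(sprintf(
      "raw samples cover [%g, %g] s but the grid requires [%g, %g] s; %s",
      raw_times[1L], raw_times[length(raw_times)], spec$t_start, spec$t_end,
      "no extrapolation is performed"))
  stats::approx(raw_times, raw_values, xout = spec$grid, method = "linear",
                ties = "ordered")$y
}

#' Static SUV: mean uptake over the end of the scan
#'
#' The static (equilibrium) SUV of a curve is the arithmetic mean of all grid
#' samples in the final `window_s` seconds of the standard grid, i.e. samples
#' with time >= `t_end - window_s` (inclusive). With the default grid and the
#' default ten-minute window this averages the last 60 samples.
#'
#' @param tac SUV values on `spec$grid`.
#' @param spec An [interpolation_spec()].
#' @param window_s Averaging window in seconds (default 600, the last ten
#'   minutes).
#' @return Scalar static SUV.
#' @export
static_suv <- function(tac, spec = interpolation_spec(), window_s = 600) {
  stopifnot(length(tac) == spec$n_points)
  if (window_s <= 0 || window_s > spec$t_end - spec$t_start)
    stop("window_s must lie in (0, t_end - t_start]")
  sel <- spec$grid >= spec$t_end - window_s
  if (!any(sel)) stop("averaging window contains no grid samples")
  mean(tac[sel])
}

#' Combine regional TAC matrices into one composite region
#'
#' Element-wise (unweighted) mean across regions, subject by subject and time
#' point by time point. Used for composite signals such as the blood pool
#' (aorta + ventricle) or the pooled left + right kidneys.
#'
#' @param tacs List of [tac_matrix()] objects sharing subject order, group
#'   labels and time grid.
#' @param region_label Label for the combined region; default joins the input
#'   labels with `"+"`.
#' @return A [tac_matrix()].
#' @export
combine_regions <- function(tacs, region_label = NULL) {
  stopifnot(is.list(tacs), length(tacs) >= 1)
  lapply(tacs, function(t) stopifnot(inherits(t, "tac_matrix")))
  ref <- tacs[[1L]]
  for (t in tacs[-1L]) {
    if (!identical(t$subject_ids, ref$subject_ids))
      stop("subject sets/order differ between regions")
    if (!identical(t$group_labels, ref$group_labels))
      stop("group labels differ between regions")
    if (!isTRUE(all.equal(t$time_grid, ref$time_grid)))
      stop("time grids differ between regions")
  }
  if (is.null(region_label))
    region_label <- paste(vapply(tacs, `[[`, "", "region_label"),
                          collapse = "+")
  vals <- Reduce(`+`, lapply(tacs, `[[`, "values")) / length(tacs)
  tac_matrix(region_label, ref$subject_ids, ref$group_labels, ref$time_grid,
             vals)
}

#' Build the static SUV table from per-region TAC matrices
#'
#' Applies [static_suv()] to every subject curve in every region and
#' assembles the subjects x regions table the s-network and delta-PCC
#' methods consume.
#'
#' @param tacs List of [tac_matrix()] objects on a common grid with a common
#'   subject set.
#' @param spec An [interpolation_spec()] describing the shared grid.
#' @param window_s Averaging window in seconds (default 600).
#' @return A [region_suv_table()].
#' @export
static_table <- function(tacs, spec = interpolation_spec(), window_s = 600) {
  stopifnot(is.list(tacs), length(tacs) >= 1)
  ref <- tacs[[1L]]
  vals <- vapply(tacs, function(t) {
    if (!identical(t$subject_ids, ref$subject_ids))
      stop("subject sets/order differ between regions")
    apply(t$values, 1L, static_suv, spec = spec, window_s = window_s)
  }, numeric(length(ref$subject_ids)))
  region_suv_table(ref$subject_ids, ref$group_labels,
                   vapply(tacs, `[[`, "", "region_label"),
                   matrix(vals, nrow = length(ref$subject_ids)))
}
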