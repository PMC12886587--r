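#' Dynamic time-activity-curve matrix for one region
#'
#' Container for the dynamic data of a single tissue region: one row of SUV
#' values per subject on a common time grid (seconds post-injection), plus
#' group labels. SUV (standardised uptake value) is dimensionless, already
#' normalised upstream for injected dose and body weight.
#'
#' @param region_label Name of the tissue region (free text, e.g. "liver").
#' @param subject_ids Character vector of unique subject identifiers.
#' @param group_labels Character vector aligned to `subject_ids`; must contain
#'   at most two distinct labels (e.g. "control" and "rifampicin").
#' @param time_grid Strictly increasing numeric vector of sample times in
#'   seconds post-injection.
#' @param values Numeric matrix, subjects x time points, of SUV values. All
#'   values must be finite and non-negative.
#'
#' @return An object of class `tac_matrix`.
#' @export
tac_matrix <- function(region_label, subject_ids, group_labels, time_grid,
                       values) {
  values <- as.matrix(values)
  stopifnot(is.character(region_label), length(region_label) == 1L)
  subject_ids <- as.character(subject_ids)
  group_labels <- as.character(group_labels)
  if (anyDuplicated(subject_ids))
    stop("duplicate subject id: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  if (length(group_labels) != length(subject_ids))
    stop("group_labels must align with subject_ids")
  if (length(unique(group_labels)) > 2L)
    stop("group_labels must contain at most two categories")
  if (is.unsorted(time_grid, strictly = TRUE))
    stop("time_grid must be strictly increasing")
  if (nrow(values) != length(subject_ids))
    stop("values must have one row per subject")
  if (ncol(values) != length(time_grid))
    stop("values must have one column per time point")
  if (!all(is.finite(values)))
    stop("all SUV values must be finite")
  if (any(values < 0))
    stop("SUV values must be non-negative")
  dimnames(values) <- list(subject_ids, NULL)
  structure(
    list(region_label = region_label, subject_ids = subject_ids,
         group_labels = group_labels, time_grid = as.numeric(time_grid),
         values = values),
    class = "tac_matrix")
}

#' @export
print.tac_matrix <- function(x, ...) {
  cat(sprintf("<tac_matrix> region '%s': %d subjects x %d time points (%g-%g s)\n",
              x$region_label, length(x$subject_ids), length(x$time_grid),
              min(x$time_grid), max(x$time_grid)))
  cat("  groups:", paste(sprintf("%s (n=%d)", names(table(x$group_labels)),
                                 table(x$group_labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Static regional SUV table
#'
#' Container for the static data: one row per subject, one column per region,
#' each cell the subject's equilibrium SUV in that region (the mean uptake
#' over the last ten minutes of the interpolated curve).
#'
#' @param subject_ids Character vector of unique subject identifiers.
#' @param group_labels Character vector aligned to `subject_ids` (at most two
#'   distinct labels).
#' @param region_labels Character vector of unique region names.
#' @param values Numeric matrix, subjects x regions, finite and non-negative.
#'
#' @return An object of class `region_suv_table`.
#' @export
region_suv_table <- function(subject_ids, group_labels, region_labels,
                             values) {
  values <- as.matrix(values)
  subject_ids <- as.character(subject_ids)
  group_labels <- as.character(group_labels)
  region_labels <- as.character(region_labels)
  if (anyDuplicated(subject_ids))
    stop("duplicate subject id: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  if (anyDuplicated(region_labels))
    stop("region labels must be unique")
  if (length(group_labels) != length(subject_ids))
    stop("group_labels must align with subject_ids")
  if (length(unique(group_labels)) > 2L)
    stop("group_labels must contain at most two categories")
  if (nrow(values) != length(subject_ids) ||
      ncol(values) != length(region_labels))
    stop("values must be subjects x regions")
  if (!all(is.finite(values)))
    stop("all SUV values must be finite")
  if (any(values < 0))
    stop("SUV values must be non-negative")
  dimnames(values) <- list(subject_ids, region_labels)
  structure(
    list(subject_ids = subject_ids, group_labels = group_labels,
         region_labels = region_labels, values = values),
    class = "region_suv_table")
}

#' @export
print.region_suv_table <- function(x, ...) {
  cat(sprintf("<region_suv_table> %d subjects x %d regions\n",
              length(x$subject_ids), length(x$region_labels)))
  cat("  regions:", paste(x$region_labels, collapse = ", "), "\n")
  cat("  groups:", paste(sprintf("%s (n=%d)", names(table(x$group_labels)),
                                 table(x$group_labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Drop named regions from a static SUV table
#'
#' Used to remove anomalous regions (in the glyburide study, the gallbladder,
#' whose filling varies person to person independent of treatment) before
#' building an s-network.
#'
#' @param table A [region_suv_table()].
#' @param regions Character vector of region labels to exclude.
#' @return A `region_suv_table` without the named regions.
#' @export
exclude_regions <- function(table, regions) {
  stopifnot(inherits(table, "region_suv_table"))
  if (length(regions) == 0L) return(table)
  missing <- setdiff(regions, table$region_labels)
  if (length(missing))
    stop("unknown region(s): ", paste(missing, collapse = ", "))
  keep <- !(table$region_labels %in% regions)
  region_suv_table(table$subject_ids, table$group_labels,
                   table$region_labels[keep],
                   table$values[, keep, drop = FALSE])
}

#' Restrict a static SUV table to a subset of subjects
#'
#' @param table A [region_suv_table()].
#' @param subjects Character vector of subject ids to keep (order preserved
#'   from the table).
#' @return A `region_suv_table`.
#' @export
subset_subjects <- function(table, subjects) {
  stopifnot(inherits(table, "region_suv_table"))
  missing <- setdiff(subjects, table$subject_ids)
  if (length(missing))
    stop("unknown subject(s): ", paste(missing, collapse = ", "))
  keep <- table$subject_ids %in% subjects
  region_suv_table(table$subject_ids[keep], table$group_labels[keep],
                   table$region_labels, table$values[keep, , drop = FALSE])
}
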