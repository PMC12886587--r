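#' Read a tabular subject CSV
#'
#' Reads the comma-separated layout the networks are built from: a header row
#' of column labels and a first column of subject identifiers. With
#' `orientation = "subjects_x_time"` the remaining column labels are parsed
#' as sample times in seconds and a [tac_matrix()] is returned; with
#' `orientation = "subjects_x_regions"` they are region names and a
#' [region_suv_table()] is returned. Row and column order are preserved.
#'
#' @param path Path to a CSV file (UTF-8, comma separator, header row).
#' @param orientation `"subjects_x_time"` (dynamic data, one region per file)
#'   or `"subjects_x_regions"` (static data).
#' @param group_labels Group assignment for the subjects: `NULL` (all
#'   subjects labelled `"ungrouped"`), a character vector in row order, a
#'   named character vector keyed by subject id, or the path to a two-column
#'   `subject,group` CSV.
#' @param region_label Region name for dynamic data; defaults to the file
#'   name without extension.
#'
#' @return A `tac_matrix` or `region_suv_table`.
#' @export
read_subject_table <- function(path,
                               orientation = c("subjects_x_time",
                                               "subjects_x_regions"),
                               group_labels = NULL,
                               region_label = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path)

  nfields <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(nfields) < 2L) stop("file has no data rows: ", path)
  if (length(unique(nfields)) != 1L) {
    bad <- which(nfields != nfields[1L])[1L]
    stop(sprintf("ragged CSV: row %d has %d fields, expected %d (%s)",
                 bad, nfields[bad], nfields[1L], path))
  }

  raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(raw) < 2L) stop("expected a subject-id column plus data columns")
  subject_ids <- raw[[1L]]
  col_labels <- colnames(raw)[-1L]
  cells <- as.matrix(raw[, -1L, drop = FALSE])

  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at row '%s', column '%s': \"%s\"",
                 subject_ids[bad[1L]], col_labels[bad[2L]],
                 cells[bad[1L], bad[2L]]))
  }

  groups <- resolve_group_labels(group_labels, subject_ids)

  if (orientation == "subjects_x_time") {
    time_grid <- suppressWarnings(as.numeric(col_labels))
    if (anyNA(time_grid))
      stop("column labels must be numeric times (seconds) for dynamic data")
    if (is.null(region_label))
      region_label <- sub("\\.[^.]*$", "", basename(path))
    tac_matrix(region_label, subject_ids, groups, time_grid, num)
  } else {
    region_suv_table(subject_ids, groups, col_labels, num)
  }
}

resolve_group_labels <- function(group_labels, subject_ids) {
  if (is.null(group_labels))
    return(rep("ungrouped", length(subject_ids)))
  if (length(group_labels) == 1L && file.exists(group_labels)) {
    tab <- utils::read.csv(group_labels, colClasses = "character")
    group_labels <- stats::setNames(tab[[2L]], tab[[1L]])
  }
  if (!is.null(names(group_labels))) {
    missing <- setdiff(subject_ids, names(group_labels))
    if (length(missing))
      stop("no group label for subject(s): ", paste(missing, collapse = ", "))
    return(unname(group_labels[subject_ids]))
  }
  if (length(group_labels) != length(subject_ids))
    stop("group_labels length must match number of subjects")
  as.character(group_labels)
}

#' Write a TAC matrix or regional SUV table to CSV
#'
#' Inverse of [read_subject_table()]: writes the header row (times in seconds
#' for dynamic data, region names for static data), one row per subject with
#' the subject id in the first column. Values are serialised with 17
#' significant digits so a write/read round trip is value-exact.
#'
#' @param x A [tac_matrix()] or [region_suv_table()].
#' @param path Output CSV path.
#' @param groups_path Optional path for a `subject,group` companion CSV.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(x, path, groups_path = NULL) {
  if (inherits(x, "tac_matrix")) {
    header <- c("subject", sprintf("%.17g", x$time_grid))
  } else if (inherits(x, "region_suv_table")) {
    header <- c("subject", x$region_labels)
  } else {
    stop("x must be a tac_matrix or region_suv_table")
  }
  rows <- vapply(seq_along(x$subject_ids), function(i) {
    paste(c(x$subject_ids[i], sprintf("%.17g", x$values[i, ])),
          collapse = ",")
  }, character(1L))
  writeLines(c(paste(header, collapse = ","), rows), path, useBytes = TRUE)
  if (!is.null(groups_path)) {
    writeLines(c("subject,group",
                 paste(x$subject_ids, x$group_labels, sep = ",")),
               groups_path, useBytes = TRUE)
  }
  invisible(path)
}
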