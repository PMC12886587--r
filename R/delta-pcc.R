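#' Interregional reference network over the control group
#'
#' Correlates every pair of regions across the n control subjects, giving
#' the region x region reference matrix (often written PCC_n) that each
#' perturbation subject is judged against.
#'
#' @param table A [region_suv_table()] containing only reference (control)
#'   subjects; >= 3 rows.
#' @param reference_group Optional group label; if given, every row must
#'   carry it.
#' @param method Correlation method.
#' @return A `correlation_result` over regions with `m = n` subjects.
#' @export
reference_network <- function(table, reference_group = NULL,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(table, "region_suv_table"))
  if (!is.null(reference_group) &&
      !all(table$group_labels == reference_group))
    stop("reference table contains non-", reference_group, " subjects")
  if (length(table$subject_ids) < 3L)
    stop("reference network requires at least 3 subjects")
  pairwise_correlation(t(table$values), method = method,
                       entity_ids = table$region_labels)
}

#' Interregional perturbation network: reference plus one subject
#'
#' Appends a single perturbation subject to the reference rows and
#' recomputes all region x region correlations over the n + 1 subjects
#' (PCC_{n+1}). There is no incremental shortcut: the correlation is
#' recomputed from the concatenated table by definition.
#'
#' @param reference_table A [region_suv_table()] of the n reference rows.
#' @param subject_values Numeric vector of the added subject's static SUVs,
#'   in the reference table's region order.
#' @param subject_id Identifier of the added subject; must not already be a
#'   reference row.
#' @param method Correlation method.
#' @return A `correlation_result` over regions with `m = n + 1`.
#' @export
perturbation_network <- function(reference_table, subject_values, subject_id,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(reference_table, "region_suv_table"))
  if (subject_id %in% reference_table$subject_ids)
    stop("subject '", subject_id, "' is already a reference row")
  if (length(subject_values) != length(reference_table$region_labels))
    stop("subject_values must have one value per region")
  aug <- rbind(reference_table$values, subject_values)
  pairwise_correlation(t(aug), method = method,
                       entity_ids = reference_table$region_labels)
}

#' Difference network between perturbation and reference
#'
#' Element-wise `delta = PCC_{n+1} - PCC_n`: how much each interregional
#' correlation moved when the perturbation subject was appended. Values lie
#' in \[-2, 2\] with an exactly zero diagonal.
#'
#' @param ref Reference `correlation_result` (over regions).
#' @param pert Perturbation `correlation_result` on the same regions.
#' @param subject_id Identifier of the perturbation subject (metadata).
#' @param threshold Critical |delta| attached to the matrix, if already
#'   known (see [calibrate_threshold()]); may be a scalar or a full
#'   region x region matrix of per-pair critical values.
#' @return An object of class `delta_pcc_matrix` with elements
#'   `region_labels`, `delta`, `perturbation_subject_id`, `n_reference`,
#'   `threshold`.
#' @export
delta_network <- function(ref, pert, subject_id = NA_character_,
                          threshold = NULL) {
  stopifnot(inherits(ref, "correlation_result"),
            inherits(pert, "correlation_result"))
  if (!identical(ref$entity_ids, pert$entity_ids))
    stop("reference and perturbation region sets differ")
  delta <- pert$r_matrix - ref$r_matrix
  diag(delta) <- 0
  if (!is.null(threshold)) {
    thr <- as.matrix(threshold)
    if (any(thr <= 0, na.rm = TRUE) || any(thr > 2, na.rm = TRUE))
      stop("threshold must lie in (0, 2]")
  }
  structure(list(region_labels = ref$entity_ids, delta = delta,
                 perturbation_subject_id = subject_id,
                 n_reference = ref$m, threshold = threshold),
            class = "delta_pcc_matrix")
}

#' @export
print.delta_pcc_matrix <- function(x, ...) {
  off <- abs(x$delta[upper.tri(x$delta)])
  cat(sprintf(
    "<delta_pcc_matrix> subject '%s' vs %d reference subjects, %d regions\n",
    x$perturbation_subject_id, x$n_reference, length(x$region_labels)))
  cat(sprintf("  |delta|: max %.3f, median %.3f\n", max(off),
              stats::median(off)))
  invisible(x)
}

#' Monte-Carlo critical value for |delta PCC|
#'
#' Calibrates the significance threshold for a change in correlation caused
#' by appending one subject. Null model, per replicate: draw `n_reference`
#' pairs from a bivariate normal with correlation `rho`, compute the sample
#' Pearson correlation, append one further pair from the same distribution,
#' recompute, and record the absolute difference. The critical value is the
#' (1 - alpha) quantile of those absolute differences, so an observed
#' |delta| above it is significant at level alpha under the null that the
#' added subject comes from the reference population.
#'
#' The threshold depends on both inputs: it shrinks as `n_reference` grows
#' (one subject carries less leverage) and as `|rho|` grows (a tight cloud
#' pins the correlation down). For a reference correlation of zero and 13
#' reference subjects it is about 0.18 at alpha = 0.05.
#'
#' @param n_reference Number of reference subjects (>= 3).
#' @param rho Population reference correlation, `|rho| < 1`.
#' @param alpha Significance level in (0, 1).
#' @param n_replicates Monte-Carlo replicates (default 100000).
#' @param seed Optional integer seed for reproducibility (local to this
#'   call).
#' @return Scalar critical |delta PCC| in (0, 2].
#' @export
calibrate_threshold <- function(n_reference, rho, alpha = 0.05,
                                n_replicates = 1e5, seed = NULL) {
  stopifnot(n_reference >= 3)
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_replicates < 10) stop("n_replicates too small")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
           else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  unname(stats::quantile(delta_null_sample(n_reference, rho, n_replicates),
                         1 - alpha))
}

# Vectorised draw of |r_{n+1} - r_n| under the bivariate-normal null:
# one column per replicate.
delta_null_sample <- function(n_reference, rho, n_replicates) {
  N <- n_reference + 1L
  R <- as.integer(n_replicates)
  x <- matrix(stats::rnorm(N * R), nrow = N)
  y <- rho * x + sqrt(1 - rho^2) * matrix(stats::rnorm(N * R), nrow = N)
  abs(col_pearson(x, y) - col_pearson(x[-N, , drop = FALSE],
                                      y[-N, , drop = FALSE]))
}

col_pearson <- function(x, y) {
  n <- nrow(x)
  xc <- x - rep(colMeans(x), each = n)
  yc <- y - rep(colMeans(y), each = n)
  colSums(xc * yc) / sqrt(colSums(xc^2) * colSums(yc^2))
}

#' Table of calibrated |delta PCC| critical values
#'
#' Evaluates [calibrate_threshold()] over a grid of reference sizes and
#' reference correlations, giving the full picture of how the significance
#' threshold moves: down in `n`, down in `rho`.
#'
#' @param n_reference Vector of reference sizes.
#' @param rho Vector of reference correlations.
#' @param alpha Significance level.
#' @param n_replicates Replicates per grid cell.
#' @param seed Optional integer seed.
#' @return An object of class `threshold_curve`: a data frame with columns
#'   `n_reference`, `rho`, `critical`, plus attributes `alpha`,
#'   `n_replicates`, `seed`.
#' @export
threshold_curve <- function(n_reference, rho, alpha = 0.05,
                            n_replicates = 1e5, seed = NULL) {
  grid <- expand.grid(n_reference = n_reference, rho = rho,
                      KEEP.OUT.ATTRS = FALSE)
  grid$critical <- mapply(function(n, r, s) {
    calibrate_threshold(n, r, alpha, n_replicates, seed = s)
  }, grid$n_reference, grid$rho,
     if (is.null(seed)) vector("list", nrow(grid))
     else seed + seq_len(nrow(grid)))
  structure(grid, class = c("threshold_curve", "data.frame"),
            alpha = alpha, n_replicates = n_replicates, seed = seed)
}

#' Threshold-then-average a set of delta-PCC matrices
#'
#' Applies each matrix's significance threshold (entries with
#' `|delta| <= threshold` are set to zero, not dropped) and then averages
#' element-wise across perturbation subjects. Because sub-threshold entries
#' are zeroed rather than removed, every element is averaged over all
#' subjects, so subjects without a significant change attenuate the group
#' mean rather than being excluded from it.
#'
#' @param deltas List of [delta_network()] matrices on a common region set.
#' @param thresholds Per-matrix critical values (recycled scalar, vector, or
#'   list of per-pair matrices); defaults to each matrix's own `threshold`.
#' @return List with `mean` (regions x regions averaged matrix),
#'   `thresholded` (list of the zeroed per-subject matrices) and
#'   `n_subjects`.
#' @export
average_network <- function(deltas, thresholds = NULL) {
  stopifnot(is.list(deltas), length(deltas) >= 1)
  lapply(deltas, function(d) stopifnot(inherits(d, "delta_pcc_matrix")))
  regions <- deltas[[1L]]$region_labels
  for (d in deltas)
    if (!identical(d$region_labels, regions))
      stop("delta matrices have mismatched region sets")
  if (is.null(thresholds)) {
    thresholds <- lapply(deltas, `[[`, "threshold")
    if (any(vapply(thresholds, is.null, logical(1L))))
      stop("no threshold attached to a delta matrix and none supplied")
  } else if (!is.list(thresholds)) {
    thresholds <- as.list(rep_len(thresholds, length(deltas)))
  }
  zeroed <- mapply(function(d, thr) {
    thr <- if (length(thr) == 1L)
      matrix(thr, nrow(d$delta), ncol(d$delta)) else as.matrix(thr)
    out <- d$delta
    out[abs(out) <= thr] <- 0
    out
  }, deltas, thresholds, SIMPLIFY = FALSE)
  avg <- Reduce(`+`, zeroed) / length(zeroed)
  dimnames(avg) <- list(regions, regions)
  list(mean = avg, thresholded = zeroed, n_subjects = length(deltas))
}

#' Full intrasubject delta-PCC pipeline
#'
#' Runs the whole perturbation-network analysis on a two-group static SUV
#' table: builds the interregional reference network from the reference
#' group, then for each perturbation subject computes the perturbation
#' network, the difference matrix, and its significance threshold; finally
#' thresholds and averages across subjects and pools all off-diagonal delta
#' values for the group histogram.
#'
#' Thresholding is per region pair by default: each pair's critical value
#' comes from [calibrate_threshold()] with `rho` set to that pair's observed
#' reference correlation, reflecting that the significance of a correlation
#' change depends on where the reference correlation sits. Passing a number
#' as `threshold` (e.g. 0.18) instead applies one global critical value.
#'
#' @param table A [region_suv_table()] containing both groups.
#' @param reference_group Group label of the reference (control) subjects.
#' @param threshold `"calibrated"` (default) or a single numeric critical
#'   value.
#' @param alpha Significance level for calibration (default 0.05).
#' @param n_replicates Monte-Carlo replicates per region pair.
#' @param seed Integer seed for the calibration draws.
#' @param method Correlation method.
#' @return List with `reference` (`correlation_result`), `deltas` (per
#'   perturbation subject), `threshold` (regions x regions matrix of
#'   critical values), `average` (from [average_network()]) and `pooled`
#'   (vector of all off-diagonal delta values across subjects).
#' @export
deltapcc_pipeline <- function(table, reference_group = "control",
                              threshold = "calibrated", alpha = 0.05,
                              n_replicates = 2e4, seed = NULL,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(table, "region_suv_table"))
  groups <- unique(table$group_labels)
  if (!reference_group %in% groups)
    stop("no subjects in reference group '", reference_group, "'")
  pert_ids <- table$subject_ids[table$group_labels != reference_group]
  if (length(pert_ids) == 0L) stop("perturbation group is empty")
  ref_table <- subset_subjects(
    table, table$subject_ids[table$group_labels == reference_group])
  ref <- reference_network(ref_table, method = method)

  p <- length(ref$entity_ids)
  if (identical(threshold, "calibrated")) {
    thr <- matrix(NA_real_, p, p,
                  dimnames = list(ref$entity_ids, ref$entity_ids))
    pairs <- which(upper.tri(thr), arr.ind = TRUE)
    for (q in seq_len(nrow(pairs))) {
      i <- pairs[q, 1L]; j <- pairs[q, 2L]
      rho <- min(0.999, max(-0.999, ref$r_matrix[i, j]))
      thr[i, j] <- thr[j, i] <- calibrate_threshold(
        ref$m, rho, alpha, n_replicates,
        seed = if (is.null(seed)) NULL else seed + q)
    }
    diag(thr) <- Inf   # the diagonal never changes; never significant
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
    thr <- matrix(threshold, p, p,
                  dimnames = list(ref$entity_ids, ref$entity_ids))
    diag(thr) <- Inf
  }

  deltas <- lapply(pert_ids, function(sid) {
    pert <- perturbation_network(ref_table,
                                 table$values[table$subject_ids == sid, ],
                                 sid, method = method)
    d <- delta_network(ref, pert, subject_id = sid)
    d$threshold <- thr
    d
  })
  names(deltas) <- pert_ids
  avg <- average_network(deltas)
  pooled <- unlist(lapply(deltas,
                          function(d) d$delta[upper.tri(d$delta)]),
                   use.names = FALSE)
  list(reference = ref, deltas = deltas, threshold = thr, average = avg,
       pooled = pooled)
}
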