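#' Pearson correlation coefficient of two vectors
#'
#' Product-moment correlation, the edge-weight statistic used by every
#' network method in this package. A zero-variance vector is an error, never
#' a silent zero: a constant curve carries no correlation information.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return Correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  check_corr_input(x, y)
  stats::cor(x, y, method = "pearson")
}

#' Spearman rank correlation of two vectors
#'
#' Pearson correlation applied to ranks, with ties given mean ranks. Offered
#' as a robustness alternative: it measures monotonic rather than linear
#' association.
#'
#' @inheritParams pearson_r
#' @return Correlation in \[-1, 1\].
#' @export
spearman_r <- function(x, y) {
  check_corr_input(x, y)
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0)
    stop("correlation undefined: a vector has zero rank variance")
  stats::cor(x, y, method = "spearman")
}

check_corr_input <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("correlation requires at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("correlation inputs must be finite")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined: a vector has zero variance")
  invisible(TRUE)
}

#' Two-sided p-value for a correlation coefficient
#'
#' Classical test of zero correlation: the statistic
#' `t = r * sqrt((m - 2) / (1 - r^2))` is referred to a t distribution with
#' `m - 2` degrees of freedom. For TAC correlations the `m` interpolated
#' samples are autocorrelated, so these p-values are nominal rather than
#' effective; the network thresholds pair them with a direct cut on `r`.
#'
#' @param r Correlation coefficient(s), `|r| <= 1`.
#' @param m Number of paired observations (at least 3).
#' @return Two-sided p-value(s) in \[0, 1\]; exactly 0 where `|r| = 1`.
#' @export
corr_pvalue <- function(r, m) {
  if (any(m < 3)) stop("p-value requires at least 3 observations")
  if (any(abs(r) > 1 + 1e-12)) stop("|r| must be <= 1")
  r <- pmin(1, pmax(-1, r))
  p <- numeric(length(r))
  exact <- abs(r) >= 1
  p[exact] <- 0
  t_stat <- r[!exact] * sqrt((m - 2) / (1 - r[!exact]^2))
  p[!exact] <- 2 * stats::pt(abs(t_stat), df = m - 2, lower.tail = FALSE)
  p
}

#' All pairwise correlations over the rows of a matrix
#'
#' Computes the symmetric correlation matrix (and paired two-sided p-values)
#' between every pair of rows. Rows are the entities being networked:
#' subjects (one TAC or one regional-SUV fingerprint per row) for the
#' intersubject methods, or regions for the intrasubject delta-PCC method
#' after transposing.
#'
#' @param data Numeric matrix, entities x observations (>= 2 rows, >= 3
#'   columns). Row names, if present, become entity ids.
#' @param method `"pearson"` or `"spearman"`.
#' @param entity_ids Optional character vector overriding row names.
#' @return An object of class `correlation_result` with elements
#'   `entity_ids`, `r_matrix`, `p_matrix`, `method` and `m` (observations per
#'   entity).
#' @export
pairwise_correlation <- function(data, method = c("pearson", "spearman"),
                                 entity_ids = NULL) {
  method <- match.arg(method)
  data <- as.matrix(data)
  if (nrow(data) < 2L) stop("need at least 2 entities")
  if (ncol(data) < 3L) stop("need at least 3 observations per entity")
  if (is.null(entity_ids))
    entity_ids <- if (!is.null(rownames(data))) rownames(data)
                  else paste0("e", seq_len(nrow(data)))
  rv <- apply(data, 1L, stats::var)
  if (any(rv == 0))
    stop("zero-variance entity: ",
         paste(entity_ids[rv == 0], collapse = ", "))
  r <- stats::cor(t(data), method = method)
  r <- pmax(pmin((r + t(r)) / 2, 1), -1)
  diag(r) <- 1
  p <- matrix(corr_pvalue(as.vector(r), ncol(data)),
              nrow = nrow(r), ncol = ncol(r))
  diag(p) <- 0
  dimnames(r) <- dimnames(p) <- list(entity_ids, entity_ids)
  structure(list(entity_ids = entity_ids, r_matrix = r, p_matrix = p,
                 method = method, m = ncol(data)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s over %d entities (m = %d observations)\n",
              x$method, length(x$entity_ids), x$m))
  off <- x$r_matrix[upper.tri(x$r_matrix)]
  if (length(off))
    cat(sprintf("  off-diagonal r: min %.3f, median %.3f, max %.3f\n",
                min(off), stats::median(off), max(off)))
  invisible(x)
}
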