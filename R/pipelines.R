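#' Pipeline configuration for the intersubject network methods
#'
#' Bundles the thresholds both intersubject pipelines share. The defaults
#' are the study settings: edges require `r > 0.65`, with `p < 0.001` for
#' dynamic (d-) networks and `p < 0.05` for static (s-) networks, followed
#' by k-nearest-neighbour reduction with `k = 3`.
#'
#' @param r_min Correlation threshold (default 0.65).
#' @param alpha_dnet Significance level for d-network edges (default 0.001).
#' @param alpha_snet Significance level for s-network edges (default 0.05).
#' @param k Neighbour count for [knn_reduce()] (default 3).
#' @param excluded_regions Region labels dropped before building s-networks
#'   (default none; the glyburide study drops the gallbladder).
#' @param method Correlation method, `"pearson"` (default) or `"spearman"`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(r_min = 0.65, alpha_dnet = 0.001,
                            alpha_snet = 0.05, k = 3,
                            excluded_regions = character(0),
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (r_min < -1 || r_min > 1) stop("r_min must lie in [-1, 1]")
  if (alpha_dnet <= 0 || alpha_dnet > 1 || alpha_snet <= 0 || alpha_snet > 1)
    stop("alpha levels must lie in (0, 1]")
  if (k < 1) stop("k must be a positive integer")
  structure(list(r_min = r_min, alpha_dnet = alpha_dnet,
                 alpha_snet = alpha_snet, k = as.integer(k),
                 excluded_regions = as.character(excluded_regions),
                 method = method),
            class = "pipeline_config")
}

#' Build the intersubject dynamic network (d-network) for one region
#'
#' Correlates every pair of subjects' time-activity curves within a single
#' region, keeps edges with `r > r_min` and `p < alpha_dnet`, and applies
#' k-nearest-neighbour edge reduction. Nodes are subjects, annotated with
#' their treatment group; one d-network is built per region.
#'
#' @param tac A [tac_matrix()] (subjects x time points, standard grid).
#' @param config A [pipeline_config()].
#' @return A [network_graph()] whose provenance records the thresholds and
#'   the region.
#' @export
build_dnetwork <- function(tac, config = pipeline_config()) {
  stopifnot(inherits(tac, "tac_matrix"), inherits(config, "pipeline_config"))
  if (length(tac$subject_ids) < 3L)
    stop("d-network requires at least 3 subjects")
  corr <- pairwise_correlation(tac$values, method = config$method,
                               entity_ids = tac$subject_ids)
  g <- build_network(corr, r_min = config$r_min, alpha = config$alpha_dnet,
                     groups = tac$group_labels)
  g <- knn_reduce(g, config$k)
  g$provenance$region <- tac$region_label
  g$provenance$network <- "d-network"
  g
}

#' Build the intersubject static network (s-network)
#'
#' Each subject is reduced to its "fingerprint": the vector of static SUVs
#' across the included regions. Subject pairs are correlated across that
#' vector, thresholded at `r > r_min`, `p < alpha_snet`, and k-NN reduced.
#' Regions named in `config$excluded_regions` are dropped first; excluding a
#' hypervariable region (the gallbladder in the glyburide study) is what
#' turns this into an informed method.
#'
#' @param table A [region_suv_table()].
#' @param config A [pipeline_config()].
#' @return A [network_graph()].
#' @export
build_snetwork <- function(table, config = pipeline_config()) {
  stopifnot(inherits(table, "region_suv_table"),
            inherits(config, "pipeline_config"))
  table <- exclude_regions(table, config$excluded_regions)
  if (length(table$region_labels) < 3L)
    stop("s-network requires at least 3 regions after exclusion")
  if (length(table$subject_ids) < 3L)
    stop("s-network requires at least 3 subjects")
  corr <- pairwise_correlation(table$values, method = config$method,
                               entity_ids = table$subject_ids)
  g <- build_network(corr, r_min = config$r_min, alpha = config$alpha_snet,
                     groups = table$group_labels)
  g <- knn_reduce(g, config$k)
  g$provenance$network <- "s-network"
  if (length(config$excluded_regions))
    g$provenance$excluded <- paste(config$excluded_regions, collapse = "+")
  g
}

#' Compare mean static SUV across regions by one-way ANOVA
#'
#' Treats regions as groups and subjects' static SUVs as observations:
#' reports each region's mean and standard deviation and the classical
#' one-way ANOVA F statistic and p-value for a difference among region
#' means. In the glyburide cohort this is what singles out the liver and
#' gallbladder as the high-uptake, high-variance regions.
#'
#' @param table A [region_suv_table()] (>= 2 regions, >= 2 subjects).
#' @return List with `summary` (data frame: region, mean, sd, n), `F`, `p`,
#'   and degrees of freedom `df_between`, `df_within`.
#' @export
region_mean_comparison <- function(table) {
  stopifnot(inherits(table, "region_suv_table"))
  if (length(table$region_labels) < 2L) stop("need at least 2 regions")
  if (length(table$subject_ids) < 2L) stop("need at least 2 subjects")
  long <- data.frame(
    suv = as.vector(table$values),
    region = factor(rep(table$region_labels,
                        each = length(table$subject_ids)),
                    levels = table$region_labels))
  fit <- stats::aov(suv ~ region, data = long)
  # a perfectly flat table triggers anova.lm's perfect-fit warning; the
  # degenerate case is reported explicitly below instead
  tab <- suppressWarnings(stats::anova(fit))
  # a flat table has zero between-region sum of squares; report F = 0, p = 1
  # rather than the 0/0 the raw decomposition would give
  if (tab[["Sum Sq"]][1L] == 0) {
    tab[["F value"]][1L] <- 0
    tab[["Pr(>F)"]][1L] <- 1
  }
  per <- data.frame(
    region = table$region_labels,
    mean = colMeans(table$values),
    sd = apply(table$values, 2L, stats::sd),
    n = length(table$subject_ids),
    row.names = NULL)
  list(summary = per,
       F = unname(tab[["F value"]][1L]),
       p = unname(tab[["Pr(>F)"]][1L]),
       df_between = tab[["Df"]][1L],
       df_within = tab[["Df"]][2L])
}
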