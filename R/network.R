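#' Weighted undirected correlation network
#'
#' Lightweight container for the graphs all three methods produce: nodes are
#' entities (subjects or regions) with a group attribute, edges carry the
#' correlation coefficient as weight, and the provenance records the
#' thresholds the edge set was built under.
#'
#' @param nodes Data frame with columns `id` (unique character) and `group`.
#' @param edges Data frame with columns `from`, `to` (node ids) and `weight`;
#'   self-edges and duplicate pairs are rejected.
#' @param provenance Named list of construction metadata (`r_min`, `alpha`,
#'   `k`, `method`).
#' @return An object of class `network_graph`.
#' @export
network_graph <- function(nodes, edges = NULL, provenance = list()) {
  stopifnot(is.data.frame(nodes), all(c("id", "group") %in% names(nodes)))
  nodes$id <- as.character(nodes$id)
  nodes$group <- as.character(nodes$group)
  if (anyDuplicated(nodes$id)) stop("duplicate node id")
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("from", "to", "weight") %in% names(edges)))
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    if (!all(c(edges$from, edges$to) %in% nodes$id))
      stop("edge endpoint not among nodes")
    if (any(edges$from == edges$to)) stop("self-edges are not allowed")
    # canonical endpoint order so duplicate detection is orientation-free
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    if (anyDuplicated(paste(edges$from, edges$to, sep = "\r")))
      stop("duplicate edge")
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges[, c("from", "to", "weight")],
                 provenance = provenance),
            class = "network_graph")
}

#' @export
print.network_graph <- function(x, ...) {
  cat(sprintf("<network_graph> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  prov <- x$provenance
  if (length(prov))
    cat("  provenance:",
        paste(names(prov), unlist(lapply(prov, format)), sep = "=",
              collapse = ", "), "\n")
  invisible(x)
}

#' Threshold a correlation result into a network
#'
#' An edge joins entities i and j exactly when `r_ij > r_min` (strict) and
#' `p_ij < alpha`; the edge weight is `r_ij`. Every entity becomes a node,
#' isolated or not. No multiple-testing correction is applied to the edge
#' p-values.
#'
#' @param corr A [pairwise_correlation()] result.
#' @param r_min Correlation threshold in \[-1, 1\] (edges require `r > r_min`).
#' @param alpha Significance level in (0, 1\] (edges require `p < alpha`).
#' @param groups Group labels for the entities: vector in entity order or
#'   named by entity id. Defaults to a single `"ungrouped"` label.
#' @return A [network_graph()] whose provenance records `r_min`, `alpha` and
#'   the correlation method.
#' @export
build_network <- function(corr, r_min = 0.65, alpha = 0.05, groups = NULL) {
  stopifnot(inherits(corr, "correlation_result"))
  if (r_min < -1 || r_min > 1) stop("r_min must lie in [-1, 1]")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  ids <- corr$entity_ids
  if (is.null(groups)) groups <- rep("ungrouped", length(ids))
  if (!is.null(names(groups))) {
    missing <- setdiff(ids, names(groups))
    if (length(missing))
      stop("no group for entity: ", paste(missing, collapse = ", "))
    groups <- unname(groups[ids])
  }
  stopifnot(length(groups) == length(ids))
  n <- length(ids)
  pair <- which(upper.tri(corr$r_matrix), arr.ind = TRUE)
  keep <- corr$r_matrix[pair] > r_min & corr$p_matrix[pair] < alpha
  edges <- data.frame(from = ids[pair[keep, 1L]], to = ids[pair[keep, 2L]],
                      weight = corr$r_matrix[pair[keep, , drop = FALSE]],
                      stringsAsFactors = FALSE)
  network_graph(data.frame(id = ids, group = as.character(groups),
                           stringsAsFactors = FALSE),
                edges,
                provenance = list(r_min = r_min, alpha = alpha, k = NA,
                                  method = corr$method))
}

#' k-nearest-neighbour edge reduction
#'
#' Sparsifies a weighted graph by keeping, for each node, only its `k`
#' strongest-weighted incident edges and pruning the rest, except that edges
#' tied with the k-th strongest weight are always kept. Under the default
#' `"union"` semantics an edge survives if either endpoint ranks it within
#' its top `k`, so no node ever loses its own strongest edge;
#' `"intersection"` requires both endpoints to rank it.
#'
#' @param g A [network_graph()].
#' @param k Positive integer neighbour count.
#' @param mode `"union"` (default) or `"intersection"` endpoint semantics.
#' @return A [network_graph()] with the reduced edge set (node set
#'   unchanged) and `k` recorded in the provenance.
#' @export
knn_reduce <- function(g, k, mode = c("union", "intersection")) {
  stopifnot(inherits(g, "network_graph"), k >= 1)
  mode <- match.arg(mode)
  k <- as.integer(k)
  ne <- nrow(g$edges)
  if (ne == 0L) {
    g$provenance$k <- k
    return(g)
  }
  # an endpoint "claims" an edge if the edge is within that node's top k
  claim_from <- claimed_by_endpoint(g$edges, k, g$edges$from)
  claim_to <- claimed_by_endpoint(g$edges, k, g$edges$to)
  keep <- if (mode == "union") claim_from | claim_to
          else claim_from & claim_to
  out <- network_graph(g$nodes, g$edges[keep, , drop = FALSE],
                       provenance = g$provenance)
  out$provenance$k <- k
  out
}

claimed_by_endpoint <- function(edges, k, owners) {
  claimed <- logical(nrow(edges))
  for (v in unique(owners)) {
    idx <- which(edges$from == v | edges$to == v)
    w <- edges$weight[idx]
    sel <- if (length(idx) <= k) rep(TRUE, length(idx))
           else w >= sort(w, decreasing = TRUE)[k]
    mine <- owners[idx] == v
    claimed[idx[sel & mine]] <- TRUE
  }
  claimed
}

#' Convert to an igraph object
#'
#' @param g A [network_graph()].
#' @return An undirected `igraph` graph with `group` vertex attribute,
#'   `weight` edge attribute and provenance entries as graph attributes.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "network_graph"))
  ig <- igraph::graph_from_data_frame(
    g$edges, directed = FALSE,
    vertices = data.frame(name = g$nodes$id, group = g$nodes$group,
                          stringsAsFactors = FALSE))
  for (nm in names(g$provenance)) {
    val <- g$provenance[[nm]]
    if (!is.null(val) && length(val) == 1L && !is.na(val))
      ig <- igraph::set_graph_attr(ig, nm, val)
  }
  ig
}

#' Connected components of a network
#'
#' @param g A [network_graph()].
#' @return List of character vectors of node ids, one per maximal connected
#'   component, in order of first appearance.
#' @export
graph_components <- function(g) {
  stopifnot(inherits(g, "network_graph"))
  comp <- igraph::components(as_igraph(g))
  ids <- igraph::V(as_igraph(g))$name
  unname(split(ids, comp$membership))
}

#' Group mixing of a network's edges
#'
#' Summarises how the edge set respects the node grouping: the fraction of
#' edges joining nodes of different groups, and the within-group edge
#' density (edges present over pairs possible) per group. In a network that
#' separates treatment groups the between-group fraction is low and the
#' within-group densities high.
#'
#' @param g A [network_graph()] whose nodes all carry a non-missing group.
#' @return List with `between_fraction` (NA if the graph has no edges),
#'   `within_density` (named per group), `n_edges` and `n_between`.
#' @export
group_mixing <- function(g) {
  stopifnot(inherits(g, "network_graph"))
  if (any(is.na(g$nodes$group) | g$nodes$group == ""))
    stop("every node needs a group attribute")
  grp <- stats::setNames(g$nodes$group, g$nodes$id)
  ne <- nrow(g$edges)
  between <- if (ne) grp[g$edges$from] != grp[g$edges$to] else logical(0)
  sizes <- table(g$nodes$group)
  dens <- vapply(names(sizes), function(gname) {
    possible <- sizes[[gname]] * (sizes[[gname]] - 1) / 2
    if (possible == 0) return(NA_real_)
    sum(!between & grp[g$edges$from] == gname) / possible
  }, numeric(1L))
  list(between_fraction = if (ne) mean(between) else NA_real_,
       within_density = dens, n_edges = ne, n_between = sum(between))
}

#' Permutation null for the between-group edge fraction
#'
#' Shuffles the node group labels (edge set fixed) and recomputes the
#' between-group edge fraction, giving the null distribution against which
#' the observed mixing is judged. A liver network that separates treatment
#' groups shows an observed fraction in the extreme low tail of this null; a
#' group-invariant region (such as the blood pool) does not.
#'
#' @param g A [network_graph()] with group attributes and at least one edge.
#' @param n_perm Number of label permutations.
#' @return List with `observed`, `null` (vector of permuted fractions) and
#'   `p_lower`, the proportion of permutations with a fraction <= observed
#'   (add-one estimator).
#' @export
mixing_permutation_test <- function(g, n_perm = 1000) {
  stopifnot(inherits(g, "network_graph"), n_perm >= 1)
  if (nrow(g$edges) == 0L) stop("graph has no edges")
  ids <- g$nodes$id
  from_i <- match(g$edges$from, ids)
  to_i <- match(g$edges$to, ids)
  observed <- mean(g$nodes$group[from_i] != g$nodes$group[to_i])
  null <- vapply(seq_len(n_perm), function(i) {
    perm <- sample(g$nodes$group)
    mean(perm[from_i] != perm[to_i])
  }, numeric(1L))
  list(observed = observed, null = null,
       p_lower = (1 + sum(null <= observed)) / (1 + n_perm))
}

#' Export a network to GraphML or edge-list CSV
#'
#' GraphML (via igraph) keeps node groups, edge weights and the provenance
#' thresholds as typed attributes and loads directly into graph tools such
#' as Graphia; the edge-list CSV is a plain `source,target,weight` table
#' with weights at full double precision, plus a node-table companion when
#' `nodes_path` is given (so isolated nodes survive the round trip).
#'
#' @param g A [network_graph()].
#' @param path Output file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @param nodes_path Optional node-table CSV path (edgelist format only).
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("graphml", "edgelist"),
                         nodes_path = NULL) {
  stopifnot(inherits(g, "network_graph"))
  format <- match.arg(format)
  if (!dir.exists(dirname(path)))
    stop("cannot write to ", path, ": no such directory")
  if (format == "graphml") {
    igraph::write_graph(as_igraph(g), path, format = "graphml")
  } else {
    rows <- paste(g$edges$from, g$edges$to,
                  sprintf("%.17g", g$edges$weight), sep = ",")
    writeLines(c("source,target,weight", rows), path, useBytes = TRUE)
    if (!is.null(nodes_path))
      writeLines(c("id,group",
                   paste(g$nodes$id, g$nodes$group, sep = ",")),
                 nodes_path, useBytes = TRUE)
  }
  invisible(path)
}

#' Import a network written by [export_graph()]
#'
#' @param path File produced by [export_graph()].
#' @param format `"graphml"` or `"edgelist"`.
#' @param nodes_path Node-table CSV for the edgelist format (optional).
#' @return A [network_graph()].
#' @export
import_graph <- function(path, format = c("graphml", "edgelist"),
                         nodes_path = NULL) {
  format <- match.arg(format)
  if (format == "graphml") {
    ig <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(id = igraph::V(ig)$name,
                        group = if ("group" %in%
                                    igraph::vertex_attr_names(ig))
                          igraph::V(ig)$group else "ungrouped",
                        stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(ig)
    edges <- data.frame(from = el[, 1L], to = el[, 2L],
                        weight = if (nrow(el)) igraph::E(ig)$weight
                                 else numeric(0),
                        stringsAsFactors = FALSE)
    prov <- as.list(igraph::graph_attr(ig))
    network_graph(nodes, edges, provenance = prov)
  } else {
    edges <- utils::read.csv(path, colClasses = c("character", "character",
                                                  "numeric"))
    names(edges) <- c("from", "to", "weight")
    nodes <- if (!is.null(nodes_path)) {
      nt <- utils::read.csv(nodes_path, colClasses = "character")
      data.frame(id = nt[[1L]], group = nt[[2L]], stringsAsFactors = FALSE)
    } else {
      data.frame(id = unique(c(edges$from, edges$to)), group = "ungrouped",
                 stringsAsFactors = FALSE)
    }
    network_graph(nodes, edges)
  }
}
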