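# Independent reference implementations used to cross-check the package.
# These deliberately use direct formulas and exhaustive search, never the
# code paths they verify.

# product-moment correlation from the raw definition
oracle_pearson <- function(x, y) {
  xd <- x - mean(x)
  yd <- y - mean(y)
  sum(xd * yd) / sqrt(sum(xd^2) * sum(yd^2))
}

# pairwise correlation matrix by looping over pairs
oracle_pairwise <- function(data) {
  n <- nrow(data)
  r <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r[i, j] <- r[j, i] <- oracle_pearson(data[i, ], data[j, ])
    }
  }
  r
}

# two-sided p-value by numeric integration of the t density
oracle_corr_p <- function(r, m) {
  t_stat <- abs(r) * sqrt((m - 2) / (1 - r^2))
  dens <- function(x) {
    gamma((m - 1) / 2) / (sqrt((m - 2) * pi) * gamma((m - 2) / 2)) *
      (1 + x^2 / (m - 2))^(-(m - 1) / 2)
  }
  2 * stats::integrate(dens, t_stat, Inf)$value
}

# k-NN retention by exhaustive enumeration: an edge survives if either
# endpoint ranks it within its top k (ties at the k-th weight kept)
oracle_knn <- function(edges, k) {
  if (nrow(edges) == 0L) return(edges)
  keep <- logical(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    for (v in c(edges$from[e], edges$to[e])) {
      inc <- edges$weight[edges$from == v | edges$to == v]
      if (length(inc) <= k ||
          edges$weight[e] >= sort(inc, decreasing = TRUE)[k])
        keep[e] <- TRUE
    }
  }
  edges[keep, , drop = FALSE]
}

# connected components by breadth-first reachability
oracle_components <- function(ids, edges) {
  unvisited <- ids
  comps <- list()
  while (length(unvisited)) {
    frontier <- unvisited[1L]
    comp <- character(0)
    while (length(frontier)) {
      v <- frontier[1L]
      frontier <- frontier[-1L]
      if (v %in% comp) next
      comp <- c(comp, v)
      nb <- c(edges$to[edges$from == v], edges$from[edges$to == v])
      frontier <- c(frontier, setdiff(nb, comp))
    }
    comps[[length(comps) + 1L]] <- sort(comp)
    unvisited <- setdiff(unvisited, comp)
  }
  comps
}

# random small weighted graph on n nodes with edge probability p
random_test_graph <- function(n, p = 0.5, groups = NULL) {
  ids <- sprintf("v%02d", seq_len(n))
  if (is.null(groups)) groups <- rep("g", n)
  pairs <- utils::combn(ids, 2)
  keep <- stats::runif(ncol(pairs)) < p
  edges <- data.frame(from = pairs[1, keep], to = pairs[2, keep],
                      weight = round(stats::runif(sum(keep)), 3),
                      stringsAsFactors = FALSE)
  network_graph(data.frame(id = ids, group = groups,
                           stringsAsFactors = FALSE), edges)
}

# tiny static SUV table with both groups, for delta-PCC plumbing tests
toy_suv_table <- function(n_control = 4, n_perturb = 2, n_regions = 3,
                          seed = 1) {
  set.seed(seed)
  n <- n_control + n_perturb
  region_suv_table(
    subject_ids = sprintf("s%d", seq_len(n)),
    group_labels = rep(c("control", "rifampicin"), c(n_control, n_perturb)),
    region_labels = sprintf("r%d", seq_len(n_regions)),
    values = matrix(stats::runif(n * n_regions, 0.5, 5), nrow = n))
}
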