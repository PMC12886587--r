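test_that("the reference network is the interregional correlation matrix", {
  tab <- toy_suv_table(n_control = 4, n_perturb = 0, n_regions = 3)
  ref <- reference_network(tab)
  expect_equal(unname(ref$r_matrix), oracle_pairwise(t(tab$values)))
  expect_identical(ref$entity_ids, tab$region_labels)
  expect_equal(ref$m, 4)

  # identical columns correlate at 1; a column mirrored about its mean at -1
  mirror <- region_suv_table(
    sprintf("s%d", 1:3), rep("control", 3), c("a", "b", "c"),
    cbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1)))
  rm_ <- reference_network(mirror)$r_matrix
  expect_equal(rm_["a", "b"], 1)
  expect_equal(rm_["a", "c"], -1)

  mixed <- toy_suv_table(n_control = 4, n_perturb = 2)
  expect_error(reference_network(mixed, reference_group = "control"),
               "non-control")
  expect_error(reference_network(toy_suv_table(3, 0)[c(1)]), "region_suv")
})

test_that("the perturbation network equals recomputation on n+1 rows", {
  tab <- toy_suv_table(n_control = 5, n_perturb = 1, n_regions = 4)
  ref_tab <- subset_subjects(tab, tab$subject_ids[1:5])
  new_vals <- tab$values[6, ]
  pert <- perturbation_network(ref_tab, new_vals, "s6")
  expect_equal(unname(pert$r_matrix),
               oracle_pairwise(t(rbind(ref_tab$values, new_vals))))
  expect_equal(pert$m, 6)
  expect_error(perturbation_network(ref_tab, new_vals, "s1"),
               "already a reference row")
  expect_error(perturbation_network(ref_tab, new_vals[1:2], "s6"),
               "per region")
})

test_that("three-point perturbation correlations match the closed form", {
  # n = 2 reference rows plus one added subject: correlations over 3 points
  ref_tab <- region_suv_table(c("s1", "s2"), rep("control", 2),
                              c("a", "b"), rbind(c(1, 5), c(2, 4)))
  pert <- perturbation_network(ref_tab, c(4, 6), "s3")
  expect_equal(pert$r_matrix["a", "b"],
               oracle_pearson(c(1, 2, 4), c(5, 4, 6)))
})

test_that("delta networks are element-wise differences with zero diagonal", {
  tab <- toy_suv_table(n_control = 5, n_perturb = 2, n_regions = 3)
  ref_tab <- subset_subjects(tab, tab$subject_ids[1:5])
  ref <- reference_network(ref_tab)
  pert <- perturbation_network(ref_tab, tab$values[6, ], "s6")

  d <- delta_network(ref, pert, "s6")
  expect_equal(d$delta, pert$r_matrix - ref$r_matrix)
  expect_equal(unname(diag(d$delta)), rep(0, 3))
  expect_true(all(abs(d$delta) <= 2))
  expect_equal(d$n_reference, 5)

  expect_equal(delta_network(ref, ref)$delta, 0 * ref$r_matrix)
  expect_equal(delta_network(ref, pert)$delta,
               -delta_network(pert, ref)$delta)

  other <- reference_network(region_suv_table(
    sprintf("x%d", 1:3), rep("control", 3), c("p", "q", "r"),
    matrix(runif(9, 1, 2), 3)))
  expect_error(delta_network(ref, other), "region sets differ")
})

test_that("the Monte-Carlo threshold is reproducible and well behaved", {
  a <- calibrate_threshold(10, 0.2, 0.05, 5000, seed = 8)
  b <- calibrate_threshold(10, 0.2, 0.05, 5000, seed = 8)
  expect_identical(a, b)
  expect_gt(a, 0)
  expect_lte(a, 2)

  # adding one point to a near-perfectly correlated sample barely moves r
  expect_lt(calibrate_threshold(13, 0.999, 0.05, 5000, seed = 8), 0.02)
  # influence of a single point shrinks roughly like 1/n
  expect_lt(calibrate_threshold(1000, 0, 0.05, 20000, seed = 8), 0.02)

  expect_error(calibrate_threshold(13, 1, 0.05), "rho")
  expect_error(calibrate_threshold(13, 0, 1.5), "alpha")
  expect_error(calibrate_threshold(2, 0, 0.05), "n_reference")
})

test_that("threshold curves fall with reference size and correlation", {
  curve <- threshold_curve(n_reference = c(8, 13, 50), rho = c(0, 0.6),
                           n_replicates = 20000, seed = 12)
  expect_s3_class(curve, "threshold_curve")
  for (r in unique(curve$rho)) {
    sub <- curve[curve$rho == r, ]
    expect_true(all(diff(sub$critical[order(sub$n_reference)]) < 0))
  }
  for (n in unique(curve$n_reference)) {
    sub <- curve[curve$n_reference == n, ]
    expect_true(all(diff(sub$critical[order(sub$rho)]) < 0))
  }
})

test_that("threshold-then-average zeroes and averages as specified", {
  mk_delta <- function(m, id) {
    structure(list(region_labels = c("a", "b", "c"),
                   delta = m, perturbation_subject_id = id,
                   n_reference = 5, threshold = NULL),
              class = "delta_pcc_matrix")
  }
  m1 <- matrix(0, 3, 3)
  m1[1, 2] <- m1[2, 1] <- 0.5
  m1[1, 3] <- m1[3, 1] <- -0.1
  m2 <- matrix(0, 3, 3)

  # all entries sub-threshold -> zero matrix
  expect_equal(average_network(list(mk_delta(m1, "p1")),
                               thresholds = 0.6)$mean,
               matrix(0, 3, 3, dimnames = list(c("a", "b", "c"),
                                               c("a", "b", "c"))))
  # single matrix, all supra-threshold entries survive unchanged
  expect_equal(unname(average_network(list(mk_delta(m1, "p1")),
                                      thresholds = 0.05)$mean), m1)
  # one zeroed matrix halves the surviving one
  avg <- average_network(list(mk_delta(m1, "p1"), mk_delta(m2, "p2")),
                         thresholds = 0.3)
  expect_equal(avg$mean["a", "b"], 0.25)
  expect_equal(avg$mean["a", "c"], 0)
  expect_equal(avg$n_subjects, 2)

  bad <- mk_delta(m1, "p3"); bad$region_labels <- c("x", "y", "z")
  expect_error(average_network(list(mk_delta(m1, "p1"), bad),
                               thresholds = 0.3), "mismatched")
})

test_that("the pipeline is order-invariant and honours a single subject", {
  tab <- toy_suv_table(n_control = 8, n_perturb = 3, n_regions = 4,
                       seed = 9)
  pl <- deltapcc_pipeline(tab, "control", n_replicates = 2000, seed = 5)
  expect_named(pl$deltas, c("s9", "s10", "s11"))
  expect_equal(dim(pl$average$mean), c(4, 4))
  expect_length(pl$pooled, 3 * choose(4, 2))

  # reordering the perturbation subjects changes nothing numerically
  perm_idx <- c(1:8, 11, 9, 10)
  tab2 <- region_suv_table(tab$subject_ids[perm_idx],
                           tab$group_labels[perm_idx],
                           tab$region_labels, tab$values[perm_idx, ])
  pl2 <- deltapcc_pipeline(tab2, "control", n_replicates = 2000, seed = 5)
  expect_equal(pl2$average$mean, pl$average$mean)
  expect_equal(pl2$deltas[["s9"]]$delta, pl$deltas[["s9"]]$delta)

  # a single perturbation subject: the average IS its thresholded matrix
  tab1 <- subset_subjects(tab, tab$subject_ids[1:9])
  pl1 <- deltapcc_pipeline(tab1, "control", n_replicates = 2000, seed = 5)
  thr1 <- pl1$deltas[[1]]$delta
  thr1[abs(thr1) <= pl1$threshold] <- 0
  expect_equal(pl1$average$mean, thr1)

  only_ctrl <- subset_subjects(tab, tab$subject_ids[1:8])
  expect_error(deltapcc_pipeline(only_ctrl, "control"), "empty")

  # a global numeric threshold is applied uniformly
  plg <- deltapcc_pipeline(tab, "control", threshold = 0.18)
  expect_equal(unique(plg$threshold[upper.tri(plg$threshold)]), 0.18)
})

test_that("under a same-distribution perturbation the histogram sits at 0", {
  co <- generate_cohort(make_fixture("null", seed = 21, n_perturb = 40))
  pl <- deltapcc_pipeline(co$suv, "control", n_replicates = 2000, seed = 3)
  expect_lt(abs(stats::median(pl$pooled)), 0.02)
  expect_gt(mean(abs(pl$pooled) < 0.18), 0.85)
})
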