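test_that("block covariance: identity case, eigenvalues, and PSD", {
  part <- setNames(c(1, 1, 1, 2, 2, 2), paste0("n", 1:6))
  expect_equal(build_block_covariance(part, 0, 0),
               diag(6), ignore_attr = TRUE)
  S <- build_block_covariance(part, within_r = 0.5, between_r = 0)
  # eigendecomposition oracle: 3-node block with r = 0.5 has spectrum {2, 0.5, 0.5}
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(min(ev), 0.5, tolerance = 1e-12)
  expect_equal(max(ev), 2, tolerance = 1e-12)
  expect_true(isSymmetric(S))
  expect_equal(diag(S), setNames(rep(1, 6), paste0("n", 1:6)))
  expect_equal(attr(S, "shrinkage"), 0)
})

test_that("Monte-Carlo draws reproduce the target block correlations", {
  part <- setNames(c(1, 1, 1, 2, 2, 2), paste0("n", 1:6))
  S <- build_block_covariance(part, 0.5, 0)
  set.seed(99)
  X <- matrix(rnorm(10000 * 6), 10000) %*% chol(S)
  r <- cor(X)
  expect_lt(max(abs(r[1:3, 1:3][upper.tri(diag(3))] - 0.5)), 0.03)
  expect_lt(max(abs(r[1:3, 4:6])), 0.03)
})

test_that("non-PSD targets are repaired by shrinkage or rejected with the block named", {
  part <- setNames(c(1, 1, 1, 2, 2, 2), paste0("n", 1:6))
  # strongly negative within-correlation in a 3-node block is infeasible
  S <- build_block_covariance(part, within_r = -0.9, between_r = 0)
  expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  expect_gt(attr(S, "shrinkage"), 0)
  expect_error(build_block_covariance(part, -0.9, 0, max_steps = 2L),
               "offending block")
  expect_error(build_block_covariance(part, 1.2, 0), "< 1")
})

test_that("cohorts are bit-identical under the same seed and sized 2 n_per_group", {
  cfg <- small_cohort_config(n_per_group = 4, seed = 7)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  expect_length(c1$subjects, 8L)
  grp <- vapply(c1$subjects, `[[`, character(1), "group")
  expect_equal(unname(table(grp)[c("AD", "CN")]), c(8, 8) / 2, ignore_attr = TRUE)
  # a different seed changes the data
  c3 <- generate_cohort(small_cohort_config(n_per_group = 4, seed = 8))
  expect_false(identical(c1$subjects[[1]]$phases$encoding$data,
                         c3$subjects[[1]]$phases$encoding$data))
})

test_that("empty cohort is valid and carries truth; bad phase length errors", {
  c0 <- generate_cohort(small_cohort_config(n_per_group = 0))
  expect_length(c0$subjects, 0L)
  expect_equal(c0$truth$true_acme,
               unname(prod(c0$config$mediation_coeffs[c("a", "b")])))
  expect_error(cohort_config(phase_lengths = c(encoding = 2L)), "4 volumes")
})

test_that("null generator (no deficit, no mediation) gives near-zero group FC difference", {
  cfg <- small_cohort_config(
    n_per_group = 200, seed = 41, ad_within_delta = 0, entropy_phi = 0,
    mediation_coeffs = c(a = 0, b = 0, cprime = 0))
  coh <- generate_cohort(cfg)
  grp <- vapply(coh$subjects, `[[`, character(1), "group")
  comm1 <- names(cfg$planted_partition)[cfg$planted_partition == 1L]
  wfc <- vapply(coh$subjects, function(s)
    mean_connectivity(compute_fc(s$phases$maintenance), comm1), numeric(1))
  expect_lt(abs(mean(wfc[grp == "AD"]) - mean(wfc[grp == "CN"])), 0.02)
  # with low-entropy nodes active, communities that do not contain them
  # must still be group-null
  cfg2 <- small_cohort_config(
    n_per_group = 200, seed = 42, ad_within_delta = 0,
    mediation_coeffs = c(a = 0, b = 0, cprime = 0))
  coh2 <- generate_cohort(cfg2)
  grp2 <- vapply(coh2$subjects, `[[`, character(1), "group")
  comm2 <- names(cfg2$planted_partition)[cfg2$planted_partition == 2L]
  wfc2 <- vapply(coh2$subjects, function(s)
    mean_connectivity(compute_fc(s$phases$maintenance), comm2), numeric(1))
  expect_lt(abs(mean(wfc2[grp2 == "AD"]) - mean(wfc2[grp2 == "CN"])), 0.02)
})

test_that("group FC deficit grows monotonically with the planted delta", {
  deltas <- c(0, 0.05, 0.1, 0.2)
  gaps <- vapply(deltas, function(d) {
    cfg <- small_cohort_config(n_per_group = 30, seed = 19, ad_within_delta = d,
                               mediation_coeffs = c(a = 0, b = 0, cprime = 0))
    coh <- generate_cohort(cfg)
    grp <- vapply(coh$subjects, `[[`, character(1), "group")
    comm1 <- names(cfg$planted_partition)[cfg$planted_partition == 1L]
    wfc <- vapply(coh$subjects, function(s)
      mean_connectivity(compute_fc(s$phases$maintenance), comm1), numeric(1))
    mean(wfc[grp == "CN"]) - mean(wfc[grp == "AD"])
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("the deficit is confined to the designated phases", {
  cfg <- small_cohort_config(n_per_group = 40, seed = 23, ad_within_delta = 0.2,
                             mediation_coeffs = c(a = 0, b = 0, cprime = 0))
  coh <- generate_cohort(cfg)
  grp <- vapply(coh$subjects, `[[`, character(1), "group")
  comm1 <- names(cfg$planted_partition)[cfg$planted_partition == 1L]
  gap <- function(ph) {
    wfc <- vapply(coh$subjects, function(s)
      mean_connectivity(compute_fc(s$phases[[ph]]), comm1), numeric(1))
    mean(wfc[grp == "CN"]) - mean(wfc[grp == "AD"])
  }
  expect_lt(abs(gap("encoding")), 0.05)
  expect_gt(gap("maintenance"), 0.1)
  expect_gt(gap("retrieval"), 0.1)
})

test_that("SUVR is elevated in the patient group and demographics are in range", {
  coh <- generate_cohort(small_cohort_config(n_per_group = 50, seed = 13))
  pt <- participants(coh)
  expect_gt(mean(pt$suvr[pt$group == "AD"]), mean(pt$suvr[pt$group == "CN"]))
  expect_true(all(pt$age >= 50 & pt$age <= 90))
  expect_true(all(pt$education >= 6 & pt$education <= 20))
  expect_true(all(pt$sex %in% c("F", "M")))
  expect_true(all(pt$accuracy >= 0 & pt$accuracy <= 1))
})

test_that("cohort-level mediation recovers ACME near a*b within its CI", {
  parc <- small_parcellation()
  cfg <- cohort_config(
    n_per_group = 250, n_nodes = nrow(parc), parcellation = parc,
    planted_partition = small_planted_partition(parc),
    phase_lengths = c(encoding = 40L, maintenance = 40L, retrieval = 150L),
    within_r = 0.4, between_r = 0.05, ad_within_delta = 0,
    entropy_nodes = parc$node_id[1:3],
    mediation_coeffs = c(a = 0.5, b = 0.5, cprime = 0),
    fc_scale = 0.15, seed = 31)
  coh <- generate_cohort(cfg)
  pt <- participants(coh)
  comm1 <- names(cfg$planted_partition)[cfg$planted_partition == 1L]
  pt$net_fc <- vapply(coh$subjects, function(s)
    mean_connectivity(compute_fc(s$phases$retrieval), comm1), numeric(1))
  fit <- mediate_fc(pt, "suvr", "net_fc", "memory", covariates = NULL,
                    n_boot = 400, seed = 2, ci = "percentile")
  expect_gte(0.25, fit$ci$acme[1])
  expect_lte(0.25, fit$ci$acme[2] + 0.03)
  expect_gt(fit$acme, 0.1)
})

test_that("default configuration mirrors the study conditions", {
  cfg <- cohort_config()
  expect_equal(cfg$n_per_group, 36L)
  expect_equal(cfg$n_nodes, 200L)
  expect_equal(cfg$tr_seconds, 3)
  expect_equal(unname(cfg$phase_lengths["maintenance"]), 40L)  # 2 min at TR 3
  expect_equal(sum(cfg$parcellation$in_restricted_set), 136L)
  expect_equal(sort(unique(cfg$parcellation$a_priori_network)),
               sort(c("visual", "somatomotor", "DAN", "VAN", "limbic",
                      "FPN", "DMN")))
  sizes <- table(cfg$planted_partition[cfg$parcellation$in_restricted_set])
  expect_equal(sort(as.integer(sizes), decreasing = TRUE)[1:3], c(56, 50, 30))
  expect_equal(unname(prod(cfg$mediation_coeffs[c("a", "b")])), -0.05)
  expect_length(cfg$entropy_nodes, 5L)
})
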