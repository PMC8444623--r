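test_that("modularity matches hand evaluation and the double-sum oracle", {
  w <- two_cliques()
  expect_equal(modularity_q(w, c(1, 1, 1, 2, 2, 2)), 0.5)
  # all nodes in one community -> Q = 0 at gamma 1
  expect_equal(modularity_q(w, rep(1, 6)), 0)
  set.seed(8)
  for (s in 1:5) {
    wr <- rand_sym_weights(6, seed = s)
    comm <- sample(1:3, 6, replace = TRUE)
    expect_equal(modularity_q(wr, comm), oracle_modularity(wr, comm),
                 tolerance = 1e-12)
    expect_equal(modularity_q(wr, comm, gamma = 1.4),
                 oracle_modularity(wr, comm, gamma = 1.4), tolerance = 1e-12)
  }
})

test_that("modularity is invariant under community relabelling", {
  wr <- rand_sym_weights(8, seed = 21)
  comm <- c(1, 1, 2, 2, 3, 3, 1, 2)
  relab <- c(7, 7, 2, 2, 9, 9, 7, 2)
  expect_equal(modularity_q(wr, comm), modularity_q(wr, relab))
})

test_that("modularity rejects invalid weights", {
  w <- two_cliques()
  expect_error(modularity_q(-w, rep(1, 6)), "non-negative")
  expect_error(modularity_q(matrix(0, 3, 3), rep(1, 3)), "positive")
})

test_that("louvain recovers the exact maximum on the two-clique instance", {
  p <- louvain(two_cliques(), seed = 4)
  expect_equal(p$modularity_q, 0.5)
  expect_equal(unname(p$assignment[1:3]), rep(p$assignment[[1]], 3))
  expect_equal(unname(p$assignment[4:6]), rep(p$assignment[[4]], 3))
  expect_equal(p$n_communities, 2L)
  # complete graph collapses to one community
  wk <- matrix(1, 5, 5); diag(wk) <- 0
  dimnames(wk) <- list(paste0("n", 1:5), paste0("n", 1:5))
  expect_equal(louvain(wk, seed = 1)$n_communities, 1L)
})

test_that("louvain is deterministic given a seed and beats trivial partitions", {
  wr <- rand_sym_weights(12, seed = 33)
  p1 <- louvain(wr, seed = 9)
  p2 <- louvain(wr, seed = 9)
  expect_identical(p1$assignment, p2$assignment)
  expect_gte(p1$modularity_q, modularity_q(wr, rep(1, 12)))
  expect_gte(p1$modularity_q, modularity_q(wr, seq_len(12)))
})

test_that("louvain reaches the exhaustive-maximum Q on small random graphs", {
  hits <- 0L
  n_graphs <- 15L
  for (s in seq_len(n_graphs)) {
    n <- 5L + (s %% 3L)
    w <- rand_sym_weights(n, seed = 100 + s)
    # sparsify so community structure exists
    w[w < 0.5] <- 0
    if (sum(w) == 0) next
    best <- oracle_best_partition(w)
    got <- louvain(w, seed = s)$modularity_q
    expect_lte(got, best$q + 1e-9)
    if (abs(got - best$q) < 1e-9) hits <- hits + 1L
  }
  expect_gte(hits / n_graphs, 0.9)
})

test_that("agreement matrix of identical partitions is 0/1 block structured", {
  a <- c(1, 1, 2, 2, 3)
  agree <- agreement_matrix(replicate(4, a, simplify = FALSE))
  expect_true(all(agree %in% c(0, 1)))
  expect_equal(diag(agree), rep(1, 5))
  expect_true(isSymmetric(agree))
  expect_equal(agree, outer(a, a, "==") * 1)
  # order of runs does not matter
  runs <- list(c(1, 1, 2, 2, 2), c(1, 2, 2, 1, 1), c(3, 3, 3, 1, 1))
  expect_equal(agreement_matrix(runs), agreement_matrix(rev(runs)))
})

test_that("consensus converges in one iteration on a seed-independent instance", {
  p <- consensus_partition(two_cliques(), n_runs = 10, seed = 2)
  expect_equal(attr(p, "iterations"), 1L)
  expect_equal(p$modularity_q, 0.5)
  expect_equal(p$n_communities, 2L)
  expect_error(consensus_partition(two_cliques(), n_runs = 1), "n_runs")
  expect_error(consensus_partition(two_cliques(), tau = 1.2), "tau")
})

test_that("consensus recovers a planted 3-block partition from sampled data, reproducibly", {
  parc <- small_parcellation()
  part <- small_planted_partition(parc)[parc$in_restricted_set]
  S <- build_block_covariance(part, within_r = 0.5, between_r = 0.05)
  set.seed(77)
  X <- matrix(rnorm(150 * length(part)), 150) %*% chol(S)
  z <- compute_fc(t(`colnames<-`(X, names(part))))
  w <- zero_negative(z)
  p1 <- consensus_partition(w, n_runs = 20, seed = 5)
  p2 <- consensus_partition(w, n_runs = 20, seed = 5)
  expect_identical(p1$assignment, p2$assignment)
  expect_equal(p1$n_communities, 3L)
  # exact planted recovery (adjusted Rand = 1)
  expect_equal(mclust::adjustedRandIndex(p1$assignment, part), 1)
})

test_that("restrict_and_cluster averages controls, restricts nodes and labels by size", {
  cfg <- small_cohort_config(n_per_group = 8, seed = 12)
  coh <- generate_cohort(cfg)
  ctrl <- Filter(function(s) s$group == "CN", coh$subjects)
  fc <- lapply(ctrl, function(s) compute_fc(s$phases$maintenance))
  p <- restrict_and_cluster(fc, coh$parcellation, n_runs = 20, seed = 3)
  expect_equal(length(p$assignment), sum(coh$parcellation$in_restricted_set))
  sizes <- as.integer(table(p$assignment))
  expect_true(all(diff(sizes) <= 0))  # community 1 is the largest
  truth <- coh$truth$planted_partition[names(p$assignment)]
  expect_equal(mclust::adjustedRandIndex(p$assignment, truth), 1)
  expect_error(restrict_and_cluster(fc[0], coh$parcellation), "2 control")
})

test_that("a single planted community yields one community and trivial consensus", {
  part <- setNames(rep(1L, 8), paste0("n", 1:8))
  S <- build_block_covariance(part, within_r = 0.5, between_r = 0)
  set.seed(3)
  X <- matrix(rnorm(200 * 8), 200) %*% chol(S)
  w <- zero_negative(compute_fc(t(`colnames<-`(X, names(part)))))
  p <- consensus_partition(w, n_runs = 10, seed = 4)
  expect_equal(p$n_communities, 1L)
})

test_that("partitions serialize to TSV with a-priori labels", {
  parc <- small_parcellation()
  part <- small_planted_partition(parc)[parc$in_restricted_set]
  S <- build_block_covariance(part, 0.5, 0.05)
  p <- new_partition_for_test <- louvain(zero_negative(S), seed = 1)
  f <- tempfile(fileext = ".tsv")
  write_partition(p, f, parcellation = parc)
  df <- read.delim(f)
  expect_named(df, c("node_id", "community", "a_priori_network"))
  expect_equal(nrow(df), length(part))
})
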