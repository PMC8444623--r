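test_that("permutation mean test: identical groups give p = 1, labels are exchangeable", {
  v <- c(1.2, 3.4, -0.5, 2.2)
  res <- permutation_mean_test(v, v, n_perm = 500, seed = 1)
  expect_equal(res$p, 1)
  set.seed(4)
  a <- rnorm(12); b <- rnorm(12) + 1
  r1 <- permutation_mean_test(a, b, n_perm = 2000, seed = 3)
  r2 <- permutation_mean_test(b, a, n_perm = 2000, seed = 3)
  expect_equal(r1$p, r2$p)  # two-sidedness: swapping groups changes nothing
  expect_equal(r1$diff, -r2$diff)
  expect_warning(permutation_mean_test(a, b, n_perm = 50, seed = 1),
                 "unreliable")
  expect_error(permutation_mean_test(numeric(0), b), "nonempty")
})

test_that("permutation mean test detects a planted 1-SD shift at n = 36/36", {
  hits <- 0L
  n_sim <- 40L
  for (s in seq_len(n_sim)) {
    set.seed(1000 + s)
    a <- rnorm(36) + 1
    b <- rnorm(36)
    p <- permutation_mean_test(a, b, n_perm = 500, seed = s)$p
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_sim, 0.9)
})

test_that("permutation mean test is calibrated under the null", {
  n_sim <- 400L
  rej <- 0L
  for (s in seq_len(n_sim)) {
    set.seed(2000 + s)
    a <- rnorm(20); b <- rnorm(20)
    if (permutation_mean_test(a, b, n_perm = 199, seed = s)$p <= 0.05)
      rej <- rej + 1L
  }
  expect_gte(rej / n_sim, 0.02)
  expect_lte(rej / n_sim, 0.09)
})

test_that("edge-wise GLM equals the pooled two-sample t without covariates", {
  set.seed(5)
  y <- matrix(rnorm(40 * 10), 40)
  g <- rep(c("AD", "CN"), each = 20)
  stk <- y
  attr(stk, "edges") <- cbind(1:10, 2:11)
  attr(stk, "node_ids") <- as.character(1:11)
  t_glm <- edgewise_glm_t(stk, g)
  t_ref <- vapply(1:10, function(j)
    t.test(y[g == "CN", j], y[g == "AD", j], var.equal = TRUE)$statistic,
    numeric(1))
  expect_lt(max(abs(t_glm - t_ref)), 1e-10)
  expect_equal(attr(t_glm, "df"), 38L)
})

test_that("edge-wise GLM handles covariates, sign convention and rank deficiency", {
  set.seed(6)
  n <- 30
  y <- matrix(rnorm(n * 5), n)
  g <- rep(c("AD", "CN"), each = 15)
  covs <- data.frame(age = rnorm(n, 70, 5), sex = sample(c("F", "M"), n, TRUE))
  stk <- y; attr(stk, "edges") <- cbind(1:5, 2:6)
  attr(stk, "node_ids") <- as.character(1:6)
  t_adj <- edgewise_glm_t(stk, g, covariates = covs)
  expect_equal(attr(t_adj, "df"), 30L - 4L)
  # per-edge lm oracle for the group coefficient
  x <- as.numeric(g == "CN")
  t_lm <- vapply(1:5, function(j) {
    fit <- summary(lm(y[, j] ~ x + covs$age + covs$sex))
    fit$coefficients["x", "t value"]
  }, numeric(1))
  expect_lt(max(abs(t_adj - t_lm)), 1e-10)
  # positive t when the positive_level group mean is higher
  y2 <- matrix(rnorm(n), n, 1)
  y2[g == "CN", ] <- y2[g == "CN", ] + 5
  stk2 <- y2; attr(stk2, "edges") <- cbind(1L, 2L)
  attr(stk2, "node_ids") <- c("1", "2")
  expect_gt(edgewise_glm_t(stk2, g)[1], 0)
  expect_lt(edgewise_glm_t(stk2, g, positive_level = "AD")[1], 0)
  # degenerate designs
  expect_error(edgewise_glm_t(stk, rep("AD", n)), "2 levels")
  expect_error(edgewise_glm_t(stk, g, covariates = data.frame(x = x)),
               "rank deficient")
})

test_that("covariates orthogonal to group and outcome leave t unchanged up to df", {
  set.seed(9)
  n <- 24
  y <- matrix(rnorm(n * 4), n)
  g <- rep(c("AD", "CN"), each = 12)
  x <- as.numeric(g == "CN")
  # construct a covariate orthogonal to intercept, group and every edge
  raw <- rnorm(n)
  cov_orth <- qr.resid(qr(cbind(1, x, y)), raw)
  stk <- y; attr(stk, "edges") <- cbind(1:4, 2:5)
  attr(stk, "node_ids") <- as.character(1:5)
  t0 <- edgewise_glm_t(stk, g)
  t1 <- edgewise_glm_t(stk, g, covariates = data.frame(c1 = cov_orth))
  expect_equal(as.numeric(t1), as.numeric(t0) * sqrt((n - 3) / (n - 2)),
               tolerance = 1e-10)
})

test_that("null edge-wise t-values follow the Student t reference distribution", {
  set.seed(77)
  n <- 72
  y <- matrix(rnorm(n * 2000), n)
  g <- rep(c("AD", "CN"), each = 36)
  covs <- data.frame(age = rnorm(n, 70, 6), sex = sample(c("F", "M"), n, TRUE))
  stk <- y; attr(stk, "edges") <- cbind(seq_len(2000), seq_len(2000) + 1L)
  attr(stk, "node_ids") <- as.character(seq_len(2001))
  tv <- edgewise_glm_t(stk, g, covariates = covs)
  ks <- suppressWarnings(ks.test(as.numeric(tv), function(q) pt(q, df = n - 4)))
  expect_gt(ks$p.value, 0.01)
})

test_that("NBS: infinite threshold empties the result; components and counts are exact", {
  set.seed(12)
  coh_fc <- replicate(20, {
    z <- matrix(rnorm(36), 6); z <- (z + t(z)) / 2; diag(z) <- 0
    dimnames(z) <- list(paste0("n", 1:6), paste0("n", 1:6)); z
  }, simplify = FALSE)
  stk <- fc_stack(coh_fc)
  g <- rep(c("AD", "CN"), each = 10)
  res_inf <- nbs(stk, g, threshold_t = 1e9, n_perm = 50, seed = 1)
  expect_equal(sum(res_inf$supra_mask), 0L)
  expect_length(res_inf$components, 0L)
  expect_length(res_inf$reduced_nodes, 0L)
  cnt <- count_reduced(res_inf)
  expect_equal(cnt$n_reduced_nodes, 0L)
  expect_equal(cnt$n_reduced_edges, 0L)
  expect_equal(cnt$n_total_nodes, 6L)
})

test_that("NBS recovers a planted dense deficit with high edge recall", {
  set.seed(13)
  n <- 72
  nodes <- paste0("n", 1:20)
  g <- rep(c("AD", "CN"), each = 36)
  planted <- 1:8  # dense deficit among the first 8 nodes in patients
  fc <- lapply(seq_len(n), function(s) {
    z <- matrix(rnorm(400, sd = 0.1), 20)
    z <- (z + t(z)) / 2
    z <- z + 0.3
    if (g[s] == "AD") z[planted, planted] <- z[planted, planted] - 0.2
    diag(z) <- 0
    dimnames(z) <- list(nodes, nodes)
    z
  })
  stk <- fc_stack(fc)
  res <- nbs(stk, g, n_perm = 300, seed = 2)
  ed <- res$edges
  planted_edges <- which(ed[, 1] <= 8 & ed[, 2] <= 8)
  recall <- length(intersect(res$reduced_edge_idx, planted_edges)) /
    length(planted_edges)
  expect_gte(recall, 0.8)
  expect_gte(mean(res$reduced_nodes %in% nodes[planted]), 0.8)
})

test_that("NBS reduced node set shrinks monotonically as the threshold grows", {
  set.seed(14)
  n <- 40
  fc <- lapply(seq_len(n), function(s) {
    z <- matrix(rnorm(144, sd = 0.2), 12); z <- (z + t(z)) / 2; diag(z) <- 0
    dimnames(z) <- list(paste0("n", 1:12), paste0("n", 1:12)); z
  })
  g <- rep(c("AD", "CN"), each = 20)
  stk <- fc_stack(fc)
  sizes <- vapply(c(1.5, 2.5, 3.5), function(thr) {
    r <- nbs(stk, g, threshold_t = thr, n_perm = 50, alpha = 1, seed = 3)
    length(unique(unlist(lapply(r$components, `[[`, "nodes"))))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("triangle of significant edges counts 3 nodes and 3 edges", {
  # construct an nbs_result-like check through a strong planted triangle
  set.seed(15)
  n <- 60
  nodes <- paste0("n", 1:6)
  g <- rep(c("AD", "CN"), each = 30)
  fc <- lapply(seq_len(n), function(s) {
    z <- matrix(rnorm(36, sd = 0.05), 6); z <- (z + t(z)) / 2
    tri <- matrix(c(1, 2, 1, 3, 2, 3), ncol = 2, byrow = TRUE)
    if (g[s] == "AD") for (k in 1:3) {
      z[tri[k, 1], tri[k, 2]] <- z[tri[k, 1], tri[k, 2]] - 1
      z[tri[k, 2], tri[k, 1]] <- z[tri[k, 1], tri[k, 2]]
    }
    diag(z) <- 0
    dimnames(z) <- list(nodes, nodes)
    z
  })
  res <- nbs(fc_stack(fc), g, threshold_t = 6, n_perm = 200, seed = 4)
  cnt <- count_reduced(res)
  expect_equal(cnt$n_reduced_nodes, 3L)
  expect_equal(cnt$n_reduced_edges, 3L)
})

test_that("chi-square on 2x2 count tables matches the Pearson formula and conventions", {
  # equal proportions: chi2 = 0, p = 1
  eq <- chi_square_counts(5, 20, 5, 20)
  expect_equal(eq$chi2, 0)
  expect_equal(eq$p, 1)
  # hand evaluation of the Pearson formula without continuity correction
  hand_chi2 <- function(k1, n1, k2, n2) {
    tbl <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE)
    e <- outer(rowSums(tbl), colSums(tbl)) / sum(tbl)
    sum((tbl - e)^2 / e)
  }
  got <- chi_square_counts(7, 30, 15, 28)
  expect_equal(got$chi2, hand_chi2(7, 30, 15, 28), tolerance = 1e-12)
  expect_equal(got$p, pchisq(got$chi2, 1, lower.tail = FALSE))
  expect_error(chi_square_counts(0, 10, 0, 12), "margin")
  expect_error(chi_square_counts(5, 4, 1, 4))
})

test_that("NBS results export to edge and node text tables", {
  set.seed(16)
  fc <- lapply(1:20, function(s) {
    z <- matrix(rnorm(25, sd = 0.3), 5); z <- (z + t(z)) / 2; diag(z) <- 0
    dimnames(z) <- list(paste0("n", 1:5), paste0("n", 1:5)); z
  })
  res <- nbs(fc_stack(fc), rep(c("AD", "CN"), each = 10), threshold_t = 2,
             n_perm = 50, seed = 5)
  fe <- tempfile(); fn <- tempfile()
  write_nbs(res, fe, fn)
  ed <- read.delim(fe)
  expect_named(ed, c("node_i", "node_j", "t", "significant", "component_id"))
  expect_equal(nrow(ed), choose(5, 2))
  expect_equal(length(readLines(fn)), 5L)
})
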