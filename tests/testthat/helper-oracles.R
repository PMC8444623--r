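# Independent brute-force oracles and small fixtures used across tests.

# Naive O(n^2) sample-entropy template counter (Chebyshev distance,
# templates i = 1..n-m so every template has an (m+1)-extension).
oracle_sampen_counts <- function(x, m, r) {
  n <- length(x)
  N <- n - m
  A <- 0L; B <- 0L
  for (i in seq_len(N - 1L)) {
    for (j in (i + 1L):N) {
      dmax <- 0
      for (k in 0:(m - 1L)) dmax <- max(dmax, abs(x[i + k] - x[j + k]))
      if (dmax <= r) {
        B <- B + 1L
        if (max(dmax, abs(x[i + m] - x[j + m])) <= r) A <- A + 1L
      }
    }
  }
  c(A = A, B = B)
}

# Direct double-sum evaluation of weighted modularity.
oracle_modularity <- function(w, comm, gamma = 1) {
  two_m <- sum(w)
  k <- rowSums(w)
  q <- 0
  n <- nrow(w)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (comm[i] == comm[j])
      q <- q + w[i, j] - gamma * k[i] * k[j] / two_m
  unname(q / two_m)
}

# All set partitions of n elements as restricted-growth strings.
set_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxid) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxid + 1L)) recurse(c(prefix, v), max(maxid, v))
  }
  recurse(integer(0), 0L)
  out
}

# Exhaustive maximum-modularity search on a small graph.
oracle_best_partition <- function(w, gamma = 1) {
  parts <- set_partitions(nrow(w))
  qs <- vapply(parts, function(p) oracle_modularity(w, p, gamma), numeric(1))
  best <- which.max(qs)
  list(q = qs[best], assignment = parts[[best]])
}

# Two disconnected 3-cliques with unit weights.
two_cliques <- function() {
  w <- matrix(0, 6, 6)
  w[1:3, 1:3] <- 1
  w[4:6, 4:6] <- 1
  diag(w) <- 0
  dimnames(w) <- list(paste0("n", 1:6), paste0("n", 1:6))
  w
}

rand_sym_weights <- function(n, seed) {
  set.seed(seed)
  w <- matrix(stats::runif(n * n), n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  dimnames(w) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  w
}

# Small parcellation / planted partition for fast synthetic cohorts:
# 18 restricted nodes in three planted communities of 6, plus 6
# unrestricted (visual/somatomotor) nodes in a fourth block.
small_parcellation <- function() {
  nets <- c(rep(c("DMN", "limbic", "FPN"), each = 6),
            rep(c("visual", "somatomotor"), each = 3))
  data.frame(node_id = sprintf("p%02d", seq_along(nets)),
             a_priori_network = nets,
             hemisphere = rep(c("LH", "RH"), length.out = length(nets)),
             in_restricted_set = !nets %in% c("visual", "somatomotor"),
             stringsAsFactors = FALSE)
}

small_planted_partition <- function(parc = small_parcellation()) {
  comm <- c(rep(1:3, each = 6), rep(4L, 6))
  names(comm) <- parc$node_id
  comm
}

small_cohort_config <- function(n_per_group = 10L, seed = 1L, ...) {
  parc <- small_parcellation()
  cohort_config(n_per_group = n_per_group, n_nodes = nrow(parc),
                parcellation = parc,
                planted_partition = small_planted_partition(parc),
                phase_lengths = c(encoding = 40L, maintenance = 40L,
                                  retrieval = 60L),
                within_r = 0.4, between_r = 0.05,
                entropy_nodes = parc$node_id[1:3],
                seed = seed, ...)
}

# Linear structural mediation draw on standardized scales.
simulate_mediation_data <- function(n, a, b, cprime, seed) {
  set.seed(seed)
  tv <- stats::rnorm(n)
  mv <- a * tv + sqrt(max(0, 1 - a^2)) * stats::rnorm(n)
  resid_var <- max(0.05, 1 - b^2 - cprime^2 - 2 * a * b * cprime)
  yv <- cprime * tv + b * mv + sqrt(resid_var) * stats::rnorm(n)
  data.frame(suvr = tv, net_fc = mv, memory = yv,
             age = stats::rnorm(n, 70, 6),
             sex = sample(c("F", "M"), n, replace = TRUE),
             education = stats::rnorm(n, 12, 3))
}
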