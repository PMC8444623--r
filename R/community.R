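#' Weighted Newman-Girvan modularity of a partition
#'
#' Evaluates `Q = (1/2m) * sum_ij [w_ij - gamma * k_i k_j / (2m)] *
#' delta(c_i, c_j)` for an undirected non-negative weight matrix, where
#' `2m` is the total weight `sum_ij w_ij` and `k_i` the weighted degree.
#' Invariant under relabelling of the communities.
#'
#' @param weights symmetric non-negative matrix (diagonal ignored as
#'   given; self-loops contribute as in the formula).
#' @param assignment community id per node (integer/factor vector).
#' @param gamma resolution parameter.
#' @return scalar modularity Q.
#' @export
modularity_q <- function(weights, assignment, gamma = 1) {
  w <- as.matrix(weights)
  if (any(w < 0)) stop("modularity requires non-negative weights")
  if (max(abs(w - t(w))) > 1e-12) stop("weights must be symmetric")
  two_m <- sum(w)
  if (two_m <= 0) stop("total weight must be positive")
  k <- rowSums(w)
  comm <- as.integer(factor(assignment))
  q <- 0
  for (c_id in unique(comm)) {
    members <- comm == c_id
    q <- q + sum(w[members, members]) -
      gamma * sum(k[members])^2 / two_m
  }
  q / two_m
}

#' Louvain community detection on a weighted graph
#'
#' Greedy modularity maximisation (multilevel Louvain, via igraph) on a
#' symmetric non-negative weight matrix. Deterministic given `seed`.
#' Nodes isolated after weighting become singleton communities.
#' Communities are relabelled by descending node count so that community
#' 1 is always the largest ("Network 1").
#'
#' @param weights symmetric non-negative weight matrix with node names.
#' @param gamma resolution parameter.
#' @param seed integer seed controlling the stochastic sweep order.
#' @param n_restarts greedy runs to take the best-modularity result
#'   over; the single-run default is used inside consensus clustering,
#'   which supplies its own diversity.
#' @return object of class `community_partition`: list with `assignment`
#'   (named integer vector, ids contiguous from 1), `n_communities`,
#'   `modularity_q`, `gamma`.
#' @export
louvain <- function(weights, gamma = 1, seed = 1L, n_restarts = 10L) {
  w <- as.matrix(weights)
  if (any(w < 0)) stop("louvain requires non-negative weights")
  if (sum(w) <= 0) stop("all-zero weight matrix")
  diag(w) <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  best <- NULL
  best_q <- -Inf
  for (i in seq_len(max(1L, n_restarts))) {
    memb <- as.integer(igraph::membership(
      igraph::cluster_louvain(g, resolution = gamma)))
    q <- modularity_q(w, memb, gamma)
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- memb
    }
  }
  new_partition(relabel_by_size(best, rownames(w)),
                weights = w, gamma = gamma)
}

relabel_by_size <- function(comm, node_names = NULL) {
  sizes <- table(comm)
  # descending size; ties broken by smallest original label for stability
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  new_ids <- stats::setNames(seq_along(sizes), names(sizes)[ord])
  out <- as.integer(new_ids[as.character(comm)])
  names(out) <- node_names
  out
}

new_partition <- function(assignment, weights = NULL, gamma = 1) {
  q <- if (!is.null(weights)) modularity_q(weights, assignment, gamma) else NA_real_
  structure(list(assignment = assignment,
                 n_communities = length(unique(assignment)),
                 modularity_q = q, gamma = gamma),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  sizes <- table(x$assignment)
  cat(sprintf("<community_partition> %d communities over %d nodes (Q = %.4f, gamma = %g)\n",
              x$n_communities, length(x$assignment), x$modularity_q, x$gamma))
  cat("  sizes:", paste(sprintf("N%s=%d", names(sizes), sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Node-pair agreement matrix over a set of partitions
#'
#' Entry (i, j) is the fraction of partitions in which nodes i and j
#' share a community. Symmetric, unit diagonal, entries in [0, 1].
#'
#' @param assignments list of assignment vectors (same node order).
#' @return node-by-node agreement matrix.
#' @export
agreement_matrix <- function(assignments) {
  n <- length(assignments[[1L]])
  agree <- matrix(0, n, n)
  for (a in assignments) {
    ind <- outer(a, a, "==")
    agree <- agree + ind
  }
  agree <- agree / length(assignments)
  nm <- names(assignments[[1L]])
  if (!is.null(nm)) dimnames(agree) <- list(nm, nm)
  agree
}

same_partition <- function(a, b) {
  # identical up to relabelling: canonicalize by first occurrence
  canon <- function(x) as.integer(factor(x, levels = unique(x)))
  identical(canon(a), canon(b))
}

#' Consensus clustering of a weighted graph
#'
#' Runs Louvain `n_runs` times from distinct seeds; if the runs disagree,
#' builds the node-pair [agreement_matrix()], zeroes entries below `tau`,
#' and re-clusters the thresholded agreement matrix, iterating until all
#' runs return the same partition (up to relabelling). The fixed point is
#' returned with its modularity evaluated on the original weights.
#'
#' @inheritParams louvain
#' @param n_runs Louvain runs per consensus iteration.
#' @param tau agreement threshold in (0, 1).
#' @param max_iters maximum consensus iterations.
#' @return a `community_partition`; its `"iterations"` attribute records
#'   the consensus iterations used.
#' @export
consensus_partition <- function(weights, gamma = 1, n_runs = 100L, tau = 0.5,
                                seed = 1L, max_iters = 50L) {
  if (n_runs < 2L) stop("n_runs must be at least 2")
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)")
  w0 <- as.matrix(weights)
  w <- w0
  run_seeds <- seed + seq_len(n_runs) - 1L
  for (iter in seq_len(max_iters)) {
    runs <- lapply(run_seeds, function(s)
      louvain(w, gamma, seed = s, n_restarts = 1L)$assignment)
    if (all(vapply(runs[-1L], same_partition, logical(1), b = runs[[1L]]))) {
      out <- new_partition(relabel_by_size(runs[[1L]], rownames(w0)),
                           weights = w0, gamma = gamma)
      attr(out, "iterations") <- iter
      return(out)
    }
    agree <- agreement_matrix(runs)
    agree[agree < tau] <- 0
    diag(agree) <- 0
    if (sum(agree) == 0) stop("agreement matrix is empty after thresholding")
    w <- agree
    run_seeds <- run_seeds + n_runs  # fresh seeds each iteration
  }
  stop("consensus clustering did not converge in ", max_iters,
       " iterations; last agreement matrix attached as attribute",
       call. = FALSE)
}

#' Data-driven empirical networks from control-group connectivity
#'
#' The canonical detection path: average the control-group connectivity
#' matrices of the clustering phase (maintenance), restrict to the
#' parcellation's restricted node set (limbic/DMN/DAN/VAN/FPN), zero
#' negative weights, and run consensus Louvain clustering. Communities
#' are labelled by descending size (largest = "Network 1").
#'
#' @param group_fc list of connectivity matrices (one per control
#'   subject), all with identical node dimnames.
#' @param parcellation parcellation table with `node_id` and
#'   `in_restricted_set` columns.
#' @inheritParams consensus_partition
#' @return a `community_partition` over the restricted node set.
#' @export
restrict_and_cluster <- function(group_fc, parcellation, gamma = 1,
                                 n_runs = 100L, tau = 0.5, seed = 1L) {
  if (length(group_fc) < 2L) stop("need at least 2 control subjects")
  avg <- Reduce(`+`, group_fc) / length(group_fc)
  keep <- parcellation$node_id[parcellation$in_restricted_set]
  miss <- setdiff(keep, rownames(avg))
  if (length(miss)) stop("restricted nodes missing from FC matrices: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  w <- zero_negative(avg[keep, keep])
  consensus_partition(w, gamma = gamma, n_runs = n_runs, tau = tau, seed = seed)
}

#' Write a community partition as TSV
#'
#' Columns `node_id`, `community` and, when a parcellation is given,
#' `a_priori_network`.
#'
#' @param partition a `community_partition`.
#' @param path output file.
#' @param parcellation optional parcellation table for the a-priori
#'   network column.
#' @export
write_partition <- function(partition, path, parcellation = NULL) {
  df <- data.frame(node_id = names(partition$assignment),
                   community = unname(partition$assignment),
                   stringsAsFactors = FALSE)
  if (!is.null(parcellation))
    df$a_priori_network <- parcellation$a_priori_network[
      match(df$node_id, parcellation$node_id)]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
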