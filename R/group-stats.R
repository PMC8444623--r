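#' Two-sided permutation test on group means
#'
#' Resampling test of a group difference in a per-subject scalar: the
#' observed mean difference is compared with the null distribution
#' obtained by permuting group labels over the pooled subjects. The
#' p-value uses the add-one convention
#' `p = (1 + #{|diff_perm| >= |diff_obs|}) / (1 + n_perm)`.
#'
#' @param values_a,values_b numeric vectors of per-subject scalars.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return list with `mean_a`, `mean_b`, `diff` (a minus b), `p`,
#'   `n_perm`, and `low_perm` flag (TRUE when `n_perm < 100`).
#' @export
permutation_mean_test <- function(values_a, values_b, n_perm = 10000L,
                                  seed = 1L) {
  if (length(values_a) == 0L || length(values_b) == 0L)
    stop("both groups must be nonempty")
  low <- n_perm < 100L
  if (low) warning("n_perm < 100: permutation p-value is unreliable")
  # permute the sorted pooled values: the null distribution depends only on
  # the pooled multiset, and sorting makes p exactly label-swap invariant
  pooled <- sort(c(values_a, values_b))
  na <- length(values_a); n <- length(pooled)
  obs <- mean(values_a) - mean(values_b)
  set.seed(seed)
  exceed <- 0L
  sum_all <- sum(pooled)
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n, na)
    sa <- sum(pooled[idx])
    d <- sa / na - (sum_all - sa) / (n - na)
    if (abs(d) >= abs(obs) - 1e-12) exceed <- exceed + 1L
  }
  list(mean_a = mean(values_a), mean_b = mean(values_b), diff = obs,
       p = (1 + exceed) / (1 + n_perm), n_perm = n_perm, low_perm = low)
}

# Shared-permutation two-sided mean-difference p-values for a
# subjects-by-variables matrix; used by the node-wise entropy comparison.
perm_diff_pvals <- function(mat, is_a, n_perm = 10000L, seed = 1L) {
  mat <- as.matrix(mat)
  n <- nrow(mat); na <- sum(is_a); nb <- n - na
  stopifnot(na > 0L, nb > 0L)
  col_sums <- colSums(mat)
  obs <- colSums(mat[is_a, , drop = FALSE]) / na -
    colSums(mat[!is_a, , drop = FALSE]) / nb
  set.seed(seed)
  exceed <- integer(ncol(mat))
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n, na)
    sa <- colSums(mat[idx, , drop = FALSE])
    d <- sa / na - (col_sums - sa) / nb
    exceed <- exceed + (abs(d) >= abs(obs) - 1e-12)
  }
  list(diff = obs, p = (1 + exceed) / (1 + n_perm))
}

#' Stack per-subject connectivity matrices into an edge matrix
#'
#' Vectorizes the upper triangle of each subject's connectivity matrix
#' (optionally restricted to a node subset) into one row of a
#' subjects-by-edges matrix. The edge-to-node-pair map is attached as
#' the `"edges"` attribute (two-column matrix of node indices, `i < j`)
#' together with `"node_ids"`.
#'
#' @param fc_list list of symmetric connectivity matrices with node-id
#'   dimnames, one per subject.
#' @param nodes optional character vector restricting to a node subset.
#' @return subjects-by-edges numeric matrix.
#' @export
fc_stack <- function(fc_list, nodes = NULL) {
  if (is.null(nodes)) nodes <- rownames(fc_list[[1L]])
  ut <- which(upper.tri(diag(length(nodes))), arr.ind = TRUE)
  stk <- t(vapply(fc_list, function(z) {
    zz <- z[nodes, nodes]
    zz[upper.tri(zz)]
  }, numeric(nrow(ut))))
  attr(stk, "edges") <- ut
  attr(stk, "node_ids") <- nodes
  stk
}

resolve_positive <- function(group, positive_level) {
  g <- as.factor(group)
  if (nlevels(g) != 2L) stop("group must have exactly 2 levels")
  if (is.null(positive_level))
    positive_level <- if ("CN" %in% levels(g)) "CN" else levels(g)[2L]
  if (!positive_level %in% levels(g))
    stop("positive_level '", positive_level, "' is not a group level")
  as.numeric(g == positive_level)
}

# Frisch-Waugh t-statistics for the group indicator across many edges:
# residualize the indicator and the edge responses against the nuisance
# design, then t follows from the single remaining regressor.
fw_tstats <- function(x_res, y_res, xx, df) {
  beta <- as.numeric(crossprod(x_res, y_res)) / xx
  rss <- colSums(y_res^2) - beta^2 * xx
  rss[rss < 0] <- 0
  se <- sqrt(rss / df / xx)
  t <- beta / se
  t[se == 0] <- 0
  t
}

#' Edge-wise group GLM t-statistics with nuisance covariates
#'
#' Fits, per edge, ordinary least squares of the edge connectivity on an
#' intercept, the group indicator and the covariates, and returns the
#' group-coefficient t-statistic. Positive t means the `positive_level`
#' group (controls by default) has the higher connectivity. With no
#' covariates this is algebraically the pooled-variance two-sample
#' t-statistic.
#'
#' @param stack subjects-by-edges matrix (see [fc_stack()]).
#' @param group two-level factor (or character/logical) per subject.
#' @param covariates data.frame or matrix of per-subject nuisance
#'   covariates (e.g. age, sex), or `NULL`.
#' @param positive_level group level whose higher connectivity yields
#'   positive t; defaults to `"CN"` when present.
#' @return numeric vector of t-values (one per edge) with attributes
#'   `df` (residual degrees of freedom) and `edges` carried over.
#' @export
edgewise_glm_t <- function(stack, group, covariates = NULL,
                           positive_level = NULL) {
  y <- as.matrix(stack)
  n <- nrow(y)
  if (n <= 4L) stop("need more than 4 subjects")
  x <- resolve_positive(group, positive_level)
  Z <- cbind(intercept = rep(1, n),
             if (!is.null(covariates)) covariate_matrix(covariates))
  X <- cbind(Z, group = x)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("design matrix (intercept, group, covariates) is rank deficient")
  qrZ <- qr(Z)
  x_res <- qr.resid(qrZ, x)
  y_res <- qr.resid(qrZ, y)
  df <- n - ncol(X)
  t <- fw_tstats(x_res, y_res, sum(x_res^2), df)
  attr(t, "df") <- df
  attr(t, "edges") <- attr(stack, "edges")
  attr(t, "node_ids") <- attr(stack, "node_ids")
  t
}

covariate_matrix <- function(covariates) {
  if (is.null(covariates)) return(NULL)
  cf <- as.data.frame(lapply(as.data.frame(covariates), function(col) {
    if (is.character(col) || is.logical(col)) factor(col) else col
  }))
  # treatment contrasts (first level dropped) so the intercept stays estimable
  stats::model.matrix(~ ., data = cf)[, -1L, drop = FALSE]
}

# union-find over node indices; returns component label per edge
edge_components <- function(ei, ej, n_nodes) {
  parent <- seq_len(n_nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(ei)) {
    ri <- find(ei[k]); rj <- find(ej[k])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(ei, find, integer(1))
  match(roots, unique(roots))
}

max_component_edges <- function(ei, ej, n_nodes) {
  if (length(ei) == 0L) return(0L)
  comp <- edge_components(ei, ej, n_nodes)
  max(tabulate(comp))
}

#' Network-based statistic: suprathreshold component inference
#'
#' Edge-wise group GLM t-map, two-sided suprathreshold at
#' `threshold_t`, connected components on the graphs formed by the
#' positive and by the negative suprathreshold edges separately, and
#' family-wise-error component p-values from the permutation
#' distribution of the maximal component size (group labels permuted,
#' covariates kept with their subjects). Components significant at
#' `alpha` with positive t (controls above patients) define the reduced
#' nodes and edges.
#'
#' @inheritParams edgewise_glm_t
#' @param threshold_t primary suprathreshold on |t|; default is the
#'   two-sided p = 0.01 Student-t quantile at the design's residual
#'   degrees of freedom. Ties at the threshold are included.
#' @param n_perm permutations for the null maximal-component-size
#'   distribution.
#' @param alpha component-level FWER significance level.
#' @param seed integer seed.
#' @param phase optional phase label stored on the result.
#' @return object of class `nbs_result`.
#' @export
nbs <- function(stack, group, covariates = NULL, threshold_t = NULL,
                n_perm = 5000L, alpha = 0.05, seed = 1L,
                positive_level = NULL, phase = NULL) {
  y <- as.matrix(stack)
  n <- nrow(y)
  x <- resolve_positive(group, positive_level)
  Z <- cbind(intercept = rep(1, n),
             if (!is.null(covariates)) covariate_matrix(covariates))
  if (qr(cbind(Z, x))$rank < ncol(Z) + 1L)
    stop("design matrix (intercept, group, covariates) is rank deficient")
  qrZ <- qr(Z)
  df <- n - ncol(Z) - 1L
  if (is.null(threshold_t)) threshold_t <- stats::qt(1 - 0.01 / 2, df)
  if (threshold_t <= 0) stop("threshold_t must be positive")
  y_res <- qr.resid(qrZ, y)
  x_res <- qr.resid(qrZ, x)
  t_obs <- fw_tstats(x_res, y_res, sum(x_res^2), df)

  edges <- attr(stack, "edges")
  node_ids <- attr(stack, "node_ids")
  if (is.null(edges)) stop("stack must carry an 'edges' attribute (see fc_stack)")
  n_nodes <- length(node_ids)

  observed_components <- function(tv) {
    out <- list()
    for (sgn in c(1, -1)) {
      sel <- which(if (sgn > 0) tv >= threshold_t else tv <= -threshold_t)
      if (!length(sel)) next
      comp <- edge_components(edges[sel, 1L], edges[sel, 2L], n_nodes)
      for (cid in seq_len(max(comp))) {
        eidx <- sel[comp == cid]
        nodes <- sort(unique(c(edges[eidx, 1L], edges[eidx, 2L])))
        out[[length(out) + 1L]] <- list(sign = sgn, edge_idx = eidx,
                                        n_edges = length(eidx),
                                        nodes = node_ids[nodes])
      }
    }
    out
  }
  comps <- observed_components(t_obs)

  # null distribution of the maximal component size (either sign)
  set.seed(seed)
  null_max <- integer(n_perm)
  for (p_i in seq_len(n_perm)) {
    xp <- x[sample.int(n)]
    xp_res <- qr.resid(qrZ, xp)
    tp <- fw_tstats(xp_res, y_res, sum(xp_res^2), df)
    mx <- 0L
    for (sgn in c(1, -1)) {
      sel <- which(if (sgn > 0) tp >= threshold_t else tp <= -threshold_t)
      if (length(sel))
        mx <- max(mx, max_component_edges(edges[sel, 1L], edges[sel, 2L], n_nodes))
    }
    null_max[p_i] <- mx
  }
  for (k in seq_along(comps))
    comps[[k]]$p <- (1 + sum(null_max >= comps[[k]]$n_edges)) / (1 + n_perm)

  sig <- vapply(comps, function(cp) cp$p <= alpha, logical(1))
  red <- sig & vapply(comps, function(cp) cp$sign > 0, logical(1))
  reduced_edge_idx <- unlist(lapply(comps[red], `[[`, "edge_idx"))
  reduced_nodes <- sort(unique(unlist(lapply(comps[red], `[[`, "nodes"))))

  structure(list(t_map = t_obs, threshold_t = threshold_t,
                 supra_mask = abs(t_obs) >= threshold_t,
                 components = comps, null_max = null_max,
                 reduced_nodes = reduced_nodes,
                 reduced_edge_idx = reduced_edge_idx,
                 edges = edges, node_ids = node_ids, df = df,
                 n_perm = n_perm, alpha = alpha, seed = seed, phase = phase),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result>%s %d nodes, %d edges; |t| >= %.3f (df = %d), %d permutations\n",
              if (!is.null(x$phase)) paste0(" ", x$phase, ":") else "",
              length(x$node_ids), length(x$t_map), x$threshold_t, x$df, x$n_perm))
  cat(sprintf("  %d suprathreshold edges in %d component(s); %d significant at alpha = %g\n",
              sum(x$supra_mask), length(x$components),
              sum(vapply(x$components, function(cp) cp$p <= x$alpha, logical(1))),
              x$alpha))
  cat(sprintf("  reduced (controls > patients): %d nodes, %d edges\n",
              length(x$reduced_nodes), length(x$reduced_edge_idx)))
  invisible(x)
}

#' @export
summary.nbs_result <- function(object, ...) {
  if (!length(object$components)) {
    cat("no suprathreshold components\n")
    return(invisible(object))
  }
  df <- data.frame(
    component = seq_along(object$components),
    sign = vapply(object$components, function(cp) cp$sign, numeric(1)),
    n_edges = vapply(object$components, function(cp) cp$n_edges, integer(1)),
    n_nodes = vapply(object$components, function(cp) length(cp$nodes), integer(1)),
    p = vapply(object$components, function(cp) cp$p, numeric(1)))
  print(df, row.names = FALSE)
  invisible(df)
}

#' Count reduced nodes and edges of an NBS result
#'
#' @param result an `nbs_result`.
#' @return one-row data.frame: `n_reduced_nodes`, `n_reduced_edges`,
#'   `n_total_nodes`, `phase`.
#' @export
count_reduced <- function(result) {
  stopifnot(inherits(result, "nbs_result"))
  data.frame(n_reduced_nodes = length(result$reduced_nodes),
             n_reduced_edges = length(result$reduced_edge_idx),
             n_total_nodes = length(result$node_ids),
             phase = if (is.null(result$phase)) NA_character_ else result$phase,
             stringsAsFactors = FALSE)
}

#' Pearson chi-square comparison of two reduced-node proportions
#'
#' Chi-square test without continuity correction on the 2x2 table
#' `[[k1, n1 - k1], [k2, n2 - k2]]` (df = 1, two-sided), e.g. to compare
#' counts of nodes with reduced connectivity between two memory phases.
#'
#' @param k1,n1 reduced count and total in condition 1.
#' @param k2,n2 reduced count and total in condition 2.
#' @return list with `chi2`, `p`, `table`.
#' @export
chi_square_counts <- function(k1, n1, k2, n2) {
  stopifnot(k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2, n1 > 0, n2 > 0)
  tbl <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE,
                dimnames = list(c("cond1", "cond2"), c("reduced", "not")))
  if (any(colSums(tbl) == 0))
    stop("chi-square undefined: a table margin is empty")
  ct <- suppressWarnings(stats::chisq.test(tbl, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value), table = tbl)
}

#' Export an NBS result as edge and node tables
#'
#' Writes a long edge table (`node_i node_j t significant component_id`)
#' and a BrainNet-style space-separated node table (coordinates if
#' given, size = incident significant edges, color = community).
#'
#' @param result an `nbs_result`.
#' @param edge_path,node_path output files.
#' @param coords optional data.frame `node_id, x, y, z`.
#' @param communities optional named community vector for the color
#'   column.
#' @export
write_nbs <- function(result, edge_path, node_path = NULL, coords = NULL,
                      communities = NULL) {
  ed <- result$edges
  comp_id <- rep(NA_integer_, length(result$t_map))
  sig <- rep(FALSE, length(result$t_map))
  for (k in seq_along(result$components)) {
    comp_id[result$components[[k]]$edge_idx] <- k
    if (result$components[[k]]$p <= result$alpha)
      sig[result$components[[k]]$edge_idx] <- TRUE
  }
  df <- data.frame(node_i = result$node_ids[ed[, 1L]],
                   node_j = result$node_ids[ed[, 2L]],
                   t = as.numeric(result$t_map),
                   significant = as.integer(sig),
                   component_id = comp_id)
  utils::write.table(df, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(node_path)) {
    deg <- integer(length(result$node_ids))
    sig_e <- which(sig)
    for (k in sig_e) {
      deg[ed[k, 1L]] <- deg[ed[k, 1L]] + 1L
      deg[ed[k, 2L]] <- deg[ed[k, 2L]] + 1L
    }
    nd <- data.frame(x = 0, y = 0, z = 0,
                     color = 1L, size = deg, label = result$node_ids)
    if (!is.null(coords)) {
      m <- match(result$node_ids, coords$node_id)
      nd$x <- coords$x[m]; nd$y <- coords$y[m]; nd$z <- coords$z[m]
    }
    if (!is.null(communities))
      nd$color <- unname(communities[result$node_ids])
    utils::write.table(nd, node_path, sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(edge_path)
}
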