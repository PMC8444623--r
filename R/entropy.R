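#' Sample entropy template-match counts
#'
#' Integer counts (A, B) underlying sample entropy: over the `n - m`
#' templates that admit a length-`(m + 1)` extension, `B` counts
#' template pairs of length `m` within Chebyshev distance `r`
#' (self-matches excluded) and `A` counts the pairs whose extensions
#' also match. Computed in C++.
#'
#' @param ts numeric series.
#' @param m embedding dimension.
#' @param r tolerance (absolute units of the series).
#' @return named numeric vector `c(A = , B = )`.
#' @export
sampen_counts <- function(ts, m = 2L, r) {
  if (length(ts) < m + 2L) stop("series must have length >= m + 2")
  if (r <= 0) stop("tolerance r must be positive")
  sampen_counts_cpp(as.numeric(ts), as.integer(m), r)
}

#' Sample entropy of a time series
#'
#' `SampEn(m, r) = -ln(A / B)` with the template counts of
#' [sampen_counts()]. Lower values indicate more ordered, predictable
#' signals. The tolerance is `r = r_factor * sd` where `sd` defaults to
#' the series' own standard deviation; pass `sd` explicitly to use a
#' scope pooled over all of a subject's node time courses, or pass `r`
#' directly. Returns `+Inf` when no length-`(m + 1)` match exists
#' (`A = 0`), and `NaN` when `B = 0`.
#'
#' @inheritParams sampen_counts
#' @param r explicit tolerance; overrides `r_factor` and `sd`.
#' @param r_factor tolerance as a fraction of the standard deviation.
#' @param sd standard deviation defining the tolerance scope; default is
#'   `sd(ts)` (per-node scope).
#' @return scalar sample entropy.
#' @export
sample_entropy <- function(ts, m = 2L, r = NULL, r_factor = 0.2, sd = NULL) {
  if (is.null(r)) {
    if (is.null(sd)) sd <- stats::sd(ts)
    r <- r_factor * sd
    if (!is.finite(r) || r <= 0)
      stop("tolerance r = r_factor * sd is not positive (constant series?); ",
           "use the pooled all-time-courses scope or pass r explicitly")
  }
  cnt <- sampen_counts(ts, m = m, r = r)
  if (cnt[["B"]] == 0) return(NaN)
  if (cnt[["A"]] == 0) return(Inf)
  -log(cnt[["A"]] / cnt[["B"]])
}

#' Node-wise sample entropy of one phase
#'
#' Computes sample entropy for every node time course of a
#' [phase_bold]. With the default `"all_timecourses"` scope the
#' tolerance is `r_factor` times the standard deviation pooled over all
#' node time courses of the phase (one common r for the subject); with
#' `"per_node"` each node uses its own SD.
#'
#' @param pb a [phase_bold].
#' @param m embedding dimension.
#' @param r_factor tolerance factor.
#' @param sd_scope `"all_timecourses"` or `"per_node"`.
#' @return named numeric vector of per-node sample entropy.
#' @export
phase_sampen <- function(pb, m = 2L, r_factor = 0.2,
                         sd_scope = c("all_timecourses", "per_node")) {
  sd_scope <- match.arg(sd_scope)
  dat <- if (inherits(pb, "phase_bold")) pb$data else pb
  pooled <- if (sd_scope == "all_timecourses") stats::sd(as.vector(dat)) else NULL
  vapply(seq_len(nrow(dat)), function(i)
    sample_entropy(dat[i, ], m = m, r_factor = r_factor, sd = pooled),
    numeric(1)) |> stats::setNames(rownames(dat))
}

#' Group comparison of node-wise sample entropy
#'
#' Per-node permutation test (shared label permutations across nodes) of
#' the group difference in sample entropy for one memory phase. Nodes
#' with patient mean below control mean at `p <= alpha` are flagged, and
#' their overlap with a supplied set of reduced-connectivity nodes is
#' reported.
#'
#' @param cohort a `memnet_cohort` (or list of subject records with
#'   `group` and `phases`).
#' @param phase which phase to analyse.
#' @param nodes optional node subset (default: all nodes).
#' @param m,r_factor,sd_scope entropy settings, see [phase_sampen()].
#' @param n_perm label permutations.
#' @param seed integer seed.
#' @param reduced_nodes optional node ids with reduced connectivity, for
#'   the overlap column.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @param alpha significance level on the (adjusted) p-value.
#' @return data.frame `node_id, phase, sampen_ad_mean, sampen_cn_mean,
#'   diff, p, significant, overlaps_reduced_fc`. Nodes where any subject
#'   has non-finite entropy get `NA` p.
#' @export
entropy_group_compare <- function(cohort, phase, nodes = NULL, m = 2L,
                                  r_factor = 0.2,
                                  sd_scope = "all_timecourses",
                                  n_perm = 10000L, seed = 1L,
                                  reduced_nodes = NULL, p_adjust = "none",
                                  alpha = 0.05) {
  subs <- if (inherits(cohort, "memnet_cohort")) cohort$subjects else cohort
  grp <- vapply(subs, `[[`, character(1), "group")
  if (length(unique(grp)) != 2L) stop("cohort must contain both groups")
  se_mat <- t(vapply(subs, function(s) {
    pb <- s$phases[[phase]]
    if (is.null(pb)) stop("subject ", s$subject, " lacks phase ", phase)
    se <- phase_sampen(pb, m = m, r_factor = r_factor, sd_scope = sd_scope)
    if (!is.null(nodes)) se[nodes] else se
  }, numeric(if (is.null(nodes)) nrow(subs[[1L]]$phases[[phase]]$data)
             else length(nodes))))
  node_ids <- colnames(se_mat)
  is_ad <- grp == "AD"
  ok <- apply(is.finite(se_mat), 2L, all)
  p <- rep(NA_real_, ncol(se_mat))
  dif <- colMeans(se_mat[is_ad, , drop = FALSE]) -
    colMeans(se_mat[!is_ad, , drop = FALSE])
  if (any(ok)) {
    pt <- perm_diff_pvals(se_mat[, ok, drop = FALSE], is_ad,
                          n_perm = n_perm, seed = seed)
    p[ok] <- pt$p
  }
  if (p_adjust != "none") p <- stats::p.adjust(p, method = p_adjust)
  sig <- !is.na(p) & p <= alpha & dif < 0
  data.frame(node_id = node_ids, phase = phase,
             sampen_ad_mean = colMeans(se_mat[is_ad, , drop = FALSE]),
             sampen_cn_mean = colMeans(se_mat[!is_ad, , drop = FALSE]),
             diff = dif, p = p, significant = sig,
             overlaps_reduced_fc = if (is.null(reduced_nodes)) NA
                                   else node_ids %in% reduced_nodes,
             row.names = NULL, stringsAsFactors = FALSE)
}
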