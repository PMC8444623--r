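#' Pearson correlation with permutation p-value
#'
#' Pearson r between two per-subject scalars, with a two-sided p-value
#' from permuting `y`, `p = (1 + #{|r_perm| >= |r_obs|}) / (1 + n_perm)`.
#'
#' @param x,y numeric vectors of equal length (n >= 4).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `r`, `p`, `n`, `n_perm`.
#' @export
corr_perm <- function(x, y, n_perm = 10000L, seed = 1L) {
  n <- length(x)
  if (n < 4L || length(y) != n) stop("x and y must have equal length >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  r_obs <- stats::cor(x, y)
  xc <- as.numeric(scale(x)); yc <- as.numeric(scale(y))
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    rp <- sum(xc * yc[sample.int(n)]) / (n - 1)
    if (abs(rp) >= abs(r_obs) - 1e-12) exceed <- exceed + 1L
  }
  list(r = r_obs, p = (1 + exceed) / (1 + n_perm), n = n, n_perm = n_perm)
}

#' Covariate-adjusted standardized regression coefficient
#'
#' OLS of a z-scored outcome on a z-scored predictor plus covariates
#' (age, sex, education by default in the pipeline), returning the
#' standardized coefficient of the predictor with its Wald p-value.
#'
#' @param outcome,predictor numeric vectors; z-scored internally.
#' @param covariates data.frame/matrix of nuisance covariates or `NULL`.
#' @return list with `beta_std`, `se`, `p`, `df`.
#' @export
glm_adjusted <- function(outcome, predictor, covariates = NULL) {
  y <- as.numeric(scale(outcome))
  x <- as.numeric(scale(predictor))
  X <- cbind(intercept = 1, predictor = x,
             if (!is.null(covariates)) covariate_matrix(covariates))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient")
  fit <- stats::lm.fit(X, y)
  df <- length(y) - ncol(X)
  rss <- sum(fit$residuals^2)
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(rss / df * XtXinv[2L, 2L])
  beta <- unname(fit$coefficients["predictor"])
  list(beta_std = beta, se = se,
       p = 2 * stats::pt(abs(beta / se), df, lower.tail = FALSE), df = df)
}

# point estimates of the linear-no-interaction mediation paths on a
# (already standardized) data matrix: columns t, m, y, then covariates
med_paths <- function(tv, mv, yv, Z) {
  Xm <- cbind(1, tv, Z)
  Xy <- cbind(1, tv, mv, Z)
  cm <- stats::lm.fit(Xm, mv)$coefficients
  cy <- stats::lm.fit(Xy, yv)$coefficients
  a <- unname(cm[2L]); cp <- unname(cy[2L]); b <- unname(cy[3L])
  c(acme = a * b, ade = cp, total = a * b + cp, a = a, b = b)
}

bca_ci <- function(theta_hat, boot, jack, conf = 0.95) {
  boot <- boot[is.finite(boot)]
  if (length(boot) < 10L || stats::sd(boot) == 0)
    return(c(theta_hat, theta_hat))
  alpha <- (1 - conf) / 2
  z0 <- stats::qnorm(mean(boot < theta_hat) +
                       0.5 * mean(boot == theta_hat))
  if (!is.finite(z0)) return(stats::quantile(boot, c(alpha, 1 - alpha),
                                             names = FALSE))
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * (sum((jm - jack)^2))^1.5
  acc <- if (den == 0) 0 else num / den
  adj <- function(a) {
    zq <- z0 + stats::qnorm(a)
    stats::pnorm(z0 + zq / (1 - acc * zq))
  }
  stats::quantile(boot, c(adj(alpha), adj(1 - alpha)), names = FALSE,
                  type = 6)
}

#' Causal mediation analysis with bootstrap intervals
#'
#' Linear-Gaussian mediation with no treatment-mediator interaction:
#' fits the mediator model `M ~ T + X` and the outcome model
#' `Y ~ T + M + X`, giving the average causal mediation effect
#' `ACME = a * b`, the average direct effect `ADE = c'` and the total
#' effect `a * b + c'` (which equals the coefficient of `T` in the
#' reduced model `Y ~ T + X`). Treatment, mediator and outcome are
#' z-scored first so effects are on the standardized scale. Uncertainty
#' comes from a nonparametric bootstrap over subjects with
#' bias-corrected and accelerated (BCa, jackknife acceleration)
#' intervals; percentile intervals are available as a faster option.
#' Two-sided bootstrap p-values use the add-one convention on the
#' bootstrap sign distribution.
#'
#' @param data data.frame holding the variables.
#' @param treatment,mediator,outcome column names (e.g. amyloid SUVR,
#'   retrieval-phase network connectivity, memory score).
#' @param covariates character vector of covariate column names (or
#'   `NULL`).
#' @param n_boot bootstrap draws.
#' @param seed integer seed.
#' @param ci `"bca"` or `"percentile"`.
#' @param conf confidence level.
#' @return object of class `mediation_fit` with elements `acme`, `ade`,
#'   `total`, `prop_mediated`, per-effect `ci` and `p`, `n`, `n_boot`,
#'   `n_skipped` (degenerate resamples), `seed`.
#' @export
mediate_fc <- function(data, treatment, mediator, outcome,
                       covariates = c("age", "sex", "education"),
                       n_boot = 10000L, seed = 1L,
                       ci = c("bca", "percentile"), conf = 0.95) {
  ci <- match.arg(ci)
  n <- nrow(data)
  if (n < 10L) stop("mediation requires at least 10 subjects")
  tv <- as.numeric(scale(data[[treatment]]))
  mv <- as.numeric(scale(data[[mediator]]))
  yv <- as.numeric(scale(data[[outcome]]))
  if (anyNA(c(tv, mv, yv))) stop("degenerate (constant or missing) variable")
  Z <- if (length(covariates)) covariate_matrix(data[covariates]) else NULL
  if (!is.null(Z) && qr(cbind(1, tv, mv, Z))$rank < 3L + ncol(Z))
    stop("design matrix is rank deficient")
  est <- med_paths(tv, mv, yv, Z)

  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, 3L,
                 dimnames = list(NULL, c("acme", "ade", "total")))
  skipped <- 0L
  for (bi in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    tb <- tv[idx]; mb <- mv[idx]; yb <- yv[idx]
    Zb <- if (!is.null(Z)) Z[idx, , drop = FALSE] else NULL
    if (stats::sd(tb) == 0 || stats::sd(mb) == 0 || stats::sd(yb) == 0) {
      skipped <- skipped + 1L
      next
    }
    pb <- tryCatch(med_paths(tb, mb, yb, Zb), error = function(e) NULL)
    if (is.null(pb) || anyNA(pb[1:3])) { skipped <- skipped + 1L; next }
    boot[bi, ] <- pb[1:3]
  }

  jack <- NULL
  if (ci == "bca") {
    jack <- t(vapply(seq_len(n), function(i) {
      med_paths(tv[-i], mv[-i], yv[-i],
                if (!is.null(Z)) Z[-i, , drop = FALSE] else NULL)[1:3]
    }, numeric(3)))
  }
  eff <- c("acme", "ade", "total")
  cis <- lapply(eff, function(e) {
    bs <- boot[, e]
    if (ci == "bca") bca_ci(est[[e]], bs, jack[, e], conf)
    else stats::quantile(bs[is.finite(bs)], c((1 - conf) / 2, 1 - (1 - conf) / 2),
                         names = FALSE, type = 6)
  })
  names(cis) <- eff
  pvals <- vapply(eff, function(e) {
    bs <- boot[is.finite(boot[, e]), e]
    2 * min((1 + sum(bs <= 0)) / (1 + length(bs)),
            (1 + sum(bs >= 0)) / (1 + length(bs)))
  }, numeric(1))
  pvals <- pmin(pvals, 1)

  structure(list(acme = unname(est[["acme"]]), ade = unname(est[["ade"]]),
                 total = unname(est[["total"]]),
                 prop_mediated = unname(est[["acme"]] /
                                          ifelse(est[["total"]] == 0, NA,
                                                 est[["total"]])),
                 a = unname(est[["a"]]), b = unname(est[["b"]]),
                 ci = cis, p = pvals, ci_type = ci, conf = conf,
                 n = n, n_boot = n_boot, n_skipped = skipped, seed = seed,
                 vars = c(treatment = treatment, mediator = mediator,
                          outcome = outcome)),
            class = "mediation_fit")
}

#' @export
print.mediation_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<mediation_fit> %s -> %s -> %s (n = %d, %d bootstrap draws, %s CI)\n",
              x$vars[["treatment"]], x$vars[["mediator"]], x$vars[["outcome"]],
              x$n, x$n_boot, toupper(x$ci_type)))
  for (e in c("acme", "ade", "total")) {
    cat(sprintf("  %-5s %8.*f  [%.*f, %.*f]  p = %.3g\n", toupper(e),
                digits, x[[e]], digits, x$ci[[e]][1], digits, x$ci[[e]][2],
                x$p[[e]]))
  }
  cat(sprintf("  proportion mediated: %.*f\n", digits, x$prop_mediated))
  invisible(x)
}

#' @export
summary.mediation_fit <- function(object, ...) {
  df <- data.frame(effect = c("acme", "ade", "total"),
                   estimate = c(object$acme, object$ade, object$total),
                   ci_low = vapply(object$ci, `[`, numeric(1), 1L),
                   ci_high = vapply(object$ci, `[`, numeric(1), 2L),
                   p = unname(object$p), row.names = NULL)
  df
}
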