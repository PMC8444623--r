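#' Fisher-z functional connectivity matrix
#'
#' Computes the node-by-node functional connectivity of one phase of one
#' subject as the Fisher z-transform (`atanh`) of the Pearson correlation
#' between node time courses. Correlations are clamped to
#' `+/-(1 - 1e-7)` before the transform so that perfectly correlated
#' nodes yield a large but finite z. The diagonal is set to 0 by
#' convention (self-connectivity is undefined).
#'
#' @param phase_bold a [phase_bold] object, or a nodes-by-volumes numeric
#'   matrix with node ids as row names.
#' @return a symmetric numeric matrix of Fisher-z values with node ids as
#'   dimnames and attributes `subject` and `phase` carried over from the
#'   input when present.
#' @examples
#' x <- matrix(rnorm(40), nrow = 4,
#'             dimnames = list(paste0("n", 1:4), NULL))
#' z <- compute_fc(x)
#' max(abs(z - t(z)))  # 0: symmetric
#' @export
compute_fc <- function(phase_bold) {
  dat <- if (inherits(phase_bold, "phase_bold")) phase_bold$data else phase_bold
  if (!is.matrix(dat) || !is.numeric(dat))
    stop("phase_bold must be a numeric nodes-by-volumes matrix")
  if (ncol(dat) < 4L)
    stop("at least 4 volumes are required to estimate connectivity")
  v <- apply(dat, 1L, stats::var)
  if (any(v <= 0 | !is.finite(v))) {
    bad <- rownames(dat)[v <= 0 | !is.finite(v)]
    if (is.null(bad)) bad <- which(v <= 0 | !is.finite(v))
    stop("zero-variance node(s): ", paste(bad, collapse = ", "))
  }
  r <- stats::cor(t(dat))
  clamp <- 1 - 1e-7
  r[r > clamp] <- clamp
  r[r < -clamp] <- -clamp
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2  # enforce exact symmetry against rounding
  if (inherits(phase_bold, "phase_bold")) {
    attr(z, "subject") <- phase_bold$subject
    attr(z, "phase") <- phase_bold$phase
  }
  z
}

#' Zero out negative connectivity weights
#'
#' Entrywise `max(z, 0)`. Used on the community-detection path only:
#' group comparisons and [mean_connectivity()] operate on signed z.
#'
#' @param z a numeric connectivity matrix.
#' @return the matrix with negative entries replaced by 0.
#' @export
zero_negative <- function(z) {
  z[z < 0] <- 0
  z
}

#' Mean connectivity within or between node sets
#'
#' Within-set mean: average of `z[i, j]` over unordered pairs `i < j`
#' inside `set_a` (diagonal excluded). Between-set mean: average over all
#' cross pairs of two disjoint sets.
#'
#' @param z symmetric connectivity matrix with node ids as dimnames (or
#'   indexable by integer).
#' @param set_a,set_b node ids (or integer indices). Omit `set_b` (or
#'   pass the same set) for the within-set mean.
#' @return scalar mean connectivity.
#' @export
mean_connectivity <- function(z, set_a, set_b = NULL) {
  idx <- function(s) {
    if (is.character(s)) {
      i <- match(s, rownames(z))
      if (anyNA(i)) stop("unknown node id(s): ", paste(s[is.na(i)], collapse = ", "))
      i
    } else as.integer(s)
  }
  a <- idx(set_a)
  if (is.null(set_b) || (length(set_b) == length(set_a) && all(idx(set_b) %in% a) &&
                         all(a %in% idx(set_b)))) {
    if (length(a) < 2L) stop("within-set mean requires at least 2 nodes")
    sub <- z[a, a, drop = FALSE]
    mean(sub[upper.tri(sub)])
  } else {
    b <- idx(set_b)
    if (length(intersect(a, b)) > 0L)
      stop("between-set mean requires disjoint node sets")
    mean(z[a, b, drop = FALSE])
  }
}

#' Write / read a connectivity matrix as TSV
#'
#' Square TSV with a node-id header (wide form), or a long-form edge list
#' `node_i node_j z` over the upper triangle.
#'
#' @param z connectivity matrix.
#' @param path output file.
#' @param format `"square"` or `"edges"`.
#' @export
write_fc <- function(z, path, format = c("square", "edges")) {
  format <- match.arg(format)
  if (format == "square") {
    df <- data.frame(node_id = rownames(z), z, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    ut <- which(upper.tri(z), arr.ind = TRUE)
    df <- data.frame(node_i = rownames(z)[ut[, 1L]],
                     node_j = colnames(z)[ut[, 2L]],
                     z = z[ut])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_fc
#' @export
read_fc <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}
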