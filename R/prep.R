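#' One phase of node time courses
#'
#' Container for the BOLD time courses of one memory phase of one
#' subject: a nodes-by-volumes matrix plus timing metadata.
#'
#' @param data numeric nodes-by-volumes matrix; row names are node ids.
#' @param phase one of `"encoding"`, `"maintenance"`, `"retrieval"`.
#' @param tr_seconds repetition time in seconds.
#' @param subject optional subject id.
#' @return an object of class `phase_bold`.
#' @export
phase_bold <- function(data, phase, tr_seconds = 3, subject = NULL) {
  phase <- match.arg(phase, c("encoding", "maintenance", "retrieval"))
  if (!is.matrix(data) || !is.numeric(data))
    stop("data must be a numeric matrix (nodes x volumes)")
  if (anyNA(data)) stop("phase data contains NA values")
  if (ncol(data) < 4L) stop("phase must contain at least 4 volumes")
  structure(list(data = data, phase = phase, tr_seconds = tr_seconds,
                 subject = subject, node_ids = rownames(data)),
            class = "phase_bold")
}

#' @export
print.phase_bold <- function(x, ...) {
  cat(sprintf("<phase_bold> %s%s: %d nodes x %d volumes (TR %gs)\n",
              if (!is.null(x$subject)) paste0(x$subject, " ") else "",
              x$phase, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' Regress confound time series out of a run
#'
#' Ordinary least-squares removal of nuisance signals (head motion,
#' tissue components, outlier indicators, task regressors supplied as
#' columns) from every node time course. An intercept is always added,
#' so the output is demeaned. Residuals are exactly orthogonal to every
#' confound column.
#'
#' @param run volumes-by-nodes numeric matrix (time in rows).
#' @param confounds volumes-by-k numeric matrix or data.frame of
#'   confound columns; `NULL` for intercept-only (demeaning).
#' @return residual matrix, same shape as `run`.
#' @export
regress_confounds <- function(run, confounds = NULL) {
  if (!is.matrix(run)) run <- as.matrix(run)
  n <- nrow(run)
  if (is.null(confounds)) {
    X <- matrix(1, n, 1L, dimnames = list(NULL, "intercept"))
  } else {
    cf <- as.matrix(confounds)
    if (nrow(cf) != n)
      stop("confounds have ", nrow(cf), " rows but the run has ", n, " volumes")
    if (is.null(colnames(cf))) colnames(cf) <- paste0("confound", seq_len(ncol(cf)))
    X <- cbind(intercept = 1, cf)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("confound matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  res <- qr.resid(qrX, run)
  dimnames(res) <- dimnames(run)
  res
}

#' Band-pass filter and linearly detrend node time courses
#'
#' Removes the per-column linear trend, then applies a zero-phase
#' (forward-backward) 2nd-order Butterworth band-pass. Defaults match
#' the conventional task-connectivity band of 0.008-0.09 Hz. Zero-phase
#' filtering avoids shifting phase boundaries in time.
#'
#' @param run volumes-by-nodes numeric matrix.
#' @param low_hz,high_hz band edges in Hz.
#' @param tr_seconds repetition time in seconds; sampling rate is
#'   `1 / tr_seconds`.
#' @return filtered matrix, same shape.
#' @export
bandpass_detrend <- function(run, low_hz = 0.008, high_hz = 0.09,
                             tr_seconds = 3) {
  if (!is.matrix(run)) run <- as.matrix(run)
  fs <- 1 / tr_seconds
  nyq <- fs / 2
  if (high_hz >= nyq)
    stop(sprintf("upper band edge %.3f Hz is not below Nyquist %.3f Hz (TR %gs)",
                 high_hz, nyq, tr_seconds))
  if (low_hz <= 0 || low_hz >= high_hz)
    stop("band edges must satisfy 0 < low_hz < high_hz")
  n <- nrow(run)
  t <- seq_len(n)
  X <- cbind(1, t - mean(t))
  trend <- X %*% qr.solve(X, run)
  detr <- run - trend
  bf <- signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
  out <- apply(detr, 2L, function(col) signal::filtfilt(bf, col))
  dimnames(out) <- dimnames(run)
  out
}

#' Split a denoised run into memory phases
#'
#' Cuts a full-run volumes-by-nodes matrix into per-phase [phase_bold]
#' objects using half-open, 0-based volume intervals `[start, end)`.
#' Intervals must lie inside the run and must not overlap. Use
#' [events_from_seconds()] to convert an event table given in seconds.
#'
#' @param run volumes-by-nodes matrix (node ids as column names).
#' @param events data.frame with columns `phase`, `start_volume`,
#'   `end_volume` (0-based half-open).
#' @param tr_seconds repetition time, stored on the outputs.
#' @param subject optional subject id, stored on the outputs.
#' @return named list of [phase_bold] objects (nodes x volumes).
#' @export
split_phases <- function(run, events, tr_seconds = 3, subject = NULL) {
  if (!is.matrix(run)) run <- as.matrix(run)
  n <- nrow(run)
  if (nrow(events) == 0L) return(stats::setNames(list(), character(0)))
  req <- c("phase", "start_volume", "end_volume")
  if (!all(req %in% names(events)))
    stop("events must have columns: ", paste(req, collapse = ", "))
  ev <- events[order(events$start_volume), , drop = FALSE]
  if (any(ev$start_volume < 0L) || any(ev$end_volume > n))
    stop("event interval outside the run (", n, " volumes)")
  if (any(ev$end_volume <= ev$start_volume))
    stop("event intervals must be non-empty half-open [start, end)")
  if (nrow(ev) > 1L && any(ev$start_volume[-1L] < ev$end_volume[-nrow(ev)]))
    stop("event intervals overlap")
  out <- lapply(seq_len(nrow(ev)), function(i) {
    vols <- (ev$start_volume[i] + 1L):ev$end_volume[i]  # 0-based -> R index
    phase_bold(t(run[vols, , drop = FALSE]), phase = as.character(ev$phase[i]),
               tr_seconds = tr_seconds, subject = subject)
  })
  stats::setNames(out, as.character(ev$phase))
}

#' Convert an event table in seconds to volume intervals
#'
#' Onsets map by `floor(start_s / TR)`, offsets by `ceiling(end_s / TR)`,
#' giving 0-based half-open volume intervals.
#'
#' @param events_s data.frame with columns `phase`, `start_s`, `end_s`.
#' @param tr_seconds repetition time in seconds.
#' @return data.frame with `phase`, `start_volume`, `end_volume`.
#' @export
events_from_seconds <- function(events_s, tr_seconds = 3) {
  data.frame(phase = as.character(events_s$phase),
             start_volume = as.integer(floor(events_s$start_s / tr_seconds)),
             end_volume = as.integer(ceiling(events_s$end_s / tr_seconds)),
             stringsAsFactors = FALSE)
}

#' Full-run denoising followed by phase segmentation
#'
#' The conventional order: confound regression, then band-pass with
#' linear detrending on the complete run, then the split into phases.
#' Denoising the complete run and then splitting is not equivalent to
#' splitting first and denoising each phase separately (the filter and
#' the trend see different data); this pipeline fixes the former.
#'
#' @inheritParams regress_confounds
#' @inheritParams bandpass_detrend
#' @inheritParams split_phases
#' @return named list of [phase_bold] objects.
#' @export
prepare_run <- function(run, events, confounds = NULL, low_hz = 0.008,
                        high_hz = 0.09, tr_seconds = 3, subject = NULL) {
  res <- regress_confounds(run, confounds)
  filt <- bandpass_detrend(res, low_hz, high_hz, tr_seconds)
  split_phases(filt, events, tr_seconds = tr_seconds, subject = subject)
}
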