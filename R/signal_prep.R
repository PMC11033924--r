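#' Construct a parcellated time series
#'
#' @param matrix P x T numeric matrix (rows = parcels, columns = timepoints).
#' @param tr sampling interval in seconds.
#' @param subject_id subject identifier.
#' @return A `parcel_timeseries` object.
#' @export
parcel_timeseries <- function(matrix, tr, subject_id = "") {
  stopifnot(is.matrix(matrix), is.numeric(matrix), tr > 0)
  structure(list(matrix = matrix, tr = tr, subject_id = as.character(subject_id)),
            class = "parcel_timeseries")
}

#' @export
print.parcel_timeseries <- function(x, ...) {
  cat("Parcel time series", if (nzchar(x$subject_id)) paste0("'", x$subject_id, "'"),
      ":", nrow(x$matrix), "parcels x", ncol(x$matrix),
      "timepoints, TR =", x$tr, "s\n")
  invisible(x)
}

#' Regress nuisance confounds out of a time series
#'
#' Replaces each parcel's series by the residual of its least-squares
#' projection onto an intercept plus the confound columns. Rank-deficient
#' confound sets are handled by the pivoted QR decomposition: linearly
#' dependent columns are dropped (with a warning naming them).
#'
#' @param ts a [parcel_timeseries()].
#' @param confounds T x C numeric matrix or data.frame of nuisance regressors
#'   (may have zero columns: then only the temporal mean is removed).
#' @return A [parcel_timeseries()] of residuals (each parcel mean ~ 0).
#' @export
regress_confounds <- function(ts, confounds = NULL) {
  stopifnot(inherits(ts, "parcel_timeseries"))
  T_len <- ncol(ts$matrix)
  if (is.null(confounds)) confounds <- matrix(numeric(0), T_len, 0)
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != T_len)
    stop("confound rows (", nrow(confounds), ") do not match timepoints (", T_len, ")")
  X <- cbind(intercept = 1, confounds)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    warning("dropping linearly dependent confound column(s): ",
            paste(dropped, collapse = ", "))
  }
  resid <- t(qr.resid(qr_x, t(ts$matrix)))
  parcel_timeseries(resid, tr = ts$tr, subject_id = ts$subject_id)
}

#' Zero-phase band-pass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass filter of
#' order 2 per pass to every parcel series. The band defaults to the standard
#' resting-state range 0.01-0.1 Hz.
#'
#' @param ts a [parcel_timeseries()].
#' @param low,high band edges in Hz; must satisfy `0 < low < high < Nyquist`
#'   where Nyquist = `1 / (2 * tr)`.
#' @param order Butterworth order per pass (default 2).
#' @return Filtered [parcel_timeseries()].
#' @export
bandpass_filter <- function(ts, low = 0.01, high = 0.1, order = 2L) {
  stopifnot(inherits(ts, "parcel_timeseries"))
  nyquist <- 1 / (2 * ts$tr)
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= nyquist)
    stop("high edge ", high, " Hz is at or above Nyquist ", format(nyquist),
         " Hz for tr = ", ts$tr, " s")
  bf <- signal::butter(order, c(low, high) / nyquist, type = "pass")
  # remove the temporal mean first: the band has no DC response and
  # demeaning avoids long filter transients at the series edges
  out <- t(apply(ts$matrix - rowMeans(ts$matrix), 1,
                 function(x) signal::filtfilt(bf, x)))
  parcel_timeseries(out, tr = ts$tr, subject_id = ts$subject_id)
}

#' Quality-control filter for a cohort
#'
#' Excludes subjects with excessive head motion (mean framewise displacement
#' strictly greater than `fd_threshold`; equality retains) and subjects with
#' missing parcel data (any all-zero or non-finite parcel row). Retained
#' subjects keep their original order.
#'
#' @param manifest cohort manifest data.frame (needs `subject_id`, `mean_fd`).
#' @param ts named list of [parcel_timeseries()] aligned with the manifest.
#' @param fd_threshold exclusion threshold in mm (default 0.5).
#' @return list with `manifest`, `ts` (filtered) and `exclusions`
#'   (data.frame `subject_id`, `reason`).
#' @export
qc_filter <- function(manifest, ts, fd_threshold = 0.5) {
  stopifnot(all(manifest$subject_id %in% names(ts)))
  reasons <- character(0); who <- character(0)
  keep <- logical(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[i]
    m <- ts[[sid]]$matrix
    if (manifest$mean_fd[i] > fd_threshold) {
      who <- c(who, sid); reasons <- c(reasons, "excessive motion")
    } else if (any(!is.finite(m)) ||
               any(apply(m, 1, function(r) all(r == 0)))) {
      who <- c(who, sid); reasons <- c(reasons, "missing parcel")
    } else keep[i] <- TRUE
  }
  list(manifest = manifest[keep, , drop = FALSE],
       ts = ts[manifest$subject_id[keep]],
       exclusions = data.frame(subject_id = who, reason = reasons,
                               stringsAsFactors = FALSE))
}
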