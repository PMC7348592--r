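# Temporal cleaning and head-motion quality control of ROI time series.

#' Construct a regional time-series object
#'
#' @param data T x N numeric matrix, one column per region.
#' @param tr_seconds repetition time (sampling interval) in seconds.
#' @param region_ids ordered region labels; default `V1..VN`.
#' @return an object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, tr_seconds,
                           region_ids = colnames(data)) {
  data <- as.matrix(data)
  if (is.null(region_ids)) region_ids <- paste0("V", seq_len(ncol(data)))
  stopifnot(nrow(data) >= 2, length(region_ids) == ncol(data))
  if (!all(is.finite(data))) stop("time series contains non-finite values")
  check_scalar(tr_seconds, "tr_seconds", 0, open_lo = TRUE)
  structure(list(data = data, tr_seconds = tr_seconds,
                 region_ids = as.character(region_ids)),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("ROI time series: %d timepoints x %d regions, TR %gs\n",
              nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' Construct a six-parameter motion trace
#'
#' @param translations T x 3 matrix (mm).
#' @param rotations T x 3 matrix; radians unless `degrees = TRUE`.
#' @param tr_seconds repetition time in seconds.
#' @param degrees set `TRUE` if rotations are supplied in degrees; they are
#'   converted to radians on construction.
#' @return an object of class `motion_trace` (framewise displacement unset
#'   until [framewise_displacement()] is called).
#' @export
motion_trace <- function(translations, rotations, tr_seconds = 2,
                         degrees = FALSE) {
  translations <- as.matrix(translations)
  rotations <- as.matrix(rotations)
  stopifnot(ncol(translations) == 3, ncol(rotations) == 3,
            nrow(translations) == nrow(rotations))
  if (degrees) rotations <- rotations * pi / 180
  structure(list(translations = translations, rotations = rotations,
                 tr_seconds = tr_seconds, fd = NULL),
            class = "motion_trace")
}

#' Linear detrending and band-pass filtering
#'
#' Removes the per-region least-squares linear trend, then suppresses
#' frequency content outside `[low_hz, high_hz]`. The default filter is an
#' ideal frequency-domain mask (FFT bins outside the band zeroed, the
#' convention of common resting-state toolchains); `method = "butterworth"`
#' applies a zero-phase forward-backward Butterworth filter instead.
#'
#' @param ts a [roi_timeseries()].
#' @param low_hz,high_hz passband edges in Hz; defaults 0.01 and 0.1, the
#'   conventional resting-state fluctuation band.
#' @param method `"fft"` (default) or `"butterworth"`.
#' @param order Butterworth order (only for `method = "butterworth"`).
#' @return a filtered `roi_timeseries` of the same shape.
#' @export
detrend_and_bandpass <- function(ts, low_hz = 0.01, high_hz = 0.1,
                                 method = c("fft", "butterworth"),
                                 order = 2) {
  stopifnot(inherits(ts, "roi_timeseries"))
  method <- match.arg(method)
  nyquist <- 1 / (2 * ts$tr_seconds)
  check_scalar(low_hz, "low_hz", 0)
  if (high_hz <= low_hz) stop("high_hz must exceed low_hz")
  if (high_hz > nyquist)
    stop(sprintf("high_hz = %g exceeds the Nyquist frequency %g Hz",
                 high_hz, nyquist))
  x <- ts$data
  n_t <- nrow(x)
  # least-squares linear detrend, all columns at once
  tt <- seq_len(n_t)
  x <- lm.fit(cbind(1, tt), x)$residuals
  if (method == "fft") {
    freqs <- (seq_len(n_t) - 1) / (n_t * ts$tr_seconds)
    freqs <- pmin(freqs, 1 / ts$tr_seconds - freqs)  # two-sided
    keep <- freqs >= low_hz & freqs <= high_hz
    xf <- stats::mvfft(x)
    xf[!keep, ] <- 0
    x <- Re(stats::mvfft(xf, inverse = TRUE)) / n_t
  } else {
    bf <- signal::butter(order, c(low_hz, high_hz) / nyquist, type = "pass")
    x <- apply(x, 2, function(col) signal::filtfilt(bf, col))
  }
  dimnames(x) <- dimnames(ts$data)
  roi_timeseries(x, ts$tr_seconds, ts$region_ids)
}

#' Regress nuisance signals out of a time series
#'
#' Each region becomes the OLS residual of its signal on an intercept plus
#' the supplied regressor columns (e.g., six motion parameters, global, WM
#' and CSF signals). Collinear regressor columns are dropped with a warning.
#'
#' @param ts a [roi_timeseries()].
#' @param regressors T x K numeric matrix (may have zero columns, in which
#'   case only the mean is removed).
#' @return the residual `roi_timeseries`.
#' @export
regress_nuisance <- function(ts, regressors) {
  stopifnot(inherits(ts, "roi_timeseries"))
  n_t <- nrow(ts$data)
  if (is.null(regressors) || NCOL(regressors) == 0 || length(regressors) == 0) {
    design <- matrix(1, n_t, 1)
  } else {
    regressors <- as.matrix(regressors)
    stopifnot(nrow(regressors) == n_t, ncol(regressors) < n_t)
    design <- cbind(Intercept = 1, regressors)
    qrd <- qr(design)
    if (qrd$rank < ncol(design)) {
      keep <- qrd$pivot[seq_len(qrd$rank)]
      warning(sprintf("dropping %d collinear nuisance column(s)",
                      ncol(design) - qrd$rank))
      design <- design[, sort(keep), drop = FALSE]
    }
  }
  res <- lm.fit(design, ts$data)$residuals
  dimnames(res) <- dimnames(ts$data)
  roi_timeseries(res, ts$tr_seconds, ts$region_ids)
}

#' Framewise displacement (Power convention)
#'
#' `fd[t] = sum |delta translation| + head_radius_mm * sum |delta rotation|`
#' between volume `t` and `t - 1`, with rotations in radians projected onto
#' a sphere of `head_radius_mm`; `fd[1] = 0`.
#'
#' @param motion a [motion_trace()].
#' @param head_radius_mm sphere radius for rotation projection (default 50).
#' @return the `motion_trace` with its `fd` field populated.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  stopifnot(inherits(motion, "motion_trace"))
  dt <- apply(motion$translations, 2, function(p) c(0, diff(p)))
  dr <- apply(motion$rotations, 2, function(p) c(0, diff(p)))
  if (nrow(motion$translations) == 1) { dt <- matrix(0, 1, 3); dr <- dt }
  motion$fd <- rowSums(abs(dt)) + head_radius_mm * rowSums(abs(dr))
  motion$fd[1] <- 0
  motion
}

#' Scrub high-motion volumes
#'
#' Removes every volume whose framewise displacement exceeds `fd_threshold`
#' together with its `n_back` preceding and `n_forward` following volumes
#' (windows clipped at the sequence ends), and reports whether the subject
#' falls below the minimum-remaining-data rule (excluded when the retained
#' data span is `<= min_remaining_seconds`).
#'
#' @param ts a [roi_timeseries()].
#' @param motion a [motion_trace()] with `fd` computed (it is computed here
#'   if absent).
#' @param fd_threshold FD censoring threshold in mm (default 0.5; strict
#'   inequality, "above" the threshold).
#' @param n_back,n_forward window sizes (defaults 1 back, 2 forward).
#' @param min_remaining_seconds exclusion boundary in seconds (default 300,
#'   i.e. five minutes; boundary itself excluded).
#' @return list with elements `timeseries` (scrubbed) and `report`
#'   (class `scrub_report`: `keep_mask`, `n_removed`, `remaining_seconds`,
#'   `excluded`).
#' @export
scrub <- function(ts, motion, fd_threshold = 0.5, n_back = 1, n_forward = 2,
                  min_remaining_seconds = 300) {
  stopifnot(inherits(ts, "roi_timeseries"), inherits(motion, "motion_trace"))
  if (is.null(motion$fd)) motion <- framewise_displacement(motion)
  n_t <- nrow(ts$data)
  stopifnot(length(motion$fd) == n_t)
  bad <- which(motion$fd > fd_threshold)
  drop <- unique(unlist(lapply(bad, function(t)
    max(1L, t - n_back):min(n_t, t + n_forward))))
  keep_mask <- !(seq_len(n_t) %in% drop)
  remaining <- sum(keep_mask) * ts$tr_seconds
  report <- structure(list(
    keep_mask = keep_mask, n_removed = sum(!keep_mask),
    remaining_seconds = remaining,
    excluded = remaining <= min_remaining_seconds), class = "scrub_report")
  out <- ts
  out$data <- ts$data[keep_mask, , drop = FALSE]
  list(timeseries = out, report = report)
}

#' @export
print.scrub_report <- function(x, ...) {
  cat(sprintf("Scrub report: %d volume(s) removed, %.0f s remaining%s\n",
              x$n_removed, x$remaining_seconds,
              if (x$excluded) " [EXCLUDED: insufficient data]" else ""))
  invisible(x)
}

#' Gross head-motion exclusion rule
#'
#' Flags a subject whose maximum absolute translation reaches
#' `trans_limit_mm` on any axis or whose maximum absolute rotation reaches
#' `rot_limit_deg` on any axis (boundaries inclusive).
#'
#' @param motion a [motion_trace()] (rotations in radians).
#' @param trans_limit_mm translation limit in mm (default 3).
#' @param rot_limit_deg rotation limit in degrees (default 3).
#' @return logical: `TRUE` if the subject should be excluded.
#' @export
motion_exclusion <- function(motion, trans_limit_mm = 3, rot_limit_deg = 3) {
  stopifnot(inherits(motion, "motion_trace"))
  max(abs(motion$translations)) >= trans_limit_mm ||
    max(abs(motion$rotations)) * 180 / pi >= rot_limit_deg
}
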