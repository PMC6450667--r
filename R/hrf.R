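#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma HRF (response peak at ~5-6 s governed by a
#' gamma with shape 6, undershoot governed by a gamma with shape 16,
#' peak-to-undershoot ratio 6), sampled at the repetition time. The kernel
#' is scaled to unit peak so regressor amplitudes are interpretable on the
#' scale of the event values.
#'
#' @param tr_seconds Sampling interval (TR) in seconds.
#' @param duration_s Length of the sampled kernel in seconds (default 32).
#' @return Numeric vector of kernel values at times 0, TR, 2*TR, ...
#' @export
canonical_hrf <- function(tr_seconds, duration_s = 32) {
  stopifnot(tr_seconds > 0)
  t <- seq(0, duration_s, by = tr_seconds)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Build an HRF-convolved regressor from events on a scan grid
#'
#' Places event values as boxcars on the TR grid of a single run (a scan
#' is covered when its acquisition time falls within \[onset, onset +
#' duration)), convolves with the canonical HRF, and truncates to the run
#' length. All non-event time points are zero before convolution.
#'
#' @param onsets_s Event onsets in seconds, relative to run start.
#' @param durations_s Event durations in seconds (scalar or per event).
#' @param values Amplitude placed on each event (scalar or per event);
#'   e.g. 1 for a condition regressor, a mean-centered score for a
#'   parametric modulator.
#' @param n_scans Number of scans in the run.
#' @param tr_seconds TR in seconds.
#' @param convolve If `FALSE`, return the raw (pre-convolution) boxcar.
#' @return Numeric vector of length `n_scans`.
#' @export
event_regressor <- function(onsets_s, durations_s, values = 1,
                            n_scans, tr_seconds, convolve = TRUE) {
  n_ev <- length(onsets_s)
  durations_s <- rep_len(durations_s, n_ev)
  values <- rep_len(values, n_ev)
  times <- (seq_len(n_scans) - 1L) * tr_seconds
  x <- numeric(n_scans)
  for (i in seq_len(n_ev)) {
    idx <- times >= onsets_s[i] & times < onsets_s[i] + durations_s[i]
    x[idx] <- x[idx] + values[i]
  }
  if (!convolve) return(x)
  h <- canonical_hrf(tr_seconds)
  stats::convolve(c(x, numeric(length(h))), rev(h), type = "open")[seq_len(n_scans)]
}
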