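# Connectivity module: phase lag index per pair and per epoch, averaged into
# one symmetric matrix per participant x condition x band.

#' Phase lag index of two phase series
#'
#' `PLI = | mean_k sign(dphi_k) |` where `dphi_k` is the phase difference
#' wrapped to (-pi, pi], with the three-case sign convention: +1 for positive
#' differences, -1 for negative, 0 for exactly zero. Values lie in \[0, 1\];
#' 1 means a perfectly consistent nonzero phase lag, 0 means no consistent
#' lag (including identical signals, whose zero differences contribute 0).
#' The index is symmetric in its arguments: it measures lag consistency, not
#' direction. Exact zeros are honoured literally (no epsilon band); exact
#' antiphase wraps to +pi and counts as positive.
#'
#' @param phase_i,phase_j Numeric vectors of equal length: instantaneous
#'   phases in radians.
#' @return A single number in \[0, 1\].
#' @export
#' @examples
#' t <- (0:2499) / 500
#' pli(2 * pi * 10 * t, 2 * pi * 10 * t - pi / 2)
pli <- function(phase_i, phase_j) {
  if (length(phase_i) != length(phase_j)) {
    stop_arg("phase series differ in length (%d vs %d)",
             length(phase_i), length(phase_j))
  }
  if (length(phase_i) == 0L) stop_arg("phase series are empty")
  if (anyNA(phase_i) || anyNA(phase_j)) stop_arg("phase series contain NA")
  d <- wrap_phase(phase_i - phase_j)
  abs(mean(sign(d)))
}

#' Epoch-averaged PLI connectivity matrix
#'
#' Computes the instantaneous phase of every ROI in every epoch, the PLI of
#' every unordered ROI pair within each epoch, and the arithmetic mean across
#' epochs. The result is one symmetric, zero-diagonal matrix with entries in
#' \[0, 1\] per participant x condition x band.
#'
#' @param epochs An `epoch_set`, normally band-passed (see [bandpass()]).
#' @param trim_s Seconds trimmed from each end of every epoch before phase
#'   estimation (default 0).
#' @return A `connectivity_matrix`: list with `values` (n_roi x n_roi),
#'   `labels`, `participant_id`, `condition`, `band`, `n_epochs_averaged`.
#' @export
#' @examples
#' spec <- coupling_spec("alpha", tibble::tibble(
#'   roi_i = 1, roi_j = 2, lag_radians = pi / 3, concentration = Inf
#' ), background_noise_sd = 0)
#' rec <- simulate_recording("s1", "DR", spec, duration_s = 60,
#'                           labels = c("a", "b", "c"), seed = 1)
#' ep <- bandpass(make_epochs(rec), "alpha")
#' pli_matrix(ep)$values[1, 2]
pli_matrix <- function(epochs, trim_s = 0) {
  if (!inherits(epochs, "epoch_set")) stop_arg("`epochs` must be an epoch_set")
  if (length(epochs$epochs) == 0L) stop_arg("epoch set is empty")
  n_roi <- nrow(epochs$epochs[[1]])
  acc <- matrix(0, n_roi, n_roi)
  for (ep in epochs$epochs) {
    ph <- instantaneous_phase(ep, fs_hz = epochs$fs_hz, trim_s = trim_s)
    acc <- acc + .pli_matrix_epoch(ph)
  }
  values <- acc / length(epochs$epochs)
  dimnames(values) <- list(epochs$labels, epochs$labels)
  structure(
    list(values = values, labels = epochs$labels,
         participant_id = epochs$participant_id, condition = epochs$condition,
         band = epochs$band, n_epochs_averaged = length(epochs$epochs)),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s / %s / %s: %d x %d, mean PLI %.3f over %d epoch(s)\n",
              x$participant_id, x$condition, x$band %||% "broadband",
              nrow(x$values), ncol(x$values),
              mean(x$values[upper.tri(x$values)]), x$n_epochs_averaged))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
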