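# Spectral module: canonical frequency bands, zero-phase FIR band-pass,
# fixed-length epoching with an epoch-count QC gate, Hilbert phase.

#' Canonical frequency bands
#'
#' The five-band decomposition used throughout the pipeline: delta 2-4 Hz,
#' theta 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz, gamma 30-60 Hz.
#'
#' @return A tibble with columns `name`, `lo_hz`, `hi_hz`.
#' @export
#' @examples
#' band_table()
band_table <- function() {
  tibble(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    lo_hz = c(2, 4, 8, 13, 30),
    hi_hz = c(4, 8, 13, 30, 60)
  )
}

# Accept a band name or a one-row data frame with name/lo_hz/hi_hz.
as_band <- function(band) {
  if (is.character(band) && length(band) == 1L) {
    tab <- band_table()
    if (!band %in% tab$name) {
      stop_arg("unknown band '%s'; known: %s", band,
               paste(tab$name, collapse = ", "))
    }
    return(as.list(tab[tab$name == band, ]))
  }
  if (is.data.frame(band) && nrow(band) == 1L) band <- as.list(band)
  if (is.list(band) && all(c("name", "lo_hz", "hi_hz") %in% names(band))) {
    if (!(band$lo_hz > 0 && band$lo_hz < band$hi_hz)) {
      stop_arg("band must satisfy 0 < lo_hz < hi_hz")
    }
    return(band[c("name", "lo_hz", "hi_hz")])
  }
  stop_arg("`band` must be a band name or a list/one-row data frame with name, lo_hz, hi_hz")
}

# Zero-phase FIR band-pass kernel. Linear-phase type-I FIR (odd length, even
# order) designed with a Hamming window; transition width 15% of the lower
# band edge, order capped so the kernel fits the signal.
fir_bandpass_kernel <- function(band, fs_hz, n_samples) {
  if (fs_hz <= 2 * band$hi_hz) {
    stop_arg("band '%s' upper edge %g Hz is at or above Nyquist (fs = %g Hz)",
             band$name, band$hi_hz, fs_hz)
  }
  tw <- 0.15 * band$lo_hz
  order <- ceiling(3.3 * fs_hz / tw)
  order <- order + order %% 2L              # even order, odd length
  cap <- n_samples - 1L
  cap <- cap - cap %% 2L
  if (cap < 8L) stop_arg("signal too short to filter (%d samples)", n_samples)
  order <- min(order, cap)
  as.numeric(signal::fir1(order, c(band$lo_hz, band$hi_hz) / (fs_hz / 2),
                          type = "pass"))
}

# Apply a linear-phase FIR kernel with exact group-delay compensation and
# reflection padding; x is n_roi x n_samples. Zero phase because the kernel
# is symmetric and the delay (order/2 samples) is removed exactly.
filter_zero_phase <- function(x, kernel) {
  n <- ncol(x)
  half <- (length(kernel) - 1L) %/% 2L
  stopifnot(half < n)
  idx_l <- seq.int(half + 1L, 2L)           # reflect without repeating edge
  idx_r <- seq.int(n - 1L, n - half)
  xp <- cbind(x[, idx_l, drop = FALSE], x, x[, idx_r, drop = FALSE])
  np <- ncol(xp)
  nfft <- stats::nextn(np + length(kernel) - 1L, 2)
  K <- stats::fft(c(kernel, rep(0, nfft - length(kernel))))
  X <- stats::mvfft(t(cbind(xp, matrix(0, nrow(x), nfft - np))))
  y <- Re(stats::mvfft(X * K, inverse = TRUE)) / nfft
  # convolution delay is `half` + padding offset `half`
  t(y)[, seq.int(2L * half + 1L, 2L * half + n), drop = FALSE]
}

#' Band-pass filter a recording, epoch set, or signal matrix
#'
#' Zero-phase band-pass filtering into one of the canonical bands (or any
#' custom band) using a linear-phase Hamming-window FIR filter with exact
#' group-delay compensation and reflection padding. Passband gain is ~1 and
#' no phase distortion is introduced, so downstream instantaneous phases are
#' unbiased.
#'
#' @param x A `roi_recording`, an `epoch_set`, or a numeric matrix
#'   (channels x samples).
#' @param band A band name (see [band_table()]) or a list/one-row data frame
#'   with `name`, `lo_hz`, `hi_hz`.
#' @param fs_hz Sampling rate; required only for the matrix method.
#' @return The same shape as `x`, filtered. Epoch sets record the band.
#' @export
#' @examples
#' fs <- 500
#' x <- matrix(sin(2 * pi * 10 * (0:4999) / fs), nrow = 1)
#' y <- bandpass(x, "alpha", fs_hz = fs)
bandpass <- function(x, band, fs_hz = NULL) UseMethod("bandpass")

#' @export
bandpass.matrix <- function(x, band, fs_hz = NULL) {
  if (is.null(fs_hz)) stop_arg("`fs_hz` is required when filtering a matrix")
  if (anyNA(x)) stop_arg("input contains NA")
  band <- as_band(band)
  kernel <- fir_bandpass_kernel(band, fs_hz, ncol(x))
  filter_zero_phase(x, kernel)
}

#' @export
bandpass.roi_recording <- function(x, band, fs_hz = NULL) {
  x$data <- bandpass(x$data, band, fs_hz = x$fs_hz)
  x$band <- as_band(band)$name
  x
}

#' @export
bandpass.epoch_set <- function(x, band, fs_hz = NULL) {
  band <- as_band(band)
  kernel <- fir_bandpass_kernel(band, x$fs_hz, ncol(x$epochs[[1]]))
  x$epochs <- lapply(x$epochs, filter_zero_phase, kernel = kernel)
  x$band <- band$name
  x
}

#' Cut a recording into fixed-length epochs with a QC gate
#'
#' Splits the recording into consecutive non-overlapping epochs of
#' `epoch_len_s` seconds, dropping any trailing remainder. If fewer than
#' `min_epochs` epochs result (default 10, i.e. at least 50 s of usable
#' signal at 5-s epochs), a QC error of class `plinet_qc_error` naming the
#' participant and condition is raised.
#'
#' @param x A `roi_recording`.
#' @param epoch_len_s Epoch length in seconds (default 5).
#' @param min_epochs Minimum epochs required to pass QC (default 10).
#' @param n_keep Optional cap: keep only the first `n_keep` epochs (used to
#'   emulate post-artifact-rejection epoch counts).
#' @return An `epoch_set`: list with `epochs` (list of n_roi x n matrices),
#'   `fs_hz`, `labels`, `participant_id`, `condition`, `epoch_len_s`.
#' @export
#' @examples
#' spec <- coupling_spec("alpha")
#' rec <- simulate_recording("s1", "DR", spec, duration_s = 60, seed = 1)
#' length(make_epochs(rec)$epochs)
make_epochs <- function(x, epoch_len_s = 5, min_epochs = 10, n_keep = NULL) {
  stopifnot(inherits(x, "roi_recording"))
  check_scalar_number(epoch_len_s, "epoch_len_s", lo = 1e-9)
  n_ep_samp <- round(epoch_len_s * x$fs_hz)
  n_epochs <- floor(ncol(x$data) / n_ep_samp)
  if (!is.null(n_keep)) n_epochs <- min(n_epochs, n_keep)
  if (n_epochs < min_epochs) {
    rlang::abort(
      sprintf("QC failure for %s/%s: %d epoch(s) of %g s available, %d required",
              x$participant_id, x$condition, n_epochs, epoch_len_s, min_epochs),
      class = "plinet_qc_error",
      participant_id = x$participant_id, condition = x$condition,
      n_epochs = n_epochs, min_epochs = min_epochs
    )
  }
  epochs <- lapply(seq_len(n_epochs), function(e) {
    x$data[, ((e - 1L) * n_ep_samp + 1L):(e * n_ep_samp), drop = FALSE]
  })
  structure(
    list(epochs = epochs, fs_hz = x$fs_hz, labels = x$labels,
         participant_id = x$participant_id, condition = x$condition,
         epoch_len_s = epoch_len_s, band = x$band),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %s / %s: %d epochs of %g s, %d ROIs @ %g Hz%s\n",
              x$participant_id, x$condition, length(x$epochs), x$epoch_len_s,
              nrow(x$epochs[[1]]), x$fs_hz,
              if (!is.null(x$band)) paste0(", band ", x$band) else ""))
  invisible(x)
}

# Analytic signal by the FFT method: null the negative frequencies, double
# the positive ones, keep DC (and Nyquist for even n) as-is. x is a matrix,
# channels x samples.
analytic_signal <- function(x) {
  n <- ncol(x)
  h <- rep(0, n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  X <- stats::mvfft(t(x))
  t(stats::mvfft(X * h, inverse = TRUE)) / n
}

#' Instantaneous phase via the Hilbert transform
#'
#' Per-channel angle of the analytic signal. Invariant to positive amplitude
#' scaling; no edge trimming by default, with an optional `trim_s` that drops
#' the stated margin at both ends (Hilbert edge effects decay within a few
#' cycles of the band's lower edge).
#'
#' @param epoch Numeric matrix, channels x samples (one epoch), or an
#'   `epoch_set` (each epoch transformed).
#' @param fs_hz Sampling rate, needed only when `trim_s > 0`.
#' @param trim_s Seconds to drop at each end (default 0).
#' @return A matrix of phases in (-pi, pi] (or a list of them for an
#'   `epoch_set`).
#' @export
#' @examples
#' fs <- 500; t <- (0:2499) / fs
#' ph <- instantaneous_phase(matrix(cos(2 * pi * 10 * t), nrow = 1))
instantaneous_phase <- function(epoch, fs_hz = NULL, trim_s = 0) {
  if (inherits(epoch, "epoch_set")) {
    epoch$phases <- lapply(epoch$epochs, instantaneous_phase,
                           fs_hz = epoch$fs_hz, trim_s = trim_s)
    return(epoch)
  }
  if (!is.matrix(epoch) || !is.numeric(epoch)) {
    stop_arg("`epoch` must be a numeric matrix (channels x samples)")
  }
  if (anyNA(epoch)) stop_arg("`epoch` contains NA")
  ph <- Arg(analytic_signal(epoch))
  ph <- wrap_phase(ph)
  if (trim_s > 0) {
    if (is.null(fs_hz)) stop_arg("`fs_hz` is required when trim_s > 0")
    k <- round(trim_s * fs_hz)
    if (2 * k >= ncol(ph)) stop_arg("trim_s leaves no samples")
    ph <- ph[, (k + 1L):(ncol(ph) - k), drop = FALSE]
  }
  ph
}

#' Decimate a recording with anti-alias filtering
#'
#' Integer-factor downsampling after a zero-phase FIR low-pass at 80% of the
#' target Nyquist. Synthetic recordings are generated at the working rate
#' (500 Hz) already, so this is only needed for externally supplied data.
#'
#' @param x A `roi_recording`.
#' @param factor Integer decimation factor (>= 1; 1 is a no-op).
#' @return A `roi_recording` at `fs_hz / factor`.
#' @export
decimate_recording <- function(x, factor) {
  stopifnot(inherits(x, "roi_recording"))
  check_scalar_number(factor, "factor", lo = 1)
  factor <- as.integer(factor)
  if (factor == 1L) return(x)
  cutoff <- 0.8 * (x$fs_hz / factor / 2)
  order <- 120L
  kernel <- as.numeric(signal::fir1(order, cutoff / (x$fs_hz / 2), type = "low"))
  y <- filter_zero_phase(x$data, kernel)
  x$data <- y[, seq(1L, ncol(y), by = factor), drop = FALSE]
  x$fs_hz <- x$fs_hz / factor
  x
}
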