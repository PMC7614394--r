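#' Band-pass filter raw A-lines
#'
#' Butterworth band-pass of the stated order applied along the sample axis
#' of each A-line, using zero-phase (forward-backward) application so echo
#' peak times — and hence depth estimates — are not biased by group delay.
#'
#' @param rf Numeric matrix (samples x frames) or vector, or an
#'   `rf_sequence`.
#' @param low,high Band edges in Hz. Defaults 10 and 40 MHz.
#' @param order Butterworth order (per pass). Default 4.
#' @param sample_rate Sampling rate in Hz; taken from the sequence config
#'   when `rf` is an `rf_sequence`.
#' @return Filtered data, same shape as the input (an `rf_sequence` input
#'   is returned with its `rf` replaced).
#' @export
bandpass_filter <- function(rf, low = 10e6, high = 40e6, order = 4,
                            sample_rate = NULL) {
  if (inherits(rf, "rf_sequence")) {
    rf$rf <- bandpass_filter(rf$rf, low, high, order, rf$config$sample_rate)
    return(rf)
  }
  if (is.null(sample_rate)) stop("sample_rate required for matrix input")
  nyq <- sample_rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("configuration error: band edges must satisfy 0 < low < high < ",
         "Nyquist (", format(nyq, scientific = TRUE), " Hz)")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  if (is.matrix(rf)) {
    apply(rf, 2, function(col) filtfilt_padded(bf, col))
  } else {
    filtfilt_padded(bf, rf)
  }
}

# Zero-phase filtering with odd-reflection end padding so start-up
# transients decay inside the padding, not the record.
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  pad <- min(n - 1L, 20L * (length(bf$a) - 1L))
  if (pad < 1) return(signal::filtfilt(bf, x))
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y[(pad + 1):(pad + n)]
}

#' Magnitude response of the zero-phase Butterworth band-pass
#'
#' Closed-form evaluation of the digital filter's transfer polynomials on
#' the unit circle, squared to account for forward-backward application.
#' Used to verify passband/stopband gains independently of the time-domain
#' filtering path.
#'
#' @param freq Frequencies in Hz (vectorised).
#' @inheritParams bandpass_filter
#' @return Magnitude gain(s) of the zero-phase filter at `freq`.
#' @export
butterworth_gain <- function(freq, low = 10e6, high = 40e6, order = 4,
                             sample_rate = 1e8) {
  bf <- signal::butter(order, c(low, high) / (sample_rate / 2), type = "pass")
  z <- exp(-1i * 2 * pi * freq / sample_rate)
  gain_once <- vapply(z, function(zz) {
    num <- sum(bf$b * zz^(seq_along(bf$b) - 1))
    den <- sum(bf$a * zz^(seq_along(bf$a) - 1))
    Mod(num / den)
  }, numeric(1))
  gain_once^2
}

#' Signal envelope via the analytic signal
#'
#' Magnitude of the analytic signal of each A-line, computed with the
#' FFT-based Hilbert construction: zero the negative-frequency half of the
#' spectrum, double the positive half, inverse-transform, take the
#' modulus.
#'
#' @param x Numeric vector or matrix (samples x frames).
#' @return Nonnegative envelope, same shape as `x`.
#' @export
envelope <- function(x) {
  if (is.matrix(x)) return(apply(x, 2, envelope))
  stopifnot(all(is.finite(x)))
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

#' Log compression for display and segmentation
#'
#' `20 log10(envelope / max(envelope))`, floored at `-dynamic_range`;
#' normalisation is global over the whole acquisition so brightness
#' changes over time are preserved.
#'
#' @param env Nonnegative envelope matrix or vector.
#' @param dynamic_range Displayed dynamic range in dB (> 0). Default 40.
#' @return Image values in dB, all <= 0.
#' @export
log_compress <- function(env, dynamic_range = 40) {
  stopifnot(dynamic_range > 0, all(env >= 0))
  m <- max(env)
  if (m == 0) {
    warning("all-zero envelope: image clamped to the dynamic-range floor")
    return(env - dynamic_range)
  }
  pmax(20 * log10(pmax(env, .Machine$double.xmin) / m), -dynamic_range)
}

#' Convert sample index to depth and back
#'
#' Round-trip time-of-flight convention: `depth = c * index / (2 fs)`.
#' Sample indices are zero-based (sample `k` records the echo arriving
#' `k/fs` seconds after excitation). `depth_to_sample` rounds to the
#' nearest sample; index -> mm -> index is the identity.
#'
#' @param sample_index Zero-based sample index (vectorised, >= 0).
#' @param config An [acquisition_config()] supplying `speed_of_sound` and
#'   `sample_rate`.
#' @return `sample_to_depth`: depth in mm; `depth_to_sample`: integer
#'   sample index.
#' @export
sample_to_depth <- function(sample_index, config) {
  if (any(sample_index < 0)) stop("sample index must be >= 0")
  config$speed_of_sound * sample_index / (2 * config$sample_rate) * 1000
}

#' @rdname sample_to_depth
#' @param depth_mm Depth in mm (vectorised, >= 0).
#' @export
depth_to_sample <- function(depth_mm, config) {
  if (any(depth_mm < 0)) stop("depth must be >= 0")
  as.integer(round(2 * (depth_mm / 1000) * config$sample_rate /
                     config$speed_of_sound))
}

#' Form the M-mode image from a raw A-line sequence
#'
#' Full display chain: Butterworth band-pass (zero-phase), Hilbert
#' envelope, global log compression, A-line concatenation, and physical
#' depth/time axes.
#'
#' @param seq An `rf_sequence` from [simulate_sequence()] (or any list
#'   with `rf`, `frame_times`, `config`).
#' @param low,high,order Band-pass parameters, see [bandpass_filter()].
#' @param dynamic_range Dynamic range in dB for [log_compress()].
#' @return An object of class `mmode_image`: `image` (dB, depth samples x
#'   frames), `depth_axis` (mm per row), `time_axis` (s per column),
#'   `dynamic_range`, and `provenance` recording every processing
#'   parameter.
#' @export
process_sequence <- function(seq, low = 10e6, high = 40e6, order = 4,
                             dynamic_range = 40) {
  filtered <- bandpass_filter(seq$rf, low, high, order,
                              seq$config$sample_rate)
  env <- envelope(filtered)
  img <- log_compress(env, dynamic_range)
  structure(list(
    image = img,
    depth_axis = sample_to_depth(seq_len(nrow(img)) - 1L, seq$config),
    time_axis = seq$frame_times,
    dynamic_range = dynamic_range,
    config = seq$config,
    provenance = list(filter = "butterworth", low_hz = low, high_hz = high,
                      order = order, zero_phase = TRUE,
                      envelope = "hilbert", log_ref = "global_max",
                      dynamic_range_db = dynamic_range)
  ), class = "mmode_image")
}
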