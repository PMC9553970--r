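#' Real-time signal processing chain
#'
#' Causal (single-pass) implementations of the on-line processing used in the
#' closed loop: EMG envelope extraction (high-pass, 20 ms bin averaging,
#' rectification), normalization to a maximum voluntary contraction (MVC)
#' peak, 4th-order Butterworth low-pass filtering of fingertip force, and the
#' threshold-crossing constant-velocity aperture controller. All filters are
#' causal with zero initial state; the system they model ran in real time, so
#' zero-phase (filtfilt) filtering is deliberately not used.
#'
#' @name signal_chain
NULL

#' EMG envelope chain configuration
#'
#' @param raw_rate Raw EMG sampling rate, Hz.
#' @param highpass_cutoff High-pass corner, Hz.
#' @param highpass_order Butterworth order of the high-pass stage.
#' @param bin_width Averaging bin width, s. `raw_rate * bin_width` must be an
#'   integer number of samples; the output rate is `1 / bin_width`.
#' @param rectify_after_average If `TRUE` (default) the bin means are computed
#'   on the signed signal and then rectified; if `FALSE`, the raw signal is
#'   rectified first and the bin means taken of the rectified signal. See the
#'   methods vignette for why the two orders behave very differently on
#'   zero-mean EMG.
#' @return A list of class `emg_chain_config`.
#' @export
emg_chain_config <- function(raw_rate = 2000, highpass_cutoff = 10,
                             highpass_order = 2, bin_width = 0.020,
                             rectify_after_average = TRUE) {
  bin_n <- raw_rate * bin_width
  if (abs(bin_n - round(bin_n)) > 1e-9) {
    stop("raw_rate * bin_width must be an integer number of samples")
  }
  structure(list(raw_rate = raw_rate, highpass_cutoff = highpass_cutoff,
                 highpass_order = highpass_order, bin_width = bin_width,
                 output_rate = 1 / bin_width,
                 rectify_after_average = isTRUE(rectify_after_average)),
            class = "emg_chain_config")
}

#' Extract a 50 Hz EMG envelope from raw EMG
#'
#' High-pass filters the raw signal (causal Butterworth), averages it over
#' non-overlapping bins (20 ms by default, i.e. exactly one output sample per
#' bin at 50 Hz), and rectifies. Output length is
#' `floor(length(raw) / (raw_rate * bin_width))`.
#'
#' @param raw Numeric vector, raw EMG at `cfg$raw_rate`.
#' @param cfg An [emg_chain_config()].
#' @return Numeric envelope at `cfg$output_rate`.
#' @export
process_emg <- function(raw, cfg = emg_chain_config()) {
  stopifnot(inherits(cfg, "emg_chain_config"))
  bin_n <- round(cfg$raw_rate * cfg$bin_width)
  if (length(raw) < bin_n) {
    stop("raw EMG must contain at least one full bin (",
         bin_n, " samples)")
  }
  hp <- signal::butter(cfg$highpass_order,
                       cfg$highpass_cutoff / (cfg$raw_rate / 2),
                       type = "high")
  x <- as.numeric(signal::filter(hp, raw))
  n_bins <- floor(length(x) / bin_n)
  x <- x[seq_len(n_bins * bin_n)]
  if (cfg$rectify_after_average) {
    env <- abs(colMeans(matrix(x, nrow = bin_n)))
  } else {
    env <- colMeans(matrix(abs(x), nrow = bin_n))
  }
  env
}

#' Normalize an EMG envelope to the MVC peak
#'
#' Values are not clipped: envelopes exceeding the MVC peak are allowed and
#' reported via a message.
#'
#' @param envelope Numeric envelope.
#' @param mvc_peak Peak envelope value recorded during a maximum voluntary
#'   contraction, same units as `envelope`; must be > 0.
#' @param quiet Suppress the above-MVC message.
#' @return `envelope / mvc_peak` (fraction of MVC).
#' @export
normalize_to_mvc <- function(envelope, mvc_peak, quiet = FALSE) {
  if (!is.numeric(mvc_peak) || length(mvc_peak) != 1 || is.na(mvc_peak) ||
      mvc_peak <= 0) {
    stop("mvc_peak must be a single positive number")
  }
  out <- envelope / mvc_peak
  if (!quiet && any(out > 1, na.rm = TRUE)) {
    message(sum(out > 1, na.rm = TRUE),
            " envelope sample(s) exceed the MVC peak (not clipped)")
  }
  out
}

#' Force low-pass filter configuration
#'
#' @param order Butterworth order.
#' @param cutoff Corner frequency, Hz; must be below Nyquist.
#' @param sample_rate Force sampling rate, Hz.
#' @return A list of class `force_filter_config`.
#' @export
force_filter_config <- function(order = 4, cutoff = 4, sample_rate = 50) {
  if (cutoff >= sample_rate / 2) {
    stop("cutoff must be below the Nyquist frequency (",
         sample_rate / 2, " Hz)")
  }
  structure(list(order = order, cutoff = cutoff, sample_rate = sample_rate),
            class = "force_filter_config")
}

#' Low-pass filter a grasp-force series
#'
#' Causal IIR Butterworth (bilinear transform, zero initial state) with unity
#' DC gain, matching the on-line sensor filtering: 4th order, 4 Hz cutoff at
#' a 50 Hz update rate by default.
#'
#' @param force Numeric force series at `cfg$sample_rate`.
#' @param cfg A [force_filter_config()].
#' @return Filtered numeric series, same length.
#' @export
lowpass_force <- function(force, cfg = force_filter_config()) {
  stopifnot(inherits(cfg, "force_filter_config"))
  if (length(force) == 0) stop("force series is empty")
  bf <- signal::butter(cfg$order, cfg$cutoff / (cfg$sample_rate / 2),
                       type = "low")
  as.numeric(signal::filter(bf, force))
}

#' Analytic magnitude response of the digital Butterworth low-pass
#'
#' Closed-form gain of the causal bilinear-transform Butterworth at frequency
#' `f`, including the frequency warping the bilinear transform introduces
#' (the design prewarps the cutoff, so the gain is exactly 1/sqrt(2) at
#' `cutoff` and is pushed below the analog value toward Nyquist).
#'
#' @param f Frequency, Hz (vectorized).
#' @param cfg A [force_filter_config()].
#' @return Magnitude gain(s) in (0, 1].
#' @export
butterworth_gain <- function(f, cfg = force_filter_config()) {
  w <- tan(pi * f / cfg$sample_rate) / tan(pi * cfg$cutoff / cfg$sample_rate)
  1 / sqrt(1 + w^(2 * cfg$order))
}

#' Threshold-crossing constant-velocity aperture controller
#'
#' Per-sample Euler integration of the control law used for myoelectric
#' control: while the normalized EMG envelope is at or above threshold the
#' hand closes at `close_velocity` (15 deg/s); otherwise it opens at
#' `open_velocity` (30 deg/s). Aperture is clamped to `aperture_range`.
#'
#' @param envelope Envelope as MVC fractions, on the 50 Hz grid.
#' @param threshold MVC-fraction threshold in (0, 1).
#' @param close_velocity Closing speed, deg/s.
#' @param open_velocity Opening speed, deg/s.
#' @param aperture_range `c(fully_open_deg, fully_closed_deg)`.
#' @param start_aperture Initial aperture, deg; must lie in range.
#' @param dt Sample interval, s.
#' @return Aperture series in degrees, same length as `envelope`.
#' @export
threshold_velocity_controller <- function(envelope, threshold,
                                          close_velocity = 15,
                                          open_velocity = 30,
                                          aperture_range = c(90, 0),
                                          start_aperture = aperture_range[1],
                                          dt = 0.02) {
  stopifnot(close_velocity > 0, open_velocity > 0)
  lo <- min(aperture_range); hi <- max(aperture_range)
  if (start_aperture < lo || start_aperture > hi) {
    stop("start_aperture outside aperture_range")
  }
  n <- length(envelope)
  ap <- numeric(n)
  a <- start_aperture
  for (i in seq_len(n)) {
    da <- if (envelope[i] >= threshold) -close_velocity * dt else
      open_velocity * dt
    a <- min(hi, max(lo, a + da))
    ap[i] <- a
  }
  ap
}
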