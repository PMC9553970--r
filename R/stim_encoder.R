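#' Force-to-stimulation-amplitude encoding
#'
#' The closed loop maps the (filtered) grasp force read from the prosthetic
#' fingertip sensors into a commanded stimulation amplitude at a 50 Hz update
#' rate, using either a linear scheme (force normalized to its calibration
#' range and mapped affinely onto the perceptual amplitude range) or an
#' exponential scheme (amplitude grows as `A_min * exp(omega * F)` with `F`
#' in raw sensor units, capped at the hardware ceiling). Stimulation-train
#' parameters are validated against the stimulator's operating ranges.
#'
#' @name stim_encoder
NULL

HARDWARE_MAX_MA <- 6.0 # ganged-channel ceiling of the stimulator, mA

#' Encoding configuration
#'
#' @param scheme `"linear"` or `"exponential"`.
#' @param F_min,F_max Sensor calibration limits, N (`F_min < F_max`).
#' @param A_min,A_max Perceptual amplitude limits, mA
#'   (`0 <= A_min < A_max <= hardware_max`).
#' @param omega Exponential scaling factor, 1/(sensor unit). The empirically
#'   useful window is 0.005-0.025; values outside it trigger a warning.
#' @param contact_threshold Force (N) below which no stimulation is delivered
#'   (default `F_min`): the loop commands zero amplitude rather than holding
#'   `A_min` during contact-free periods, so a stimulation onset exists.
#' @param exp_threshold Sensor-unit threshold of the exponential scheme
#'   (amplitude is 0 for `F <= exp_threshold`); default 1 sensor unit.
#' @param sensor_scale Sensor units per newton (default 20): converts the
#'   simulator's newton-scale forces to the raw sensor counts the exponential
#'   scheme is parameterized in.
#' @param hardware_max Hardware amplitude ceiling, mA.
#' @param update_rate Encoder update rate, Hz.
#' @return A list of class `encoding_config`.
#' @export
encoding_config <- function(scheme = c("linear", "exponential"),
                            F_min = 0.5, F_max = 10,
                            A_min = 1, A_max = 5,
                            omega = 0.005,
                            contact_threshold = F_min,
                            exp_threshold = 1,
                            sensor_scale = 20,
                            hardware_max = HARDWARE_MAX_MA,
                            update_rate = 50) {
  scheme <- match.arg(scheme)
  if (!(F_min < F_max)) field_error("F_min/F_max", "requires F_min < F_max")
  if (!(A_min >= 0 && A_min < A_max)) {
    field_error("A_min/A_max", "requires 0 <= A_min < A_max")
  }
  if (A_max > hardware_max) {
    field_error("A_max", sprintf("%.3g mA exceeds the %.3g mA hardware limit",
                                 A_max, hardware_max))
  }
  if (omega <= 0) field_error("omega", "must be > 0")
  if (omega < 0.005 || omega > 0.025) {
    warning("omega = ", omega, " is outside the empirically assigned ",
            "window [0.005, 0.025]", call. = FALSE)
  }
  structure(list(scheme = scheme, F_min = F_min, F_max = F_max,
                 A_min = A_min, A_max = A_max, omega = omega,
                 contact_threshold = contact_threshold,
                 exp_threshold = exp_threshold, sensor_scale = sensor_scale,
                 hardware_max = hardware_max, update_rate = update_rate),
            class = "encoding_config")
}

#' Normalize grasp force to [0, 1]
#'
#' `(F - F_min) / (F_max - F_min)`, clipped to the unit interval.
#'
#' @param F Force, N (vectorized).
#' @param cfg An [encoding_config()].
#' @return Normalized force in \[0, 1\].
#' @export
normalize_force <- function(F, cfg) {
  if (cfg$F_max <= cfg$F_min) stop("degenerate calibration: F_max <= F_min")
  pmin(1, pmax(0, (F - cfg$F_min) / (cfg$F_max - cfg$F_min)))
}

#' Linear encoding scheme
#'
#' `A = F_n * (A_max - A_min) + A_min`. When the driving force is supplied,
#' samples below `contact_threshold` command zero amplitude.
#'
#' @param F_n Normalized force in \[0, 1\] (vectorized).
#' @param cfg An [encoding_config()].
#' @param force Optional raw driving force (N), used for the
#'   contact-threshold gate.
#' @return Amplitude, mA.
#' @export
encode_linear <- function(F_n, cfg, force = NULL) {
  A <- F_n * (cfg$A_max - cfg$A_min) + cfg$A_min
  A <- pmin(A, cfg$hardware_max)
  if (!is.null(force)) A[force < cfg$contact_threshold] <- 0
  A
}

#' Exponential encoding scheme
#'
#' `A = A_min * exp(omega * F)` for `F > exp_threshold` and 0 otherwise,
#' with `F` in raw sensor units; output capped at
#' `min(A_max, hardware_max)`. The scheme is discontinuous at its threshold
#' (jump from 0 to `A_min * exp(omega * exp_threshold)`); see
#' [encoding_jump()].
#'
#' @param F Force in raw sensor units (vectorized).
#' @param cfg An [encoding_config()].
#' @return Amplitude, mA.
#' @export
encode_exponential <- function(F, cfg) {
  stopifnot(cfg$omega > 0)
  A <- cfg$A_min * exp(cfg$omega * F)
  A <- pmin(A, cfg$A_max, cfg$hardware_max)
  A[F <= cfg$exp_threshold] <- 0
  A
}

#' Size of the exponential scheme's onset discontinuity
#'
#' The exponential map jumps from 0 to `A_min * exp(omega * exp_threshold)`
#' at its threshold. The jump is reported, never smoothed.
#'
#' @param cfg An [encoding_config()].
#' @return Jump size, mA.
#' @export
encoding_jump <- function(cfg) {
  if (cfg$scheme != "exponential") return(0)
  min(cfg$A_min * exp(cfg$omega * cfg$exp_threshold), cfg$A_max,
      cfg$hardware_max)
}

#' Stimulation pulse-train parameters
#'
#' Charge-balanced, anodic-first square pulses with symmetric phases; per
#' phase charge is `amplitude * pulse_width`.
#'
#' @param frequency Pulse rate, Hz (operating range 1-300).
#' @param pulse_width Per-phase width, microseconds (range 50-1000).
#' @param interphase Interphase interval, microseconds (60 in-study).
#' @param polarity Only `"anodic_first"` is supported.
#' @param configuration `"monopolar"` or `"multipolar"`.
#' @param electrode_id Electrode label.
#' @return A list of class `stim_train`.
#' @export
stim_train <- function(frequency = 100, pulse_width = 200, interphase = 60,
                       polarity = "anodic_first",
                       configuration = c("monopolar", "multipolar"),
                       electrode_id = "E1") {
  structure(list(frequency = frequency, pulse_width = pulse_width,
                 interphase = interphase, polarity = polarity,
                 configuration = match.arg(configuration),
                 electrode_id = electrode_id),
            class = "stim_train")
}

#' Validate stimulation-train parameters against hardware ranges
#'
#' @param train A [stim_train()].
#' @return Character vector of violations (empty when the train is valid),
#'   each naming the offending value and the allowed range.
#' @export
validate_stim_params <- function(train) {
  v <- character(0)
  if (train$frequency < 1 || train$frequency > 300) {
    v <- c(v, sprintf("frequency %g Hz outside range 1-300 Hz",
                      train$frequency))
  }
  if (train$pulse_width < 50 || train$pulse_width > 1000) {
    v <- c(v, sprintf("pulse_width %g us outside range 50-1000 us",
                      train$pulse_width))
  }
  if (train$interphase < 0) {
    v <- c(v, sprintf("interphase %g us is negative", train$interphase))
  }
  if (!identical(train$polarity, "anodic_first")) {
    v <- c(v, "polarity must be anodic_first (charge-balanced symmetric)")
  }
  v
}

#' Run the 50 Hz encoding loop over a force series
#'
#' Applies the configured scheme sample-wise to a filtered force series on
#' the 50 Hz grid. Both schemes command zero amplitude while the force is
#' below `contact_threshold`; the exponential scheme additionally applies its
#' own sensor-unit threshold. All commanded amplitudes respect the hardware
#' ceiling.
#'
#' @param filtered_force Filtered force series, N, on the 50 Hz grid.
#' @param cfg An [encoding_config()].
#' @param train A [stim_train()]; validated before encoding.
#' @param time Optional time vector (s); defaults to the encoder grid.
#' @return A list of class `stim_trace`: `time`, `amplitude` (mA),
#'   `encoding`, `train`, and `charge_per_phase_nC` (peak, for audit).
#' @export
run_encoder <- function(filtered_force, cfg, train = stim_train(),
                        time = NULL) {
  stopifnot(inherits(cfg, "encoding_config"))
  viol <- validate_stim_params(train)
  if (length(viol)) {
    stop("invalid stimulation train: ", paste(viol, collapse = "; "))
  }
  if (is.null(time)) {
    time <- (seq_along(filtered_force) - 1) / cfg$update_rate
  }
  amp <- if (cfg$scheme == "linear") {
    encode_linear(normalize_force(filtered_force, cfg), cfg,
                  force = filtered_force)
  } else {
    a <- encode_exponential(filtered_force * cfg$sensor_scale, cfg)
    a[filtered_force < cfg$contact_threshold] <- 0
    a
  }
  structure(list(time = time, amplitude = amp, encoding = cfg, train = train,
                 charge_per_phase_nC = max(amp) * train$pulse_width),
            class = "stim_trace")
}
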