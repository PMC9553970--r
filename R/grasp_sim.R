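#' Synthetic grasp-trial generator
#'
#' Simulates single grasp trials at 50 Hz under the two prosthesis-control
#' schemes used in the discrimination tasks:
#'
#' * `glove_proportional` — the subject's intact contralateral hand wears a
#'   data glove whose normalized aperture proportionally commands the
#'   prosthetic hand aperture (identity mapping on normalized aperture).
#' * `emg_threshold_velocity` — ipsilateral surface EMG is processed by the
#'   real-time chain; while the MVC-normalized envelope is above a manual
#'   threshold the hand closes at a constant 15 deg/s, otherwise it opens at
#'   30 deg/s.
#'
#' Object contact is a linear spring: zero force until the closing hand
#' reaches the object's contact aperture, then `stiffness * closure-beyond-
#' contact`. The reported raw force is the maximum across three simulated
#' fingertip sensors receiving identical contact force plus independent
#' Gaussian noise, mirroring the max-pooling over index/middle/ring sensors.
#'
#' @name grasp_sim
NULL

#' Prosthesis control configuration
#'
#' @param scheme `"glove_proportional"` or `"emg_threshold_velocity"`.
#' @param close_velocity EMG-scheme closing speed, deg/s.
#' @param open_velocity EMG-scheme opening speed, deg/s.
#' @param emg_threshold MVC-fraction threshold in (0, 1).
#' @param aperture_range `c(fully_open_deg, fully_closed_deg)`.
#' @param sample_rate Control/force sampling rate, Hz.
#' @param glove_close_velocity Typical contralateral-hand closing speed under
#'   glove control, deg/s (the subject, not the control law, sets this).
#' @return A list of class `control_config`.
#' @export
control_config <- function(scheme = c("glove_proportional",
                                      "emg_threshold_velocity"),
                           close_velocity = 15, open_velocity = 30,
                           emg_threshold = 0.3,
                           aperture_range = c(90, 0), sample_rate = 50,
                           glove_close_velocity = 25) {
  scheme <- match.arg(scheme)
  if (close_velocity <= 0) field_error("close_velocity", "must be > 0")
  if (open_velocity <= 0) field_error("open_velocity", "must be > 0")
  if (emg_threshold <= 0 || emg_threshold >= 1) {
    field_error("emg_threshold", "must lie strictly in (0, 1)")
  }
  structure(list(scheme = scheme, close_velocity = close_velocity,
                 open_velocity = open_velocity, emg_threshold = emg_threshold,
                 aperture_range = aperture_range, sample_rate = sample_rate,
                 glove_close_velocity = glove_close_velocity),
            class = "control_config")
}

#' Trial-to-trial noise configuration
#'
#' `command_onset_jitter_sd` is the key behavioural noise source: under the
#' EMG scheme the intent profile contains a brief initial flexion burst
#' followed, after a truncated-normal delay (mean `grasp_delay_mean`, sd
#' `command_onset_jitter_sd`), by the sustained grasp epoch. This delay
#' between the onset of flexion and the onset of grasp is what injects
#' variance into the stimulation onset lag. Under the glove scheme the same
#' jitter shifts the closure onset time (which leaves aperture-based features
#' untouched).
#'
#' @param sensor_noise_sd Per-sensor force noise SD, N.
#' @param stiffness_cv Trial-to-trial coefficient of variation of the
#'   effective contact stiffness (lognormal): grip geometry and object
#'   placement vary between presentations.
#' @param contact_jitter_sd Trial-to-trial SD of the effective contact
#'   aperture, deg (where on the fingers the object is met varies).
#' @param command_onset_jitter_sd Onset jitter SD, s (>= 0).
#' @param grasp_delay_mean Mean flexion-to-grasp delay under the EMG scheme, s.
#' @param glove_ballistic If `TRUE`, glove closures are rapid near-step
#'   movements (rate-limited at `ballistic_velocity`) rather than smooth
#'   constant-rate closures.
#' @param ballistic_velocity Closure speed of ballistic movements, deg/s.
#' @param glove_speed_cv Trial-to-trial coefficient of variation of the glove
#'   closure speed.
#' @param emg_baseline Resting EMG amplitude as a fraction of the grasp-epoch
#'   amplitude.
#' @param emg_band Band of the synthetic EMG noise carrier, Hz.
#' @param flex_onset Nominal time of the first flexion burst, s.
#' @param burst_duration Duration of the flexion burst, s.
#' @param rng_seed Integer seed for the trial.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(sensor_noise_sd = 0.05,
                         stiffness_cv = 0.10,
                         contact_jitter_sd = 2,
                         command_onset_jitter_sd = 0.3,
                         grasp_delay_mean = 0.5,
                         glove_ballistic = FALSE,
                         ballistic_velocity = 200,
                         glove_speed_cv = 0.1,
                         emg_baseline = 0.05,
                         emg_band = c(20, 450),
                         flex_onset = 1.0,
                         burst_duration = 0.25,
                         rng_seed = NULL) {
  if (sensor_noise_sd < 0) field_error("sensor_noise_sd", "must be >= 0")
  if (stiffness_cv < 0) field_error("stiffness_cv", "must be >= 0")
  if (contact_jitter_sd < 0) field_error("contact_jitter_sd", "must be >= 0")
  if (command_onset_jitter_sd < 0) {
    field_error("command_onset_jitter_sd", "must be >= 0")
  }
  structure(list(sensor_noise_sd = sensor_noise_sd,
                 stiffness_cv = stiffness_cv,
                 contact_jitter_sd = contact_jitter_sd,
                 command_onset_jitter_sd = command_onset_jitter_sd,
                 grasp_delay_mean = grasp_delay_mean,
                 glove_ballistic = isTRUE(glove_ballistic),
                 ballistic_velocity = ballistic_velocity,
                 glove_speed_cv = glove_speed_cv,
                 emg_baseline = emg_baseline, emg_band = emg_band,
                 flex_onset = flex_onset, burst_duration = burst_duration,
                 rng_seed = rng_seed),
            class = "noise_config")
}

#' Spring-contact force model
#'
#' Zero force while the hand is more open than the object's contact
#' aperture; a linear spring (`stiffness` N/deg) beyond it.
#'
#' @param aperture Hand aperture, deg (vectorized).
#' @param object One row of an `object_set` (list or data.frame row with
#'   `contact_aperture` and `stiffness`).
#' @return Contact force, N.
#' @export
contact_force <- function(aperture, object) {
  pmax(0, object$stiffness * (object$contact_aperture - aperture))
}

# per-trial grip-geometry variability: effective stiffness (lognormal) and
# effective contact aperture vary between presentations of the same object
perturb_object <- function(object, noise_cfg) {
  o <- as.list(object)
  if (noise_cfg$stiffness_cv > 0) {
    o$stiffness <- o$stiffness * exp(stats::rnorm(1, 0, noise_cfg$stiffness_cv))
  }
  if (noise_cfg$contact_jitter_sd > 0) {
    o$contact_aperture <- o$contact_aperture +
      stats::rnorm(1, 0, noise_cfg$contact_jitter_sd)
  }
  o
}

# max across three fingertip sensors seeing the same contact force plus
# independent noise; sensors never report negative force
sense_force <- function(contact, sd) {
  n <- length(contact)
  if (sd <= 0) return(pmax(0, contact))
  s <- matrix(stats::rnorm(3 * n, 0, sd), nrow = 3)
  pmax(0, apply(sweep(s, 2, contact, "+"), 2, max))
}

finish_trace <- function(time, command, aperture, raw_force, object,
                         command_onset_time, control_cfg, noise_cfg,
                         filter_cfg, extra = list()) {
  trace <- list(time = time, command = command, aperture = aperture,
                raw_force = raw_force,
                filtered_force = lowpass_force(raw_force, filter_cfg),
                object = as.list(object),
                command_onset_time = command_onset_time)
  trace <- c(trace, extra)
  attr(trace, "control_cfg") <- control_cfg
  attr(trace, "noise_cfg") <- noise_cfg
  class(trace) <- "grasp_trace"
  trace
}

#' Simulate one glove-controlled grasp trial
#'
#' The contralateral hand starts fully open, begins closing at a jittered
#' onset time, and closes at either a smooth constant rate (with
#' trial-to-trial speed variability) or a ballistic rate-limited near-step,
#' down to full closure. The prosthetic aperture equals the glove aperture
#' (identity proportional mapping); force follows the spring-contact model
#' plus sensor noise.
#'
#' @param object One row of an `object_set`.
#' @param control_cfg A [control_config()] with scheme `glove_proportional`.
#' @param noise_cfg A [noise_config()].
#' @param timeout Trial duration, s (> 0).
#' @param filter_cfg Force filter, a [force_filter_config()].
#' @return A `grasp_trace`: `time`, `command` (glove aperture fraction, 1 =
#'   fully open), `aperture` (deg), `raw_force`, `filtered_force` (N),
#'   `object`, `command_onset_time`.
#' @export
simulate_glove_trial <- function(object, control_cfg, noise_cfg,
                                 timeout = 10,
                                 filter_cfg = force_filter_config()) {
  stopifnot(identical(control_cfg$scheme, "glove_proportional"))
  if (timeout <= 0) stop("timeout must be > 0")
  if (!is.null(noise_cfg$rng_seed)) {
    return(with_seed(noise_cfg$rng_seed,
                     simulate_glove_trial(object, control_cfg,
                                          noise_config_unseeded(noise_cfg),
                                          timeout, filter_cfg)))
  }
  fs <- control_cfg$sample_rate
  dt <- 1 / fs
  time <- seq(0, timeout - dt, by = dt)
  open <- max(control_cfg$aperture_range)
  closed <- min(control_cfg$aperture_range)

  t0 <- max(0, noise_cfg$flex_onset +
              stats::rnorm(1, 0, noise_cfg$command_onset_jitter_sd))
  v <- if (noise_cfg$glove_ballistic) noise_cfg$ballistic_velocity else
    max(1, control_cfg$glove_close_velocity *
          (1 + stats::rnorm(1, 0, noise_cfg$glove_speed_cv)))
  aperture <- pmin(open, pmax(closed, open - v * (time - t0)))
  command <- (aperture - closed) / (open - closed)

  object <- perturb_object(object, noise_cfg)
  raw <- sense_force(contact_force(aperture, object), noise_cfg$sensor_noise_sd)
  finish_trace(time, command, aperture, raw, object, t0, control_cfg,
               noise_cfg, filter_cfg)
}

# copy of a noise config with the seed cleared (used once consumed)
noise_config_unseeded <- function(noise_cfg) {
  noise_cfg$rng_seed <- NULL
  noise_cfg
}

#' Generate synthetic raw EMG at 2000 Hz
#'
#' Band-limited zero-mean Gaussian noise amplitude-modulated by an intent
#' profile: resting baseline, a brief initial flexion burst at a jittered
#' onset, then the sustained grasp epoch after a truncated-normal
#' flexion-to-grasp delay. Returns the raw series together with the true
#' flexion-onset and grasp-onset times.
#'
#' @param duration Trial duration, s.
#' @param noise_cfg A [noise_config()].
#' @param raw_rate EMG sampling rate, Hz (2000).
#' @return List: `raw` (numeric), `raw_rate`, `flex_onset_time`,
#'   `grasp_onset_time`.
#' @export
generate_emg <- function(duration, noise_cfg, raw_rate = 2000) {
  n <- round(duration * raw_rate)
  t <- (seq_len(n) - 1) / raw_rate
  bp <- signal::butter(2, noise_cfg$emg_band / (raw_rate / 2), type = "pass")
  carrier <- as.numeric(signal::filter(bp, stats::rnorm(n)))
  # normalize carrier power so amplitude profile is in consistent units
  carrier <- carrier / stats::sd(carrier)

  t_flex <- max(0, noise_cfg$flex_onset)
  delay <- max(noise_cfg$burst_duration,
               stats::rnorm(1, noise_cfg$grasp_delay_mean,
                            noise_cfg$command_onset_jitter_sd))
  t_grasp <- t_flex + delay
  amp <- rep(noise_cfg$emg_baseline, n)
  amp[t >= t_flex & t < t_flex + noise_cfg$burst_duration] <- 1
  amp[t >= t_grasp] <- 1
  list(raw = amp * carrier, raw_rate = raw_rate,
       flex_onset_time = t_flex, grasp_onset_time = t_grasp)
}

#' Reference MVC envelope peak for the synthetic EMG model
#'
#' Simulates a maximum voluntary contraction (amplitude-1 epoch) through the
#' same envelope chain and returns its peak, for MVC normalization.
#'
#' @param noise_cfg A [noise_config()].
#' @param emg_cfg An [emg_chain_config()].
#' @param duration MVC recording length, s.
#' @param seed Seed for the MVC recording.
#' @return Peak envelope value (chain units).
#' @export
simulate_mvc_peak <- function(noise_cfg, emg_cfg = emg_chain_config(),
                              duration = 3, seed = 1L) {
  with_seed(seed, {
    n <- round(duration * emg_cfg$raw_rate)
    bp <- signal::butter(2, noise_cfg$emg_band / (emg_cfg$raw_rate / 2),
                         type = "pass")
    carrier <- as.numeric(signal::filter(bp, stats::rnorm(n)))
    carrier <- carrier / stats::sd(carrier)
    env <- process_emg(carrier, emg_cfg)
    # drop the settling edge of the high-pass stage
    max(env[-seq_len(min(10, length(env) - 1))])
  })
}

#' Simulate one EMG-controlled grasp trial
#'
#' Generates raw EMG with [generate_emg()], extracts the 50 Hz envelope with
#' [process_emg()], normalizes to the MVC peak, integrates the
#' threshold-crossing velocity control law, and applies the spring-contact
#' force model plus sensor noise.
#'
#' @param object One row of an `object_set`.
#' @param control_cfg A [control_config()] with scheme
#'   `emg_threshold_velocity`.
#' @param noise_cfg A [noise_config()].
#' @param timeout Trial duration, s.
#' @param filter_cfg Force filter configuration.
#' @param emg_cfg EMG chain configuration. The control loop uses
#'   rectification before bin averaging (`rectify_after_average = FALSE`);
#'   see the methods vignette.
#' @param mvc_peak MVC envelope peak in chain units; computed via
#'   [simulate_mvc_peak()] when `NULL`.
#' @param emg_generator Function `(duration, noise_cfg)` returning the raw
#'   EMG list (defaults to [generate_emg()]); must produce 2000 Hz data.
#' @return A `grasp_trace` whose `command` is the MVC-normalized envelope;
#'   `command_onset_time` is the first threshold crossing, and the extra
#'   fields `flex_onset_time`/`grasp_onset_time` carry the generator's ground
#'   truth.
#' @export
simulate_emg_trial <- function(object, control_cfg, noise_cfg, timeout = 10,
                               filter_cfg = force_filter_config(),
                               emg_cfg = emg_chain_config(
                                 rectify_after_average = FALSE),
                               mvc_peak = NULL,
                               emg_generator = generate_emg) {
  stopifnot(identical(control_cfg$scheme, "emg_threshold_velocity"))
  if (timeout <= 0) stop("timeout must be > 0")
  if (!is.null(noise_cfg$rng_seed)) {
    return(with_seed(noise_cfg$rng_seed,
                     simulate_emg_trial(object, control_cfg,
                                        noise_config_unseeded(noise_cfg),
                                        timeout, filter_cfg, emg_cfg,
                                        mvc_peak, emg_generator)))
  }
  emg <- emg_generator(timeout, noise_cfg)
  if (!isTRUE(all.equal(as.numeric(emg$raw_rate),
                        as.numeric(emg_cfg$raw_rate)))) {
    stop("emg_generator sample rate (", emg$raw_rate,
         " Hz) does not match the chain configuration (",
         emg_cfg$raw_rate, " Hz)")
  }
  if (is.null(mvc_peak)) mvc_peak <- simulate_mvc_peak(noise_cfg, emg_cfg)
  env <- normalize_to_mvc(process_emg(emg$raw, emg_cfg), mvc_peak,
                          quiet = TRUE)
  fs <- emg_cfg$output_rate
  dt <- 1 / fs
  time <- (seq_along(env) - 1) / fs
  open <- max(control_cfg$aperture_range)
  aperture <- threshold_velocity_controller(
    env, control_cfg$emg_threshold,
    close_velocity = control_cfg$close_velocity,
    open_velocity = control_cfg$open_velocity,
    aperture_range = control_cfg$aperture_range,
    start_aperture = open, dt = dt)

  object <- perturb_object(object, noise_cfg)
  raw <- sense_force(contact_force(aperture, object), noise_cfg$sensor_noise_sd)
  crossing <- which(env >= control_cfg$emg_threshold)
  t_cmd <- if (length(crossing)) time[crossing[1]] else NA_real_
  finish_trace(time, env, aperture, raw, object, t_cmd, control_cfg,
               noise_cfg, filter_cfg,
               extra = list(flex_onset_time = emg$flex_onset_time,
                            grasp_onset_time = emg$grasp_onset_time,
                            mvc_peak = mvc_peak))
}

#' Simulate a full scheduled session
#'
#' Runs one grasp trial per scheduled presentation (per-trial seeds derived
#' from the session seed with [derive_seed()], so any trial can be reproduced
#' in isolation) and encodes each force trace into a stimulation trace.
#'
#' @param schedule A `session_schedule` from [make_schedule()] or
#'   [preset_schedule()].
#' @param control_cfg A [control_config()].
#' @param noise_cfg A [noise_config()]; its `rng_seed` (or `session_seed`)
#'   seeds the whole session.
#' @param encoding_cfg An [encoding_config()].
#' @param train A [stim_train()].
#' @param session_seed Overrides `noise_cfg$rng_seed` when given.
#' @param filter_cfg Force filter configuration.
#' @param emg_cfg EMG chain configuration (EMG scheme only).
#' @return A list of class `grasp_session`; each element is
#'   `list(grasp = <grasp_trace>, stim = <stim_trace>)`. The schedule and
#'   configurations are attached as attributes.
#' @export
simulate_session <- function(schedule, control_cfg, noise_cfg, encoding_cfg,
                             train = stim_train(), session_seed = NULL,
                             filter_cfg = force_filter_config(),
                             emg_cfg = emg_chain_config(
                               rectify_after_average = FALSE)) {
  stopifnot(inherits(schedule, "session_schedule"))
  master <- if (!is.null(session_seed)) session_seed else
    if (!is.null(noise_cfg$rng_seed)) noise_cfg$rng_seed else 1L
  mvc <- if (control_cfg$scheme == "emg_threshold_velocity") {
    simulate_mvc_peak(noise_cfg, emg_cfg, seed = derive_seed(master, 0))
  } else NULL

  trials <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    row <- schedule[i, , drop = FALSE]
    ncfg <- noise_cfg
    ncfg$rng_seed <- derive_seed(master, i)
    grasp <- if (control_cfg$scheme == "glove_proportional") {
      simulate_glove_trial(row, control_cfg, ncfg, timeout = row$timeout_s,
                           filter_cfg = filter_cfg)
    } else {
      simulate_emg_trial(row, control_cfg, ncfg, timeout = row$timeout_s,
                         filter_cfg = filter_cfg, emg_cfg = emg_cfg,
                         mvc_peak = mvc)
    }
    stim <- run_encoder(grasp$filtered_force, encoding_cfg, train,
                        time = grasp$time)
    trials[[i]] <- list(grasp = grasp, stim = stim)
  }
  structure(trials, schedule = schedule, control_cfg = control_cfg,
            noise_cfg = noise_cfg, encoding_cfg = encoding_cfg,
            train = train, session_seed = master,
            class = "grasp_session")
}

#' Simulate a built-in preset session end to end
#'
#' Convenience wrapper: builds the preset schedule, the scheme-appropriate
#' control and noise defaults, and the preset's encoding scheme, then runs
#' [simulate_session()]. The S2 presets (EMG control) default to the
#' seconds-scale flexion-to-grasp onset variability characteristic of
#' impaired ipsilateral myoelectric control.
#'
#' @param name Preset name; see [list_presets()].
#' @param seed Session seed (also shuffles the schedule).
#' @param noise_cfg Optional [noise_config()] override.
#' @param encoding_cfg Optional [encoding_config()] override.
#' @param control_cfg Optional [control_config()] override.
#' @return A `grasp_session`.
#' @export
simulate_preset_session <- function(name, seed = 1L, noise_cfg = NULL,
                                    encoding_cfg = NULL, control_cfg = NULL) {
  pc <- preset_config(name)
  sched <- make_schedule(pc$object_set, pc$repetitions, seed = seed,
                         timeout = pc$timeout_s,
                         queried_property = pc$queried_property)
  emg <- pc$control_scheme == "emg_threshold_velocity"
  if (is.null(control_cfg)) control_cfg <- control_config(pc$control_scheme)
  if (is.null(noise_cfg)) {
    noise_cfg <- if (emg) {
      noise_config(command_onset_jitter_sd = 2.5, grasp_delay_mean = 3.0)
    } else {
      noise_config()
    }
  }
  if (is.null(encoding_cfg)) encoding_cfg <- encoding_config(pc$encoding_scheme)
  simulate_session(sched, control_cfg, noise_cfg, encoding_cfg,
                   session_seed = seed)
}
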