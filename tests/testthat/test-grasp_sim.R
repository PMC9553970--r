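obj <- function(size = "M", comp = "medium", ...) {
  os <- build_object_set(sizes = size, compliances = comp, ...)
  os[1, , drop = FALSE]
}

test_that("spring-contact model: no force before contact, linear after", {
  o <- obj() # contact at 45 deg, stiffness 0.15
  expect_equal(contact_force(70, list(contact_aperture = 60,
                                      stiffness = 0.15)), 0)
  expect_equal(contact_force(50, list(contact_aperture = 60,
                                      stiffness = 0.2)), 2.0)
  # monotone in stiffness at equal closure past contact
  hard <- obj(comp = "hard"); soft <- obj(comp = "soft")
  expect_gt(contact_force(30, hard), contact_force(30, soft))
  expect_equal(contact_force(o$contact_aperture, o), 0)
})

test_that("glove trial: zero force when closure never reaches contact", {
  o <- obj(size = "S") # contact at 30 deg
  ctl <- control_config("glove_proportional", aperture_range = c(90, 40))
  tr <- simulate_glove_trial(o, ctl, quick_noise(sensor_noise_sd = 0),
                             timeout = 8)
  expect_equal(max(tr$raw_force), 0)
  expect_equal(min(tr$aperture), 40)
})

test_that("glove trial: noiseless force slope after contact equals k*v", {
  o <- obj(comp = "medium") # k = 0.15 N/deg
  ctl <- control_config("glove_proportional", glove_close_velocity = 25)
  nz <- noise_config(sensor_noise_sd = 0, stiffness_cv = 0, contact_jitter_sd = 0, command_onset_jitter_sd = 0,
                     glove_speed_cv = 0, rng_seed = 1L)
  tr <- simulate_glove_trial(o, ctl, nz, timeout = 6)
  # slope of the raw force while closing past contact (before full closure)
  moving <- which(tr$raw_force > 0.2 & tr$aperture > 1)
  seg <- moving[5:(length(moving) - 5)]
  slope <- coef(lm(tr$raw_force[seg] ~ tr$time[seg]))[2]
  expect_equal(unname(slope), 0.15 * 25, tolerance = 0.02)
})

test_that("larger objects are contacted earlier on the same profile", {
  ctl <- control_config("glove_proportional")
  nz <- noise_config(sensor_noise_sd = 0, stiffness_cv = 0, contact_jitter_sd = 0, command_onset_jitter_sd = 0,
                     glove_speed_cv = 0, rng_seed = 1L)
  t_contact <- vapply(c("S", "M", "L"), function(sz) {
    tr <- simulate_glove_trial(obj(size = sz), ctl, nz, timeout = 8)
    tr$time[which(tr$raw_force > 0)[1]]
  }, numeric(1))
  expect_true(all(diff(t_contact[c("S", "M", "L")]) < 0))
})

test_that("EMG trial: contact time matches the constant-velocity closed form", {
  o <- obj(size = "L") # contact at 60 deg
  ctl <- control_config("emg_threshold_velocity") # close at 15 deg/s from 90
  nz <- noise_config(sensor_noise_sd = 0, stiffness_cv = 0, contact_jitter_sd = 0, command_onset_jitter_sd = 0,
                     grasp_delay_mean = 0, rng_seed = 3L)
  tr <- simulate_emg_trial(o, ctl, nz, timeout = 8)
  t_close <- tr$command_onset_time
  t_contact <- tr$time[which(tr$raw_force > 0)[1]]
  expect_equal(t_contact - t_close, (90 - 60) / 15, tolerance = 0.1)
})

test_that("EMG trial: sub-threshold envelope keeps the hand open", {
  o <- obj(size = "L")
  ctl <- control_config("emg_threshold_velocity", emg_threshold = 0.9)
  # baseline-only EMG (no grasp epoch within the trial)
  nz <- noise_config(sensor_noise_sd = 0, stiffness_cv = 0, contact_jitter_sd = 0, flex_onset = 100,
                     grasp_delay_mean = 0, command_onset_jitter_sd = 0,
                     rng_seed = 4L)
  tr <- simulate_emg_trial(o, ctl, nz, timeout = 5)
  expect_equal(min(tr$aperture), 90)
  expect_equal(max(tr$raw_force), 0)
})

test_that("trials and sessions are seed-deterministic", {
  o <- obj()
  ctl <- control_config("emg_threshold_velocity")
  nz <- quick_noise()
  a <- simulate_emg_trial(o, ctl, nz, timeout = 6)
  b <- simulate_emg_trial(o, ctl, nz, timeout = 6)
  expect_identical(a, b)

  sch <- preset_schedule("S2-physical-size", seed = 5)
  args <- list(sch, control_config("emg_threshold_velocity"),
               noise_config(), encoding_config("linear"))
  s1 <- do.call(simulate_session, c(args, session_seed = 5))
  s2 <- do.call(simulate_session, c(args, session_seed = 5))
  expect_identical(s1[[7]], s2[[7]])
})

test_that("sessions produce one trace pair per scheduled trial", {
  sch <- preset_schedule("S1-virtual-size", seed = 2)
  s <- simulate_session(sch, control_config("glove_proportional"),
                        noise_config(), encoding_config("exponential"),
                        session_seed = 2)
  expect_length(s, 72)
  expect_s3_class(s[[1]]$grasp, "grasp_trace")
  expect_s3_class(s[[1]]$stim, "stim_trace")
  expect_equal(length(s[[1]]$grasp$time), length(s[[1]]$stim$amplitude))

  empty <- make_schedule(build_object_set(), 0, seed = 1)
  s0 <- simulate_session(empty, control_config("glove_proportional"),
                         noise_config(), encoding_config("linear"),
                         session_seed = 1)
  expect_length(s0, 0)
})

test_that("mean contact time decreases with size; force slope grows with stiffness", {
  ctl <- control_config("glove_proportional")
  contact_times <- sapply(c("S", "M", "L"), function(sz) {
    mean(vapply(1:30, function(i) {
      tr <- simulate_glove_trial(obj(size = sz), ctl,
                                 noise_config(rng_seed = i), timeout = 8)
      tr$time[which(tr$raw_force > 0.2)[1]]
    }, numeric(1)))
  })
  expect_true(all(diff(contact_times[c("S", "M", "L")]) < 0))

  slopes <- sapply(c("soft", "medium", "hard"), function(cp) {
    mean(vapply(1:30, function(i) {
      tr <- simulate_glove_trial(obj(size = "L", comp = cp), ctl,
                                 noise_config(rng_seed = i), timeout = 8)
      idx <- which(tr$raw_force > 0.2 & tr$aperture > 1)
      seg <- idx[3:(length(idx) - 2)]
      unname(coef(lm(tr$raw_force[seg] ~ tr$time[seg]))[2])
    }, numeric(1)))
  })
  expect_true(all(diff(slopes[c("soft", "medium", "hard")]) > 0))
})

test_that("EMG generator validates its sample rate", {
  gen_bad <- function(duration, noise_cfg) {
    list(raw = numeric(1000), raw_rate = 1000)
  }
  expect_error(
    simulate_emg_trial(obj(), control_config("emg_threshold_velocity"),
                       quick_noise(), timeout = 4, emg_generator = gen_bad),
    "sample rate")
})
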