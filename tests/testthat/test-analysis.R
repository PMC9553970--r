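sim_emg_trial_pair <- function(size = "L", comp = "medium", seed = 1L,
                               scheme = "linear", timeout = 10, ...) {
  os <- build_object_set(sizes = size, compliances = comp)
  ctl <- control_config("emg_threshold_velocity")
  nz <- noise_config(sensor_noise_sd = 0, stiffness_cv = 0, contact_jitter_sd = 0, command_onset_jitter_sd = 0,
                     grasp_delay_mean = 0, rng_seed = seed, ...)
  grasp <- simulate_emg_trial(os[1, ], ctl, nz, timeout = timeout)
  stim <- run_encoder(grasp$filtered_force, encoding_config(scheme),
                      time = grasp$time)
  list(grasp = grasp, stim = stim)
}

test_that("onset lag matches the constant-velocity closed form", {
  # start 90 deg, contact 60 deg, 15 deg/s => lag ~ 2 s (+ contact threshold)
  tp <- sim_emg_trial_pair(size = "L", comp = "hard")
  f <- extract_features(tp$grasp, tp$stim)
  expect_true(is.na(f$null_reason))
  # crossing 0.5 N at k = 0.45 N/deg adds 0.5/(0.45*15) ~ 0.07 s; the causal
  # filter adds a few samples of group delay
  expect_equal(f$onset_lag_s, 2.0, tolerance = 0.15)
  expect_equal(f$aperture_at_onset_deg, 60, tolerance = 3)
})

test_that("zero-force trials yield null features, not zeros", {
  os <- build_object_set(sizes = "S")
  ctl <- control_config("glove_proportional", aperture_range = c(90, 50))
  grasp <- simulate_glove_trial(os[1, ], ctl, quick_noise(sensor_noise_sd = 0),
                                timeout = 5)
  stim <- run_encoder(grasp$filtered_force, encoding_config("linear"),
                      time = grasp$time)
  f <- extract_features(grasp, stim)
  expect_equal(f$null_reason, "no_stimulation")
  expect_true(is.na(f$onset_lag_s))
  expect_true(is.na(f$peak_amp_mA))
})

test_that("rate of change recovers the encoder gain times k*v", {
  # ramp force k*v with the linear scheme: rate = k*v*(A_max-A_min)/(F_max-F_min)
  k <- 0.15; v <- 15
  tp <- sim_emg_trial_pair(size = "L", comp = "medium")
  f <- extract_features(tp$grasp, tp$stim)
  cfg <- tp$stim$encoding
  expected <- k * v * (cfg$A_max - cfg$A_min) / (cfg$F_max - cfg$F_min)
  expect_equal(f$rate_mA_per_s, expected, tolerance = 0.05 * expected + 0.02)
  # regression-based alternative agrees
  f2 <- extract_features(tp$grasp, tp$stim, rate_method = "regression")
  expect_equal(f2$rate_mA_per_s, expected, tolerance = 0.1 * expected)
})

test_that("exact binomial equals the enumeration oracle and is monotone", {
  for (n in c(5, 12, 20)) {
    for (k in 0:n) {
      for (p0 in c(0.25, 1 / 3, 0.5)) {
        expect_equal(binomial_above_chance(k, n, p0)$p_value,
                     oracle_binom_upper(k, n, p0), tolerance = 1e-12)
      }
    }
  }
  # monotone decreasing in k
  ps <- vapply(0:30, function(k)
    binomial_above_chance(k, 30, 1 / 3)$p_value, numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
  # closed forms
  expect_equal(binomial_above_chance(10, 10, 0.5)$p_value, 2^-10)
  expect_equal(binomial_above_chance(0, 17, 0.3)$p_value, 1)
  # agreement with the standard exact test
  expect_equal(binomial_above_chance(53, 72, 1 / 3)$p_value,
               binom.test(53, 72, 1 / 3, alternative = "greater")$p.value,
               tolerance = 1e-12)
  expect_error(binomial_above_chance(5, 3, 0.5), "k <= n")
  expect_error(binomial_above_chance(2, 3, 1.2), "strictly")
})

test_that("MANOVA Wilks' lambda equals explicit scatter-matrix arithmetic", {
  # hand-computable 2-group, 2-feature fixture
  fx <- data.frame(
    onset_lag_s = c(1.0, 1.2, 0.9, 1.1, 2.0, 2.2, 1.9, 2.1),
    peak_amp_mA = c(2.0, 2.1, 1.9, 2.2, 3.0, 3.1, 2.9, 3.2),
    size_class = rep(c("S", "L"), each = 4))
  res <- feature_manova(fx, factors = "size_class",
                        response = c("onset_lag_s", "peak_amp_mA"))
  lam <- oracle_wilks(as.matrix(fx[, 1:2]), fx$size_class)
  expect_equal(res$table$wilks, lam, tolerance = 1e-10)
  expect_lt(res$table$p_value, 0.01)
})

test_that("MANOVA null and strong-effect behaviour", {
  null_ps <- vapply(1:200, function(s) with_seed(s, {
    fx <- data.frame(onset_lag_s = rnorm(40), peak_amp_mA = rnorm(40),
                     size_class = rep(c("S", "L"), each = 20))
    feature_manova(fx, factors = "size_class",
                   response = c("onset_lag_s", "peak_amp_mA"))$table$p_value
  }), numeric(1))
  expect_gt(median(null_ps), 0.3)

  sep_ps <- vapply(1:20, function(s) with_seed(s, {
    fx <- data.frame(onset_lag_s = c(rnorm(30), rnorm(30, 10)),
                     peak_amp_mA = rnorm(60),
                     size_class = rep(c("S", "L"), each = 30))
    feature_manova(fx, factors = "size_class",
                   response = c("onset_lag_s", "peak_amp_mA"))$table$p_value
  }), numeric(1))
  expect_true(all(sep_ps < 0.001))

  # collinear features are named in the singularity error
  fx <- data.frame(onset_lag_s = rnorm(20), peak_amp_mA = 0,
                   size_class = rep(c("S", "L"), each = 10))
  fx$rate_mA_per_s <- fx$onset_lag_s * 2
  expect_error(
    feature_manova(fx, factors = "size_class",
                   response = c("onset_lag_s", "peak_amp_mA",
                                "rate_mA_per_s")),
    "singular")
})

test_that("one-way ANOVA + Tukey match an explicit sums-of-squares oracle", {
  # 3 x 5 fixture
  x <- c(18.2, 20.1, 17.9, 19.6, 18.8,
         22.3, 24.0, 23.1, 22.8, 23.5,
         28.1, 27.5, 29.0, 28.4, 27.9)
  g <- rep(c("a", "b", "c"), each = 5)
  res <- anova_tukey(x, g)
  expect_equal(res$F, oracle_anova_F(x, g), tolerance = 1e-10)
  expect_equal(nrow(res$tukey), 3)
  expect_true(all(res$tukey$p_adj < 0.01))

  # null: identical distributions give uniform-ish p
  null_ps <- vapply(1:200, function(s) with_seed(s, {
    anova_tukey(rnorm(30), rep(c("a", "b", "c"), 10))$p_value
  }), numeric(1))
  expect_gt(median(null_ps), 0.3)

  # one group shifted 10 SD: its two comparisons always significant; the
  # null pair non-significant except at the nominal type-I rate
  null_pair_ns <- 0
  for (s in 1:20) {
    res <- with_seed(s, anova_tukey(c(rnorm(10), rnorm(10), rnorm(10, 10)),
                                    rep(c("a", "b", "c"), each = 10)))
    tk <- res$tukey
    expect_lt(max(tk$p_adj[grepl("c", tk$comparison)]), 0.05)
    null_pair_ns <- null_pair_ns + (tk$p_adj[tk$comparison == "b-a"] > 0.05)
  }
  expect_gte(null_pair_ns, 16)
  expect_error(anova_tukey(rep(1, 10), rep(c("a", "b"), 5)),
               "zero within-group variance")
  expect_error(anova_tukey(rnorm(5), rep("a", 5)), ">= 2 groups")
})

test_that("standard deviational ellipses recover shape and orientation", {
  # circular limit
  e <- with_seed(1, sd_ellipse(rnorm(5000), rnorm(5000)))
  expect_lt(e$semi_axes[["a"]] / e$semi_axes[["b"]], 1.1)
  expect_lt(abs(e$pearson_r), 0.05)

  # exactly collinear points degenerate to the line
  x <- 1:10
  e2 <- sd_ellipse(x, 2 * x + 1)
  expect_equal(e2$semi_axes[["b"]], 0, tolerance = 1e-10)
  expect_equal(e2$orientation, atan(2), tolerance = 1e-10)
  expect_equal(e2$pearson_r, 1)

  # r = 0.8, equal variances: major axis at 45 degrees
  e3 <- with_seed(2, {
    z <- rnorm(5000); w <- 0.8 * z + sqrt(1 - 0.8^2) * rnorm(5000)
    sd_ellipse(z, w)
  })
  expect_equal(e3$orientation, pi / 4, tolerance = 3 * pi / 180)
  # centroid equals sample means by construction
  e4 <- sd_ellipse(c(1, 2, 3), c(4, 6, 8))
  expect_equal(e4$centroid, c(2, 6))
  expect_error(sd_ellipse(1:2, 1:2), ">= 3")
  expect_error(sd_ellipse(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("ellipse overlap follows the boundary-sampling tangency rule", {
  circ <- function(cx, cy, r = 1) {
    structure(list(centroid = c(cx, cy), semi_axes = c(a = r, b = r),
                   orientation = 0), class = "sd_ellipse")
  }
  expect_false(ellipse_overlap(circ(0, 0), circ(3, 0)))
  expect_true(ellipse_overlap(circ(0, 0), circ(2, 0))) # exact tangency
  expect_true(ellipse_overlap(circ(0, 0), circ(1, 0)))
  # concentric: containment counts as overlap
  expect_true(ellipse_overlap(circ(0, 0, 2), circ(0, 0, 0.5)))
  # degenerate segment crossing a circle
  seg <- structure(list(centroid = c(0, 0), semi_axes = c(a = 2, b = 0),
                        orientation = 0), class = "sd_ellipse")
  expect_true(ellipse_overlap(seg, circ(1, 0, 0.5)))
  expect_false(ellipse_overlap(seg, circ(0, 3, 0.5)))
})

test_that("ideal observer separates separable classes and not chance data", {
  make_feats <- function(n, shift) {
    data.frame(onset_lag_s = c(rnorm(n), rnorm(n, shift), rnorm(n, 2 * shift)),
               peak_amp_mA = rnorm(3 * n),
               size_class = rep(c("S", "M", "L"), each = n))
  }
  accs <- vapply(1:20, function(s) with_seed(s, {
    tr <- make_feats(50, 10); te <- make_feats(100, 10)
    ideal_observer(tr, te, "size_class",
                   features = c("onset_lag_s", "peak_amp_mA"))$overall_accuracy
  }), numeric(1))
  expect_true(all(accs >= 0.95))

  # label-independent features: accuracy inside the chance binomial interval
  res <- with_seed(99, {
    tr <- make_feats(50, 0); te <- make_feats(100, 0)
    ideal_observer(tr, te, "size_class",
                   features = c("onset_lag_s", "peak_amp_mA"))
  })
  n <- res$n_test
  interval <- qbinom(c(0.025, 0.975), n, 1 / 3)
  k <- sum(diag(res$confusion))
  expect_gte(k, interval[1]); expect_lte(k, interval[2])
  expect_equal(res$chance, 1 / 3)
  expect_equal(sum(res$confusion), n)
  # row sums equal per-class presentation counts
  expect_equal(as.vector(rowSums(res$confusion)), rep(100, 3))

  tr <- make_feats(10, 5)
  expect_error(ideal_observer(tr[tr$size_class != "M", ], make_feats(5, 5),
                              "size_class"),
               "absent from the training set")
})

test_that("ideal observer agrees with an independent LDA on separable data", {
  skip_if_not_installed("MASS")
  dat <- with_seed(3, data.frame(
    onset_lag_s = c(rnorm(40), rnorm(40, 4)),
    peak_amp_mA = c(rnorm(40), rnorm(40, 2)),
    size_class = rep(c("S", "L"), each = 40)))
  te <- with_seed(4, data.frame(
    onset_lag_s = c(rnorm(40), rnorm(40, 4)),
    peak_amp_mA = c(rnorm(40), rnorm(40, 2)),
    size_class = rep(c("S", "L"), each = 40)))
  mine <- ideal_observer(dat, te, "size_class",
                         features = c("onset_lag_s", "peak_amp_mA"))
  ld <- MASS::lda(size_class ~ onset_lag_s + peak_amp_mA, data = dat,
                  prior = c(0.5, 0.5))
  pred <- predict(ld, te)$class
  acc_lda <- mean(pred == te$size_class)
  expect_equal(mine$overall_accuracy, acc_lda, tolerance = 0.05)
})

test_that("full-session analysis wires features, tests, and observer together", {
  s <- simulate_preset_session("S1-virtual-size", seed = 11)
  rep1 <- run_full_analysis(s)
  expect_s3_class(rep1, "analysis_report")
  expect_equal(rep1$task$chance, 1 / 3)
  expect_equal(rep1$counts$n_trials, 72)
  expect_equal(rep1$counts$n_used + rep1$counts$n_null, 72)
  # aperture at onset carries the size effect (glove scheme)
  expect_lt(rep1$anova$aperture_at_onset_deg$p_value, 0.001)
  # confusion-matrix conservation: every classified trial is counted once,
  # and train + test cover the non-null trials
  ob <- rep1$observer
  expect_equal(sum(ob$confusion), ob$n_test)
  expect_lte(ob$n_test + ob$n_null, rep1$counts$n_used)
})
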