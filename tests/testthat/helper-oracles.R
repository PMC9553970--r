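# Independent oracles used by the tests. Everything here is derived from
# first principles (closed forms, enumeration, explicit matrix arithmetic)
# and never calls the implementation path it checks.

# --- Digital Butterworth magnitude (bilinear transform, prewarped cutoff) ---
oracle_butter_gain <- function(f, fc, fs, order) {
  ratio <- tan(pi * f / fs) / tan(pi * fc / fs)
  1 / sqrt(1 + ratio^(2 * order))
}

# --- Hand-derived 2nd-order Butterworth high-pass (bilinear), run through an
# explicit difference-equation loop ---
oracle_highpass2 <- function(x, fc, fs) {
  K <- 1 / tan(pi * fc / fs)
  norm <- K^2 + sqrt(2) * K + 1
  b0 <- K^2 / norm; b1 <- -2 * b0; b2 <- b0
  a1 <- 2 * (1 - K^2) / norm
  a2 <- (K^2 - sqrt(2) * K + 1) / norm
  y <- numeric(length(x))
  xm1 <- xm2 <- ym1 <- ym2 <- 0
  for (n in seq_along(x)) {
    y[n] <- b0 * x[n] + b1 * xm1 + b2 * xm2 - a1 * ym1 - a2 * ym2
    xm2 <- xm1; xm1 <- x[n]
    ym2 <- ym1; ym1 <- y[n]
  }
  y
}

# sample-by-sample envelope chain: high-pass, 20 ms bin means, rectify
oracle_emg_envelope <- function(raw, fc = 10, fs = 2000, bin_n = 40,
                                rectify_after_average = TRUE) {
  x <- oracle_highpass2(raw, fc, fs)
  n_bins <- floor(length(x) / bin_n)
  vapply(seq_len(n_bins), function(b) {
    seg <- x[((b - 1) * bin_n + 1):(b * bin_n)]
    if (rectify_after_average) abs(mean(seg)) else mean(abs(seg))
  }, numeric(1))
}

# --- Exact upper-tail binomial by explicit enumeration (choose-based) ---
oracle_binom_upper <- function(k, n, p0) {
  if (k == 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i),
             numeric(1)))
}

# --- Wilks' lambda from explicit scatter matrices (one-way layout) ---
oracle_wilks <- function(Y, groups) {
  groups <- factor(groups)
  grand <- colMeans(Y)
  W <- matrix(0, ncol(Y), ncol(Y))
  B <- matrix(0, ncol(Y), ncol(Y))
  for (g in levels(groups)) {
    Yg <- Y[groups == g, , drop = FALSE]
    mg <- colMeans(Yg)
    W <- W + crossprod(sweep(Yg, 2, mg))
    B <- B + nrow(Yg) * tcrossprod(mg - grand)
  }
  det(W) / det(W + B)
}

# --- One-way ANOVA F from explicit sums of squares ---
oracle_anova_F <- function(x, groups) {
  groups <- factor(groups)
  grand <- mean(x)
  ssb <- sum(tapply(x, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(x, groups, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(groups) - 1
  df2 <- length(x) - nlevels(groups)
  (ssb / df1) / (ssw / df2)
}

# shared quick-simulation defaults for tests
quick_noise <- function(...) noise_config(rng_seed = 42L, ...)
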