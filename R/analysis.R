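#' Post-hoc discrimination analysis
#'
#' Per-trial stimulation-feature extraction, exact binomial tests against
#' chance, MANOVA (Wilks' lambda) and one-way ANOVA with Tukey-HSD over the
#' features, standard deviational ellipses, and a pooled-covariance
#' nearest-centroid ideal observer producing confusion matrices.
#'
#' The four per-trial features mirror the stimulation dynamics a subject
#' could attend to: the lag between grasp-command onset and stimulation
#' onset, the peak stimulation amplitude, the rate of change of stimulation
#' from onset to first peak, and the (glove or prosthetic) hand aperture at
#' stimulation onset.
#'
#' @name analysis
NULL

FEATURE_COLS <- c("onset_lag_s", "peak_amp_mA", "rate_mA_per_s",
                  "aperture_at_onset_deg")

#' Extract the per-trial stimulation features
#'
#' Command onset is the first threshold crossing of the normalized envelope
#' (EMG scheme) or the first sample whose aperture velocity drops below
#' `-vel_eps` (glove scheme). Stimulation onset is the first sample with
#' positive commanded amplitude. The first peak is the first sample at which
#' a short moving average of the amplitude reaches `peak_frac` of its
#' maximum (robust against sensor-noise ripple on ramp-then-plateau
#' profiles); `rate_method = "regression"` instead fits a least-squares line
#' from onset to that peak.
#'
#' Trials in which stimulation never turns on yield null (NA) features with
#' a reason code, never zeros.
#'
#' @param grasp A `grasp_trace`.
#' @param stim The matching `stim_trace`.
#' @param vel_eps Glove-scheme velocity threshold, deg/s.
#' @param peak_frac Fraction of the smoothed maximum defining the first peak.
#' @param smooth_n Moving-average width (samples) used for peak finding.
#' @param rate_method `"onset_to_peak"` (default) or `"regression"`.
#' @return One-row data.frame: `onset_lag_s`, `peak_amp_mA`,
#'   `rate_mA_per_s`, `aperture_at_onset_deg`, `size_class`,
#'   `compliance_class`, `null_reason` (NA when features are defined).
#' @export
extract_features <- function(grasp, stim, vel_eps = 1, peak_frac = 0.98,
                             smooth_n = 5,
                             rate_method = c("onset_to_peak", "regression")) {
  rate_method <- match.arg(rate_method)
  ctl <- attr(grasp, "control_cfg")
  out <- data.frame(onset_lag_s = NA_real_, peak_amp_mA = NA_real_,
                    rate_mA_per_s = NA_real_,
                    aperture_at_onset_deg = NA_real_,
                    size_class = as.character(grasp$object$size_class),
                    compliance_class =
                      as.character(grasp$object$compliance_class),
                    null_reason = NA_character_,
                    stringsAsFactors = FALSE)
  null_out <- function(reason) { out$null_reason <- reason; out }

  amp <- stim$amplitude
  on_idx <- which(amp > 0)
  if (!length(on_idx)) return(null_out("no_stimulation"))
  i_on <- on_idx[1]

  # command onset
  if (!is.null(ctl) && ctl$scheme == "emg_threshold_velocity") {
    cross <- which(grasp$command >= ctl$emg_threshold)
    if (!length(cross)) return(null_out("no_command_onset"))
    i_cmd <- cross[1]
  } else {
    dt <- grasp$time[2] - grasp$time[1]
    vel <- c(0, diff(grasp$aperture)) / dt
    mov <- which(vel < -vel_eps)
    if (!length(mov)) return(null_out("no_command_onset"))
    i_cmd <- mov[1]
  }
  lag <- stim$time[i_on] - grasp$time[i_cmd]
  if (lag < 0) return(null_out("stim_before_command"))

  # first peak via smoothed amplitude
  k <- min(smooth_n, length(amp))
  sm <- as.numeric(stats::filter(amp, rep(1 / k, k), sides = 1))
  sm[seq_len(k - 1)] <- cumsum(amp[seq_len(k - 1)]) / seq_len(k - 1)
  i_pk <- which(sm >= peak_frac * max(sm))[1]
  if (i_pk < i_on) i_pk <- i_on

  peak <- max(amp)
  rate <- if (i_pk > i_on) {
    if (rate_method == "regression") {
      seg <- i_on:i_pk
      unname(stats::coef(stats::lm(amp[seg] ~ stim$time[seg]))[2])
    } else {
      (amp[i_pk] - amp[i_on]) / (stim$time[i_pk] - stim$time[i_on])
    }
  } else {
    0
  }

  out$onset_lag_s <- lag
  out$peak_amp_mA <- peak
  out$rate_mA_per_s <- rate
  out$aperture_at_onset_deg <- grasp$aperture[i_on]
  out
}

#' Feature table for a whole session
#'
#' @param session A `grasp_session` from [simulate_session()].
#' @param ... Passed to [extract_features()].
#' @return Data.frame with one row per trial (`trial_index` first), class
#'   `feature_table`.
#' @export
features_table <- function(session, ...) {
  rows <- lapply(seq_along(session), function(i) {
    cbind(trial_index = i,
          extract_features(session[[i]]$grasp, session[[i]]$stim, ...))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(trial_index = integer(0))
  }
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Exact binomial test against chance
#'
#' Upper-tail exact probability `P(X >= k | n, p0)` by direct summation of
#' the binomial mass (never a normal approximation). The upper tail matches
#' the stated null that task accuracy is no better than chance; a two-sided
#' option (minimum-likelihood rule, as in [stats::binom.test()]) is provided
#' for sensitivity analysis.
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param p0 Chance probability, in (0, 1).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A list of class `binomial_result`: `n`, `k`, `p0`, `accuracy`,
#'   `p_value`, `alternative`.
#' @export
binomial_above_chance <- function(k, n, p0,
                                  alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!is_count(k) || !is_count(n) || k > n) {
    stop("require integers 0 <= k <= n")
  }
  if (!is.numeric(p0) || length(p0) != 1 || p0 <= 0 || p0 >= 1) {
    stop("p0 must lie strictly in (0, 1)")
  }
  mass <- stats::dbinom(0:n, n, p0)
  p <- if (alternative == "greater") {
    sum(mass[(k:n) + 1])
  } else {
    # minimum-likelihood two-sided rule
    sum(mass[mass <= mass[k + 1] * (1 + 1e-7)])
  }
  structure(list(n = n, k = k, p0 = p0, accuracy = k / n,
                 p_value = min(1, p), alternative = alternative),
            class = "binomial_result")
}

#' @export
print.binomial_result <- function(x, ...) {
  cat(sprintf("exact binomial: k = %d / n = %d (accuracy %.1f%%), chance %.0f%%, p = %.4g (%s)\n",
              x$k, x$n, 100 * x$accuracy, 100 * x$p0, x$p_value,
              x$alternative))
  invisible(x)
}

#' MANOVA over stimulation features
#'
#' Multivariate analysis of variance of the feature columns on the supplied
#' factors, reporting Wilks' lambda with the standard F approximation per
#' factor. Rows with any null feature are dropped (and counted).
#'
#' @param features A feature table (e.g. from [features_table()]).
#' @param factors Factor column names (e.g. `"size_class"`,
#'   `"compliance_class"`); only factors with >= 2 observed levels enter the
#'   model.
#' @param response Feature column names to use as dependent variables.
#' @param interaction Include the factor interaction (crossed designs only).
#' @return A list of class `manova_result`: `table` (data.frame with factor,
#'   wilks, approx_F, df1, df2, p_value), `n_used`, `n_dropped`, `fit`.
#' @export
feature_manova <- function(features,
                           factors = c("size_class", "compliance_class"),
                           response = FEATURE_COLS,
                           interaction = FALSE) {
  response <- intersect(response, names(features))
  keep <- stats::complete.cases(features[, response, drop = FALSE])
  dat <- features[keep, , drop = FALSE]
  factors <- factors[vapply(factors, function(f)
    length(unique(dat[[f]])) >= 2, logical(1))]
  if (!length(factors)) stop("need at least one factor with >= 2 levels")
  for (f in factors) dat[[f]] <- factor(dat[[f]])
  if (nrow(dat) <= length(response) + prod(vapply(factors, function(f)
    nlevels(dat[[f]]), numeric(1)))) {
    stop("more observations than feature dimensions per cell are required")
  }

  Y <- as.matrix(dat[, response, drop = FALSE])
  # guard: collinear/degenerate features make the within-class scatter singular
  op <- paste(factors, collapse = if (interaction) " * " else " + ")
  fit <- stats::manova(stats::as.formula(paste("Y ~", op)), data = dat)
  R <- stats::residuals(fit)
  qrR <- qr(R)
  if (qrR$rank < ncol(Y)) {
    bad <- response[setdiff(seq_len(ncol(Y)), qrR$pivot[seq_len(qrR$rank)])]
    stop("within-class scatter is singular; collinear or constant ",
         "feature(s): ", paste(bad, collapse = ", "))
  }
  sm <- summary(fit, test = "Wilks")$stats
  terms <- setdiff(rownames(sm), "Residuals")
  tab <- data.frame(factor = terms,
                    wilks = sm[terms, "Wilks"],
                    approx_F = sm[terms, "approx F"],
                    df1 = sm[terms, "num Df"],
                    df2 = sm[terms, "den Df"],
                    p_value = sm[terms, "Pr(>F)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, n_used = nrow(dat),
                 n_dropped = sum(!keep), response = response, fit = fit),
            class = "manova_result")
}

#' One-way ANOVA with Tukey-HSD post-hoc comparisons
#'
#' @param x Numeric feature vector.
#' @param labels Group labels (>= 2 groups, >= 2 observations each after
#'   dropping NAs).
#' @return A list of class `anova_tukey_result`: `F`, `df`, `p_value`,
#'   `tukey` (data.frame comparison/diff/lwr/upr/p_adj), `group_means`.
#' @export
anova_tukey <- function(x, labels) {
  keep <- !is.na(x) & !is.na(labels)
  x <- x[keep]
  g <- factor(as.character(labels[keep]))
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (any(table(g) < 2)) stop("need >= 2 observations per group")
  if (all(tapply(x, g, stats::var) < .Machine$double.eps)) {
    stop("zero within-group variance in every group")
  }
  fit <- stats::aov(x ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  structure(list(
    F = an[["F value"]][1],
    df = c(an[["Df"]][1], an[["Df"]][2]),
    p_value = an[["Pr(>F)"]][1],
    tukey = data.frame(comparison = rownames(tk),
                       diff = tk[, "diff"], lwr = tk[, "lwr"],
                       upr = tk[, "upr"], p_adj = tk[, "p adj"],
                       row.names = NULL, stringsAsFactors = FALSE),
    group_means = tapply(x, g, mean)),
    class = "anova_tukey_result")
}

#' Standard deviational ellipse of a bivariate sample
#'
#' Centroid at the sample means; semi-axes are the square roots of the
#' eigenvalues of the 2x2 sample covariance (scaled by `scale` standard
#' deviations, default 1 SD); orientation is the angle of the major axis.
#'
#' @param x,y Coordinates (>= 3 points).
#' @param scale SD multiplier for the axes.
#' @return A list of class `sd_ellipse`: `centroid`, `semi_axes` (a >= b),
#'   `orientation` (radians in (-pi/2, pi/2]), `pearson_r`, `n`, `scale`.
#' @export
sd_ellipse <- function(x, y, scale = 1) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need >= 3 points")
  S <- stats::cov(cbind(x, y))
  if (all(S < .Machine$double.eps)) {
    stop("zero variance in both coordinates")
  }
  e <- eigen(S, symmetric = TRUE)
  a <- scale * sqrt(max(0, e$values[1]))
  b <- scale * sqrt(max(0, e$values[2]))
  v <- e$vectors[, 1]
  ang <- atan2(v[2], v[1])
  if (ang <= -pi / 2) ang <- ang + pi
  if (ang > pi / 2) ang <- ang - pi
  r <- if (stats::sd(x) > 0 && stats::sd(y) > 0) stats::cor(x, y) else NA_real_
  structure(list(centroid = c(mean(x), mean(y)), semi_axes = c(a = a, b = b),
                 orientation = ang, pearson_r = r, n = length(x),
                 scale = scale),
            class = "sd_ellipse")
}

#' Boundary points of an ellipse
#'
#' @param e An [sd_ellipse()].
#' @param n Number of boundary points.
#' @return An `n` x 2 matrix.
#' @export
ellipse_boundary <- function(e, n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  a <- e$semi_axes[["a"]]; b <- e$semi_axes[["b"]]
  R <- matrix(c(cos(e$orientation), sin(e$orientation),
                -sin(e$orientation), cos(e$orientation)), 2, 2)
  pts <- cbind(a * cos(th), b * sin(th)) %*% t(R)
  sweep(pts, 2, e$centroid, "+")
}

# quadratic form value of points relative to an ellipse (1 on the boundary);
# degenerate (b = 0) ellipses are handled by the caller
ellipse_qform <- function(pts, e) {
  a <- e$semi_axes[["a"]]; b <- e$semi_axes[["b"]]
  d <- sweep(pts, 2, e$centroid, "-")
  R <- matrix(c(cos(e$orientation), sin(e$orientation),
                -sin(e$orientation), cos(e$orientation)), 2, 2)
  loc <- d %*% R # rotate into the ellipse frame
  (loc[, 1] / a)^2 + (loc[, 2] / max(b, .Machine$double.eps))^2
}

#' Do two standard deviational ellipses overlap?
#'
#' `TRUE` iff the closed regions bounded by the two ellipses intersect;
#' boundary tangency counts as overlap. Decided by dense boundary sampling
#' (default 720 points per ellipse) with point-in-ellipse containment tests
#' (which also covers one ellipse containing the other). A degenerate
#' ellipse (`b = 0`) is treated as its major-axis segment.
#'
#' @param e1,e2 [sd_ellipse()] objects.
#' @param n Boundary samples per ellipse.
#' @param tol Numerical tolerance for the tangency rule.
#' @return Logical.
#' @export
ellipse_overlap <- function(e1, e2, n = 720, tol = 1e-9) {
  inside <- function(pts, e) any(ellipse_qform(pts, e) <= 1 + tol)
  inside(ellipse_boundary(e1, n), e2) || inside(ellipse_boundary(e2, n), e1)
}

#' Pooled-covariance nearest-centroid ideal observer
#'
#' A surrogate for the human observer: classifies each test trial to the
#' class whose training centroid is nearest in Mahalanobis distance under
#' the pooled within-class covariance (equal priors). It lower-bounds the
#' information available in the chosen feature subset; it is not a model of
#' human perception. Features with (near-)zero variance are kept via a small
#' ridge on the pooled covariance.
#'
#' @param train_features,test_features Feature tables (disjoint trial sets).
#' @param target_label `"size_class"` or `"compliance_class"`.
#' @param features Feature column names to use.
#' @param ridge Relative ridge added to the pooled covariance diagonal.
#' @return A list of class `discrimination_result`: `confusion` (K x K count
#'   table, rows = true class), `per_class_accuracy`, `overall_accuracy`,
#'   `chance`, `binomial` (per-class [binomial_above_chance()] results plus
#'   `overall`), `n_test`, `n_null`.
#' @export
ideal_observer <- function(train_features, test_features,
                           target_label = "size_class",
                           features = FEATURE_COLS,
                           ridge = 1e-6) {
  features <- intersect(features, names(train_features))
  tr_keep <- stats::complete.cases(train_features[, features, drop = FALSE])
  te_keep <- stats::complete.cases(test_features[, features, drop = FALSE])
  tr <- train_features[tr_keep, , drop = FALSE]
  te <- test_features[te_keep, , drop = FALSE]
  classes <- sort(unique(as.character(tr[[target_label]])))
  if (length(classes) < 2) stop("need >= 2 classes in the training set")
  if (!all(unique(as.character(te[[target_label]])) %in% classes)) {
    stop("test set contains a class absent from the training set")
  }
  K <- length(classes)

  Xtr <- as.matrix(tr[, features, drop = FALSE])
  Xte <- as.matrix(te[, features, drop = FALSE])
  g <- as.character(tr[[target_label]])
  centroids <- t(vapply(classes, function(cl)
    colMeans(Xtr[g == cl, , drop = FALSE]), numeric(length(features))))
  pooled <- Reduce(`+`, lapply(classes, function(cl) {
    Xc <- Xtr[g == cl, , drop = FALSE]
    crossprod(sweep(Xc, 2, colMeans(Xc)))
  })) / (nrow(Xtr) - K)
  pooled <- pooled + diag(ridge * max(mean(diag(pooled)),
                                      .Machine$double.eps),
                          ncol(pooled))
  Sinv <- solve(pooled)
  d2 <- vapply(seq_len(K), function(j) {
    d <- sweep(Xte, 2, centroids[j, ])
    rowSums((d %*% Sinv) * d)
  }, numeric(nrow(Xte)))
  if (nrow(Xte) == 1) d2 <- matrix(d2, nrow = 1)
  pred <- classes[apply(d2, 1, which.min)]
  truth <- as.character(te[[target_label]])

  confusion <- table(factor(truth, levels = classes),
                     factor(pred, levels = classes))
  per_class <- diag(confusion) / pmax(1, rowSums(confusion))
  overall <- sum(diag(confusion)) / nrow(Xte)
  chance <- 1 / K
  binom <- lapply(classes, function(cl) {
    binomial_above_chance(confusion[cl, cl], sum(confusion[cl, ]), chance)
  })
  names(binom) <- classes
  binom$overall <- binomial_above_chance(sum(diag(confusion)), nrow(Xte),
                                         chance)
  structure(list(confusion = confusion, per_class_accuracy = per_class,
                 overall_accuracy = overall, chance = chance,
                 binomial = binom, n_test = nrow(Xte),
                 n_null = sum(!te_keep), features = features),
            class = "discrimination_result")
}

#' Full post-hoc analysis of a simulated (or loaded) session
#'
#' Extracts the feature table, runs MANOVA on the varying factors, per-feature
#' one-way ANOVA with Tukey-HSD on the queried property, fits standard
#' deviational ellipses per class of the queried property for every feature
#' pair (with the pairwise overlap matrix), and evaluates the ideal observer
#' on a stratified train/test split of the session's trials.
#'
#' Null-feature trials (no stimulation) are excluded from the statistics and
#' reported in `counts`. Beyond Tukey's family-wise adjustment, no correction
#' is applied across the several ANOVAs; the report flags this.
#'
#' @param session A `grasp_session`.
#' @param observer_features Feature subset given to the ideal observer.
#' @param split Fraction of trials used for observer training.
#' @param split_seed Seed for the stratified split.
#' @param ellipse_scale SD multiplier for the ellipses.
#' @return A list of class `analysis_report` with elements `task`,
#'   `counts`, `features`, `manova`, `anova`, `ellipses`, `observer`,
#'   `notes`.
#' @export
run_full_analysis <- function(session,
                              observer_features = FEATURE_COLS,
                              split = 0.5, split_seed = 1L,
                              ellipse_scale = 1) {
  if (!length(session)) stop("no trials in session")
  sched <- attr(session, "schedule")
  queried <- sched$queried_property[1]
  target <- if (identical(queried, "compliance")) "compliance_class" else
    "size_class"
  feats <- features_table(session)
  ok <- is.na(feats$null_reason)
  if (!any(ok)) stop("all trials have null features (no stimulation)")
  fuse <- feats[ok, , drop = FALSE]

  varying <- c("size_class", "compliance_class")[
    c(length(unique(fuse$size_class)) > 1,
      length(unique(fuse$compliance_class)) > 1)]

  man <- tryCatch(feature_manova(fuse, factors = varying),
                  error = function(e) list(error = conditionMessage(e)))
  anovas <- lapply(FEATURE_COLS, function(f) {
    tryCatch(anova_tukey(fuse[[f]], fuse[[target]]),
             error = function(e) list(error = conditionMessage(e)))
  })
  names(anovas) <- FEATURE_COLS

  pairs <- utils::combn(FEATURE_COLS, 2, simplify = FALSE)
  classes <- sort(unique(as.character(fuse[[target]])))
  ellipses <- lapply(pairs, function(pr) {
    ells <- lapply(classes, function(cl) {
      sub <- fuse[fuse[[target]] == cl, , drop = FALSE]
      tryCatch(sd_ellipse(sub[[pr[1]]], sub[[pr[2]]], scale = ellipse_scale),
               error = function(e) NULL)
    })
    names(ells) <- classes
    valid <- !vapply(ells, is.null, logical(1))
    ov <- matrix(NA, length(classes), length(classes),
                 dimnames = list(classes, classes))
    for (i in seq_along(classes)) for (j in seq_along(classes)) {
      if (i != j && valid[i] && valid[j]) {
        ov[i, j] <- ellipse_overlap(ells[[i]], ells[[j]])
      }
    }
    list(features = pr, ellipses = ells, overlap = ov)
  })
  names(ellipses) <- vapply(pairs, paste, character(1), collapse = "~")

  # stratified train/test split for the observer
  idx <- with_seed(split_seed, {
    unlist(lapply(split(seq_len(nrow(fuse)), fuse[[target]]), function(ii) {
      sample(ii, max(1, floor(length(ii) * split)))
    }))
  })
  observer <- tryCatch(
    ideal_observer(fuse[idx, , drop = FALSE], fuse[-idx, , drop = FALSE],
                   target_label = target, features = observer_features),
    error = function(e) list(error = conditionMessage(e)))

  structure(list(
    task = list(queried_property = queried, target = target,
                n_classes = length(classes),
                chance = 1 / length(classes)),
    counts = list(n_trials = nrow(feats), n_used = sum(ok),
                  n_null = sum(!ok),
                  null_reasons = table(feats$null_reason[!ok])),
    features = feats, manova = man, anova = anovas, ellipses = ellipses,
    observer = observer,
    notes = paste("No multiple-testing correction applied across the",
                  "per-feature ANOVAs beyond Tukey's family-wise",
                  "adjustment.")),
    class = "analysis_report")
}
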