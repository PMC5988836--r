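#' Fitting configuration
#'
#' Controls the model-selection and optimisation behaviour of [fit_trace()].
#'
#' Pulse durations are bounded to `[6, 60]` minutes by default: the lower
#' bound keeps a pulse above the sampling floor (4 frames at 1.5-min
#' sampling) and the upper bound reflects the length of a typical recording.
#' The amplitude threshold for ERK-pulse+ classification defaults to
#' `threshold_k` times a robust estimate of the trace's noise sd (see
#' [estimate_noise_sd()]); set `amplitude_threshold` to override it with an
#' absolute value in ratio units.
#'
#' @param max_pulses Maximum number of pulses considered (>= 0).
#' @param duration_bounds Length-2 admissible pulse duration range in minutes.
#' @param amplitude_threshold Absolute classification threshold in ratio
#'   units, or `NULL` to derive it from the trace noise.
#' @param threshold_k Multiplier on the robust noise sd when
#'   `amplitude_threshold` is `NULL` (default 3).
#' @param smooth_window Number of frames of any moving average already
#'   applied to the trace (1 = unsmoothed); used to de-bias the noise
#'   estimate.
#' @param criterion Model-selection criterion: `"bic"` (default) penalises
#'   each pulse by 3 parameters, or `"sse"` accepts any pulse improving the
#'   squared error by `min_improvement`.
#' @param min_improvement Minimum fractional improvement of the flat-fit sse
#'   required to accept a pulse (numerical guard; default 1e-6).
#' @param n_seeds Residual local maxima tried as pulse seeds per round.
#' @param duration_starts Pulse durations (min) used as multi-start values
#'   for the optimiser.
#' @return A `fit_config` list.
#' @export
fit_config <- function(max_pulses = 5, duration_bounds = c(6, 60),
                       amplitude_threshold = NULL, threshold_k = 3,
                       smooth_window = 1, criterion = c("bic", "sse"),
                       min_improvement = 1e-6, n_seeds = 2,
                       duration_starts = c(10, 20, 40)) {
  criterion <- match.arg(criterion)
  if (max_pulses < 0) stop("`max_pulses` must be >= 0", call. = FALSE)
  if (length(duration_bounds) != 2L || any(duration_bounds <= 0) ||
      duration_bounds[1] >= duration_bounds[2]) {
    stop("`duration_bounds` must be positive with min < max", call. = FALSE)
  }
  if (!is.null(amplitude_threshold) && amplitude_threshold <= 0) {
    stop("`amplitude_threshold` must be > 0", call. = FALSE)
  }
  structure(list(max_pulses = as.integer(max_pulses),
                 duration_bounds = duration_bounds,
                 amplitude_threshold = amplitude_threshold,
                 threshold_k = threshold_k,
                 smooth_window = as.integer(smooth_window),
                 criterion = criterion,
                 min_improvement = min_improvement,
                 n_seeds = as.integer(n_seeds),
                 duration_starts = duration_starts),
            class = "fit_config")
}

#' Robust noise estimate for a (possibly smoothed) trace
#'
#' Estimates the sd of the additive noise carried by a trace (or a fit
#' residual) from the median absolute successive difference. For white noise
#' of sd `sigma`, successive differences have sd `sqrt(2) * sigma`; after a
#' `w`-frame moving average the smoothed noise has sd `sigma / sqrt(w)` while
#' its successive differences have sd `sqrt(2) * sigma / w`, so the estimator
#' rescales by `sqrt(w / 2) / qnorm(0.75)` to report the noise sd actually
#' present on the series given. [fit_trace()] applies it to the fit residual
#' when deriving the default classification threshold: on the trace itself
#' the differences are robust to sparse pulses but are dominated by pulse
#' slopes once pulses cover most of the recording.
#'
#' @param values Numeric trace or residual values.
#' @param smooth_window Frames of moving average already applied (1 = raw).
#' @return Estimated noise sd in ratio units.
#' @export
estimate_noise_sd <- function(values, smooth_window = 1) {
  d <- diff(values[!is.na(values)])
  if (length(d) < 3) stop("too few samples to estimate noise", call. = FALSE)
  w <- max(1, smooth_window)
  stats::median(abs(d)) * sqrt(w / 2) / stats::qnorm(0.75)
}

# --- internal: packed-parameter objective -------------------------------

# theta = c(basal, A1, t1, w1, A2, t2, w2, ...)
unpack_theta <- function(theta) {
  np <- (length(theta) - 1L) %/% 3L
  if (np == 0L) {
    return(list(basal = theta[1], amplitude = numeric(), center = numeric(),
                omega = numeric()))
  }
  m <- matrix(theta[-1], nrow = 3L)
  list(basal = theta[1], amplitude = m[1, ], center = m[2, ], omega = m[3, ])
}

fit_objective <- function(theta, t, y) {
  p <- unpack_theta(theta)
  pred <- model_values(t, p$basal, p$amplitude, p$center, p$omega)
  sum((pred - y)^2)
}

# Analytic gradient of the squared error. The max-composition model is
# piecewise smooth; at each time point only the active (maximal) pulse
# receives gradient, which is the subgradient almost everywhere.
fit_gradient <- function(theta, t, y) {
  p <- unpack_theta(theta)
  np <- length(p$amplitude)
  n <- length(t)
  if (np == 0L) {
    r <- p$basal - y
    return(2 * sum(r))
  }
  ym <- matrix(0, n, np)
  for (i in seq_len(np)) {
    s <- t - p$center[i]
    inside <- abs(s) <= pi / p$omega[i]
    ym[inside, i] <- p$amplitude[i] * (cos(p$omega[i] * s[inside]) + 1)
  }
  active <- max.col(ym, ties.method = "first")
  ymax <- ym[cbind(seq_len(n), active)]
  r <- p$basal + ymax - y
  g <- numeric(length(theta))
  g[1] <- 2 * sum(r)
  for (i in seq_len(np)) {
    rows <- which(active == i & ymax > 0)
    if (length(rows) == 0) next
    s <- t[rows] - p$center[i]
    w <- p$omega[i]
    phi <- cos(w * s) + 1
    ri <- r[rows]
    g[1 + 3 * (i - 1) + 1] <- 2 * sum(ri * phi)
    g[1 + 3 * (i - 1) + 2] <- 2 * sum(ri * p$amplitude[i] * w * sin(w * s))
    g[1 + 3 * (i - 1) + 3] <- 2 * sum(ri * p$amplitude[i] * (-sin(w * s) * s))
  }
  g
}

selection_score <- function(sse, n, n_pulses, config, sse_flat) {
  floor_sse <- max(sse, n * 1e-16, sse_flat * 1e-12)
  if (config$criterion == "bic") {
    # a w-frame moving average leaves roughly n / w independent samples;
    # using the effective size keeps the criterion calibrated on smoothed
    # traces, whose correlated noise would otherwise be over-fitted
    n_eff <- max(8, n / max(1, config$smooth_window))
    n_eff * log(floor_sse / n) + (1 + 3 * n_pulses) * log(n_eff)
  } else {
    # raw sse with a per-pulse tie-break nudge so flat wins exact ties
    floor_sse * (1 + 1e-12 * n_pulses)
  }
}

#' Fit a trace to a flat line or the multi-peak pulse model
#'
#' The core quantification step: each trace is fitted to either a flat line
#' (`y(t) = omega_0`) or the max-composition of `N` cosine pulses plus basal
#' activity, by least squares. Pulses are added greedily: each round seeds a
#' new pulse at the largest positive residual local maximum (multi-started
#' over candidate durations), all parameters are re-optimised jointly with
#' box-constrained BFGS, and the pulse is kept only while the selection
#' criterion (BIC by default) improves, up to `max_pulses`. On a criterion
#' tie the flat/simpler model wins. Pulse centres may lie up to half the
#' maximum duration outside the recording, so truncated edge pulses remain
#' representable.
#'
#' Smoothing is the caller's responsibility: pass the trace through
#' [moving_average()] first if desired, and set `smooth_window` in the config
#' accordingly so the classification threshold is calibrated to the smoothed
#' noise level.
#'
#' @param x A trace data frame (no missing values).
#' @param config A [fit_config()].
#' @return A `pulse_fit` object: list with `n_pulses`, `basal`, `pulses`
#'   ([pulse_params()] table), `sse`, `classification` (`"pulse+"` /
#'   `"pulse-"`), `threshold`, `n_obs`, `recording_duration`, `cell_id`,
#'   `condition`.
#' @export
fit_trace <- function(x, config = fit_config()) {
  validate_trace(x)
  if (!inherits(config, "fit_config"))
    stop("`config` must be a fit_config", call. = FALSE)
  if (anyNA(x$value)) {
    stop("fit_trace requires a complete trace (interpolate or drop NAs first)",
         call. = FALSE)
  }
  t <- x$time_min
  y <- x$value
  n <- length(y)
  dur_lo <- config$duration_bounds[1]
  dur_hi <- config$duration_bounds[2]
  if (diff(range(t)) < dur_lo) {
    stop("trace shorter than the minimum pulse duration", call. = FALSE)
  }
  w_lo <- 2 * pi / dur_hi
  w_hi <- 2 * pi / dur_lo
  t_lo <- min(t) - dur_hi / 2
  t_hi <- max(t) + dur_hi / 2
  rng <- max(diff(range(y)), 1e-8)
  a_hi <- 5 * rng

  basal0 <- mean(y)
  sse_flat <- sum((y - basal0)^2)

  refit <- function(theta0, lower, upper) {
    res <- try(stats::optim(theta0, fit_objective, gr = fit_gradient,
                            t = t, y = y, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = 200)), silent = TRUE)
    if (inherits(res, "try-error")) return(NULL)
    res
  }

  # Grow the model greedily (one pulse per round, seeded at the largest
  # positive residual local maxima), keeping the best fit for every pulse
  # count up to max_pulses; the reported count is the one with the best
  # selection score. Growth never stops early on a score worsening: with
  # several unmodelled pulses the flat line sits high, so early additions
  # gain little until the later ones are in place.
  thetas <- list(basal0)
  sses <- sse_flat
  scores <- selection_score(sse_flat, n, 0, config, sse_flat)
  np <- 0L
  durs <- unique(pmin(pmax(config$duration_starts, dur_lo), dur_hi))
  while (np < config$max_pulses) {
    cur_theta <- thetas[[np + 1L]]
    p <- unpack_theta(cur_theta)
    pred <- model_values(t, p$basal, p$amplitude, p$center, p$omega)
    res <- y - pred
    # positive local maxima of the residual; the endpoints count as
    # one-sided maxima so edge-truncated pulses can be seeded
    cand <- which(res > 0)
    cand <- cand[(cand == 1 | res[cand] >= res[pmax(cand - 1, 1)]) &
                   (cand == n | res[cand] >= res[pmin(cand + 1, n)])]
    if (length(cand) == 0) break
    cand <- cand[order(res[cand], decreasing = TRUE)]
    cand <- cand[seq_len(min(config$n_seeds, length(cand)))]

    lower <- c(-Inf, rep(c(0, t_lo, w_lo), np + 1))
    upper <- c(Inf, rep(c(a_hi, t_hi, w_hi), np + 1))

    best_cand <- NULL
    for (ci in cand) {
      for (d0 in durs) {
        theta0 <- c(cur_theta, max(res[ci] / 2, 1e-6), t[ci], 2 * pi / d0)
        opt <- refit(theta0, lower, upper)
        if (!is.null(opt) &&
            (is.null(best_cand) || opt$value < best_cand$value)) {
          best_cand <- opt
        }
      }
    }
    # continuity start: previous optimum plus a vanishing pulse, so the
    # best (N+1)-pulse sse can never exceed the best N-pulse sse
    theta0 <- c(cur_theta, 1e-9, t[cand[1]], 2 * pi / durs[1])
    opt <- refit(theta0, lower, upper)
    if (!is.null(opt) && (is.null(best_cand) || opt$value < best_cand$value)) {
      best_cand <- opt
    }
    if (is.null(best_cand)) break
    if ((sses[np + 1L] - best_cand$value) <=
        config$min_improvement * max(sse_flat, n * 1e-16)) {
      break    # numerically negligible gain: the model is saturated
    }
    np <- np + 1L
    thetas[[np + 1L]] <- best_cand$par
    sses[np + 1L] <- min(best_cand$value, sses[np])
    scores[np + 1L] <- selection_score(sses[np + 1L], n, np, config,
                                       sse_flat)
    if (sses[np + 1L] < 1e-10 * max(sse_flat, n * 1e-16)) break
  }
  sel <- which.min(scores + 1e-9 * seq_along(scores))  # ties favour fewer
  best_theta <- thetas[[sel]]
  best_sse <- sses[sel]

  p <- unpack_theta(best_theta)
  keep <- p$amplitude > 1e-9 * max(1, rng)
  pulses <- pulse_params(p$amplitude[keep], p$center[keep], p$omega[keep])
  basal <- p$basal
  if (nrow(pulses) == 0L && np > 0L) {
    # every accepted pulse shrank to zero: fall back to the flat fit
    basal <- basal0
    best_sse <- sse_flat
  }
  threshold <- config$amplitude_threshold
  if (is.null(threshold)) {
    # estimate the trace's noise from the fit residual: in pulse-dense
    # traces the raw successive differences are dominated by pulse slopes
    # and would inflate the threshold several-fold
    resid <- y - model_values(t, basal, pulses$amplitude, pulses$center,
                              pulses$omega)
    threshold <- config$threshold_k *
      estimate_noise_sd(resid, config$smooth_window)
  }
  fit <- structure(list(n_pulses = nrow(pulses), basal = basal,
                        pulses = pulses, sse = best_sse,
                        classification = NA_character_,
                        threshold = threshold, n_obs = n,
                        recording_duration = diff(range(t)),
                        cell_id = if ("cell_id" %in% names(x))
                          x$cell_id[1] else NA_character_,
                        condition = if ("condition" %in% names(x))
                          x$condition[1] else NA_character_),
                   class = "pulse_fit")
  fit$classification <- classify_cell(fit, threshold)
  fit
}

#' @export
print.pulse_fit <- function(x, ...) {
  cat("Pulse-model fit:", x$n_pulses, "pulse(s),",
      x$classification, "\n")
  cat("  basal activity:", signif(x$basal, 4),
      "  sse:", signif(x$sse, 4),
      "  threshold:", signif(x$threshold, 4), "\n")
  if (x$n_pulses > 0) {
    print(x$pulses, row.names = FALSE)
  }
  invisible(x)
}

#' Classify a cell as ERK-pulse+ or ERK-pulse-
#'
#' A cell is ERK-pulse+ when its fitted multi-peak model contains at least
#' one pulse whose amplitude exceeds the threshold; cells fitted by the flat
#' line, or with only sub-threshold pulses, are ERK-pulse-.
#'
#' @param fit A `pulse_fit`.
#' @param threshold Amplitude threshold in ratio units (> 0); defaults to the
#'   threshold stored in the fit.
#' @return `"pulse+"` or `"pulse-"`.
#' @export
classify_cell <- function(fit, threshold = fit$threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop("`threshold` must be a single nonnegative number", call. = FALSE)
  }
  if (fit$n_pulses == 0L) return("pulse-")
  if (max(fit$pulses$amplitude) > threshold) "pulse+" else "pulse-"
}

#' Pulse metrics from a fit
#'
#' @param fit A `pulse_fit`.
#' @param recording_duration Recording length in minutes (> 0); defaults to
#'   the span of the fitted trace.
#' @return A list with `frequency_per_h` (`N / duration`, per hour),
#'   `durations_min` (`2 * pi / omega_i` per pulse), `amplitudes` (the model
#'   amplitudes `A_i`) and `peak_heights` (`2 * A_i`, the rise of each pulse
#'   peak above basal — reported separately because "amplitude" in published
#'   summaries can mean either).
#' @export
pulse_metrics <- function(fit, recording_duration = fit$recording_duration) {
  if (!is.numeric(recording_duration) || recording_duration <= 0) {
    stop("`recording_duration` must be > 0", call. = FALSE)
  }
  list(frequency_per_h = fit$n_pulses / recording_duration * 60,
       durations_min = fit$pulses$duration,
       amplitudes = fit$pulses$amplitude,
       peak_heights = 2 * fit$pulses$amplitude)
}

#' Fit every cell of a trace table
#'
#' @param x Long trace table (`cell_id`, `time_min`, `value`, optional
#'   `condition`).
#' @param config A [fit_config()].
#' @param smooth_window_min Optional moving-average span (minutes) applied to
#'   each trace before fitting; the config's `smooth_window` is updated to
#'   the corresponding frame count automatically.
#' @return Named list of `pulse_fit` objects (one per cell).
#' @export
fit_population <- function(x, config = fit_config(),
                           smooth_window_min = NULL) {
  traces <- split_traces(x)
  lapply(traces, function(tr) {
    if (!is.null(smooth_window_min)) {
      dt <- trace_interval(tr)
      tr <- moving_average(tr, smooth_window_min)
      config$smooth_window <- 2 * floor(smooth_window_min / 2 / dt) + 1
    }
    fit_trace(tr, config)
  })
}

#' Tabulate fits for export
#'
#' @param fits List of `pulse_fit` objects (as from [fit_population()]).
#' @return A list of two data frames: `cells` (one row per cell: `cell_id`,
#'   `condition`, `n_pulses`, `basal`, `sse`, `classification`, `threshold`,
#'   `frequency_per_h`) and `pulses` (one row per pulse: `cell_id`,
#'   `amplitude`, `peak_height`, `center`, `duration`).
#' @export
fits_to_df <- function(fits) {
  cells <- do.call(rbind, lapply(fits, function(f) {
    data.frame(cell_id = f$cell_id, condition = f$condition,
               n_pulses = f$n_pulses, basal = f$basal, sse = f$sse,
               classification = f$classification, threshold = f$threshold,
               frequency_per_h = f$n_pulses / f$recording_duration * 60)
  }))
  rownames(cells) <- NULL
  pulses <- do.call(rbind, lapply(fits, function(f) {
    if (f$n_pulses == 0L) return(NULL)
    data.frame(cell_id = f$cell_id, amplitude = f$pulses$amplitude,
               peak_height = 2 * f$pulses$amplitude,
               center = f$pulses$center, duration = f$pulses$duration)
  }))
  if (!is.null(pulses)) rownames(pulses) <- NULL
  list(cells = cells,
       pulses = if (is.null(pulses)) {
         data.frame(cell_id = character(), amplitude = numeric(),
                    peak_height = numeric(), center = numeric(),
                    duration = numeric())
       } else {
         pulses
       })
}
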