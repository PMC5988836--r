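#' Specification of a stochastic pulse train
#'
#' Describes how spontaneously generated ERK pulses are drawn for one cell:
#' pulse timing follows a homogeneous Poisson process (the observed pulses are
#' sporadic, with no periodicity in their autocorrelation) thinned by a hard
#' refractory period, and amplitudes/durations are Gaussian draws truncated to
#' the model's admissible ranges.
#'
#' @param rate Expected pulses per hour (>= 0), before refractory thinning.
#' @param amplitude_mean,amplitude_sd Mean and sd of pulse amplitude `A_i` in
#'   ratio units; negative draws are truncated to 0.
#' @param duration_mean,duration_sd Mean and sd of pulse duration in minutes
#'   (mean > 0); draws are floored at a small positive value.
#' @param refractory Minimum separation between pulse centres in minutes
#'   (>= 0).
#' @return A `pulse_train_spec` list.
#' @export
pulse_train_spec <- function(rate = 2, amplitude_mean = 0.15,
                             amplitude_sd = 0.05, duration_mean = 20,
                             duration_sd = 5, refractory = 10) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate < 0)
    stop("`rate` must be a single number >= 0 (pulses per hour)",
         call. = FALSE)
  if (amplitude_mean < 0) stop("`amplitude_mean` must be >= 0", call. = FALSE)
  if (duration_mean <= 0) stop("`duration_mean` must be > 0", call. = FALSE)
  if (refractory < 0) stop("`refractory` must be >= 0", call. = FALSE)
  if (amplitude_sd < 0 || duration_sd < 0)
    stop("spread parameters must be >= 0", call. = FALSE)
  structure(list(rate = rate, amplitude_mean = amplitude_mean,
                 amplitude_sd = amplitude_sd, duration_mean = duration_mean,
                 duration_sd = duration_sd, refractory = refractory),
            class = "pulse_train_spec")
}

#' Specification of a sampled recording
#'
#' Defaults mirror a typical time-lapse session: 90-minute recordings sampled
#' every 1.5 minutes.
#'
#' @param basal Ground-truth basal activity `omega_0` in ratio units (> 0).
#' @param noise_sd Additive Gaussian noise sd on the ratio (>= 0). No noise
#'   magnitude is measurable from published traces, so this is a free fixture
#'   parameter; the default 0.02 gives pulses of typical amplitude a peak
#'   signal-to-noise around 15.
#' @param duration Recording length in minutes (> 0).
#' @param interval Sampling interval in minutes (> 0); at least 4 frames are
#'   required.
#' @return A `trace_spec` list.
#' @export
trace_spec <- function(basal = 1, noise_sd = 0.02, duration = 90,
                       interval = 1.5) {
  if (basal <= 0) stop("`basal` must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (duration <= 0 || interval <= 0)
    stop("`duration` and `interval` must be > 0", call. = FALSE)
  if (duration / interval < 4)
    stop("recording must span at least 4 sampling intervals", call. = FALSE)
  structure(list(basal = basal, noise_sd = noise_sd, duration = duration,
                 interval = interval), class = "trace_spec")
}

#' Specification of a propagating-wave scene
#'
#' Cells on a regular grid; one or more source cells fire a triggered pulse
#' and recruit their 4-neighbours, each hop adding a fixed onset delay, so a
#' wave travels at `spacing / hop_lag` micrometres per minute. Each cell is
#' recruited at most once (a single outward wave, no re-triggering).
#'
#' @param rows,cols Grid dimensions (>= 1).
#' @param spacing Centroid spacing in micrometres (> 0).
#' @param wave_sources Integer indices (row-major, 1-based) of source cells.
#' @param hop_lag Onset delay per neighbour hop in minutes (> 0).
#' @param trigger_prob Probability that each neighbour is recruited (0-1).
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(rows, cols, spacing = 20, wave_sources = 1L,
                       hop_lag = 2, trigger_prob = 1) {
  if (rows < 1 || cols < 1) stop("grid must be nonempty", call. = FALSE)
  if (spacing <= 0) stop("`spacing` must be > 0", call. = FALSE)
  if (hop_lag <= 0) stop("`hop_lag` must be > 0", call. = FALSE)
  if (trigger_prob < 0 || trigger_prob > 1)
    stop("`trigger_prob` must be in [0, 1]", call. = FALSE)
  n <- rows * cols
  wave_sources <- as.integer(wave_sources)
  if (length(wave_sources) < 1 || any(wave_sources < 1 | wave_sources > n))
    stop("`wave_sources` must index cells in the grid", call. = FALSE)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 spacing = spacing, wave_sources = wave_sources,
                 hop_lag = hop_lag, trigger_prob = trigger_prob),
            class = "scene_spec")
}

#' Specification of a condition effect
#'
#' Encodes how a treatment reshapes pulse dynamics relative to control:
#' `rate_multiplier` scales the pulse rate (an EGFR-inhibitor-like effect
#' suppresses pulses) and `basal_multiplier` scales basal activity (an
#' ErbB2-inhibitor-like effect lowers the sustained component).
#'
#' @param name Condition label.
#' @param rate_multiplier,basal_multiplier Nonnegative scale factors.
#' @return A `condition_effect` list.
#' @export
condition_effect <- function(name, rate_multiplier = 1, basal_multiplier = 1) {
  if (rate_multiplier < 0 || basal_multiplier < 0)
    stop("multipliers must be >= 0", call. = FALSE)
  structure(list(name = as.character(name),
                 rate_multiplier = rate_multiplier,
                 basal_multiplier = basal_multiplier),
            class = "condition_effect")
}

#' Draw a ground-truth pulse train
#'
#' Pulse count is Poisson with mean `rate * duration / 60`; centres are
#' uniform on `[0, duration]`, then thinned left-to-right so consecutive
#' centres are at least `refractory` minutes apart. Amplitudes are Gaussian
#' draws truncated at 0; durations are Gaussian draws floored at a small
#' positive value and converted to angular frequency `omega = 2 * pi /
#' duration`.
#'
#' @param spec A [pulse_train_spec()].
#' @param duration Recording length in minutes (> 0).
#' @param seed Optional integer seed; identical seeds give identical trains.
#' @return A [pulse_params()] data frame (possibly zero rows).
#' @export
generate_pulse_train <- function(spec, duration, seed = NULL) {
  if (!inherits(spec, "pulse_train_spec"))
    stop("`spec` must be a pulse_train_spec", call. = FALSE)
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("`duration` must be a single positive number (minutes)",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1, spec$rate * duration / 60)
  if (n == 0) return(pulse_params())
  centers <- sort(stats::runif(n, 0, duration))
  if (spec$refractory > 0 && n > 1) {
    keep <- logical(n)
    last <- -Inf
    for (i in seq_len(n)) {
      if (centers[i] - last >= spec$refractory) {
        keep[i] <- TRUE
        last <- centers[i]
      }
    }
    centers <- centers[keep]
  }
  m <- length(centers)
  if (m == 0) return(pulse_params())
  amp <- pmax(0, stats::rnorm(m, spec$amplitude_mean, spec$amplitude_sd))
  dur <- pmax(1e-3, stats::rnorm(m, spec$duration_mean, spec$duration_sd))
  pulse_params(amplitude = amp, center = centers, omega = 2 * pi / dur)
}

#' Simulate a noisy single-cell trace from a pulse train
#'
#' Evaluates the max-composition pulse model at the sampling grid and adds
#' independent Gaussian noise. The generating parameters travel with the
#' trace as the `ground_truth` attribute.
#'
#' @param train A [pulse_params()] data frame (the ground-truth pulses).
#' @param tspec A [trace_spec()].
#' @param seed Optional integer seed.
#' @param cell_id,condition Optional labels attached to the trace.
#' @return A trace data frame with attribute `ground_truth` (a list with
#'   `basal`, `pulses` and `noise_sd`).
#' @export
generate_trace <- function(train, tspec, seed = NULL, cell_id = NULL,
                           condition = NULL) {
  if (!inherits(tspec, "trace_spec"))
    stop("`tspec` must be a trace_spec", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, tspec$duration, by = tspec$interval)
  clean <- model_values(tt, tspec$basal, train$amplitude, train$center,
                        train$omega)
  noisy <- clean + stats::rnorm(length(tt), 0, tspec$noise_sd)
  out <- trace(tt, noisy, cell_id = cell_id, condition = condition)
  attr(out, "ground_truth") <- list(basal = tspec$basal, pulses = train,
                                    noise_sd = tspec$noise_sd)
  out
}

#' Simulate a condition-labelled population of traces
#'
#' Generates `n_cells` traces for a control condition and for each listed
#' effect, with the effect's multipliers applied to the pulse rate and basal
#' activity. Everything is drawn from one seeded stream, so a given seed
#' reproduces the population exactly.
#'
#' @param n_cells Cells per condition (>= 1).
#' @param train A [pulse_train_spec()] for the control condition.
#' @param tspec A [trace_spec()] for the control condition.
#' @param effects List of [condition_effect()]s (may be empty: control only).
#' @param seed Optional integer seed.
#' @return A list with `traces` (long data frame: `cell_id`, `condition`,
#'   `time_min`, `value`) and `truth` (per-cell data frame: `cell_id`,
#'   `condition`, `basal`, `n_pulses`, `rate`, plus a `pulses` list of
#'   ground-truth pulse tables named by cell).
#' @export
generate_population <- function(n_cells, train, tspec, effects = list(),
                                seed = NULL) {
  if (n_cells < 1) stop("`n_cells` must be >= 1", call. = FALSE)
  if (inherits(effects, "condition_effect")) effects <- list(effects)
  if (!is.null(seed)) set.seed(seed)
  conds <- c(list(condition_effect("control", 1, 1)), effects)
  traces <- list()
  truth_rows <- list()
  truth_pulses <- list()
  for (eff in conds) {
    tr_spec <- train
    tr_spec$rate <- train$rate * eff$rate_multiplier
    ts <- tspec
    ts$basal <- tspec$basal * eff$basal_multiplier
    for (i in seq_len(n_cells)) {
      id <- paste0(eff$name, "_", sprintf("%03d", i))
      pt <- generate_pulse_train(tr_spec, ts$duration)
      tr <- generate_trace(pt, ts, cell_id = id, condition = eff$name)
      traces[[id]] <- tr
      truth_rows[[id]] <- data.frame(cell_id = id, condition = eff$name,
                                     basal = ts$basal, n_pulses = nrow(pt),
                                     rate = tr_spec$rate)
      truth_pulses[[id]] <- pt
    }
  }
  list(traces = do.call(rbind, c(traces, list(make.row.names = FALSE))),
       truth = list(cells = do.call(rbind,
                                    c(truth_rows,
                                      list(make.row.names = FALSE))),
                    pulses = truth_pulses))
}

#' Simulate a propagating-wave scene on a cell grid
#'
#' Each source cell fires a triggered pulse at a random time in the first
#' half of the recording and recruits its 4-neighbours with probability
#' `trigger_prob`; every hop delays the pulse onset by `hop_lag` minutes
#' (optionally jittered), so the ground-truth propagation velocity is
#' `spacing / hop_lag` micrometres per minute. Cells can additionally carry
#' spontaneous background pulses (sporadic activity coexists with
#' propagating activity in epithelial sheets).
#'
#' @param scene A [scene_spec()].
#' @param tspec A [trace_spec()].
#' @param seed Optional integer seed.
#' @param wave_amplitude Amplitude of triggered pulses (ratio units).
#' @param wave_duration Duration of triggered pulses in minutes.
#' @param onset_jitter Gaussian sd added to each recruited onset, in minutes.
#' @param background Optional [pulse_train_spec()] for spontaneous pulses in
#'   all cells (default none).
#' @return A list with `traces` (long data frame), `positions` (`cell_id`,
#'   `x_um`, `y_um`) and `truth` (list: `onsets` data frame with `cell_id`,
#'   `onset_min`, `hops`, and `velocity` in um/min).
#' @export
generate_propagating_scene <- function(scene, tspec, seed = NULL,
                                       wave_amplitude = 0.2,
                                       wave_duration = 15,
                                       onset_jitter = 0,
                                       background = NULL) {
  if (!inherits(scene, "scene_spec"))
    stop("`scene` must be a scene_spec", call. = FALSE)
  if (!inherits(tspec, "trace_spec"))
    stop("`tspec` must be a trace_spec", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nr <- scene$rows; nc <- scene$cols
  n <- nr * nc
  idx <- seq_len(n)
  row_of <- (idx - 1L) %/% nc + 1L
  col_of <- (idx - 1L) %% nc + 1L
  positions <- data.frame(cell_id = sprintf("cell_%03d", idx),
                          x_um = (col_of - 1) * scene$spacing,
                          y_um = (row_of - 1) * scene$spacing)

  # breadth-first recruitment over 4-neighbours; each cell fires once
  onset <- rep(NA_real_, n)
  hops <- rep(NA_integer_, n)
  t0 <- stats::runif(length(scene$wave_sources), 0.1 * tspec$duration,
                     0.4 * tspec$duration)
  queue <- scene$wave_sources
  onset[queue] <- t0
  hops[queue] <- 0L
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    nbrs <- c(if (row_of[cur] > 1) cur - nc,
              if (row_of[cur] < nr) cur + nc,
              if (col_of[cur] > 1) cur - 1L,
              if (col_of[cur] < nc) cur + 1L)
    for (nb in nbrs) {
      if (is.na(onset[nb]) && stats::runif(1) <= scene$trigger_prob) {
        jit <- if (onset_jitter > 0) stats::rnorm(1, 0, onset_jitter) else 0
        onset[nb] <- onset[cur] + scene$hop_lag + jit
        hops[nb] <- hops[cur] + 1L
        queue <- c(queue, nb)
      }
    }
  }

  w_wave <- 2 * pi / wave_duration
  traces <- list()
  for (i in idx) {
    pt <- if (!is.null(background)) {
      generate_pulse_train(background, tspec$duration)
    } else {
      pulse_params()
    }
    if (!is.na(onset[i])) {
      # onset is the start of the pulse support, centre is half a duration on
      wave <- pulse_params(amplitude = wave_amplitude,
                           center = onset[i] + wave_duration / 2,
                           omega = w_wave)
      pt <- pulse_params(amplitude = c(pt$amplitude, wave$amplitude),
                         center = c(pt$center, wave$center),
                         omega = c(pt$omega, wave$omega))
    }
    traces[[i]] <- generate_trace(pt, tspec,
                                  cell_id = positions$cell_id[i])
  }
  fired <- !is.na(onset)
  list(traces = do.call(rbind, c(traces, list(make.row.names = FALSE))),
       positions = positions,
       truth = list(onsets = data.frame(cell_id = positions$cell_id[fired],
                                        onset_min = onset[fired],
                                        hops = hops[fired]),
                    velocity = scene$spacing / scene$hop_lag))
}

#' Render a synthetic two-channel movie from traces
#'
#' Paints each cell as a disk of constant CFP intensity; the FRET channel is
#' CFP times the cell's current ratio value, so that ratio imaging followed by
#' trace extraction recovers the input traces. A uniform background offset and
#' optional Gaussian intensity noise are added to both channels.
#'
#' @param traces Long trace table (`cell_id`, `time_min`, `value`).
#' @param positions Data frame `cell_id`, `x_um`, `y_um` (micrometres).
#' @param pixel_size Micrometres per pixel.
#' @param radius_um Nucleus radius in micrometres (> 0); nuclei must not
#'   overlap, so ROI ground truth stays unambiguous.
#' @param cfp_level CFP intensity inside each nucleus (arbitrary units).
#' @param background Uniform offset added to both channels.
#' @param noise_sd Gaussian intensity noise sd added to both channels.
#' @param margin_um Blank margin around the outermost nuclei.
#' @param interval Frame interval in minutes (taken from the trace times by
#'   default).
#' @param seed Optional integer seed (noise only).
#' @return A list with `stack` (an [image_stack()]) and `mask` (a
#'   [label_mask()]); mask label `i` corresponds to `levels(cell_id)[i]`, and
#'   the mapping is in `attr(mask, "cell_ids")`.
#' @export
render_movie <- function(traces, positions, pixel_size = 1, radius_um = 5,
                         cfp_level = 1000, background = 0, noise_sd = 0,
                         margin_um = 10, interval = NULL, seed = NULL) {
  if (radius_um <= 0) stop("`radius_um` must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  times <- sort(unique(traces$time_min))
  if (is.null(interval)) {
    interval <- if (length(times) > 1) mean(diff(times)) else 1
  }
  if (length(times) == 0) times <- 0   # zero cells: one background frame
  n <- nrow(positions)
  if (n >= 2) {
    d <- as.matrix(stats::dist(positions[, c("x_um", "y_um")]))
    diag(d) <- Inf
    if (min(d) < 2 * radius_um) {
      stop("nuclei overlap: reduce `radius_um` or spread positions",
           call. = FALSE)
    }
  }
  x0 <- if (n > 0) min(positions$x_um) - margin_um else 0
  y0 <- if (n > 0) min(positions$y_um) - margin_um else 0
  wid <- if (n > 0) diff(range(positions$x_um)) + 2 * margin_um else
    2 * margin_um
  hei <- if (n > 0) diff(range(positions$y_um)) + 2 * margin_um else
    2 * margin_um
  nx <- max(4L, ceiling(wid / pixel_size))
  ny <- max(4L, ceiling(hei / pixel_size))
  px_x <- x0 + (seq_len(nx) - 0.5) * pixel_size
  px_y <- y0 + (seq_len(ny) - 0.5) * pixel_size

  labels <- matrix(0L, ny, nx)
  for (i in seq_len(n)) {
    dx <- outer(rep(1, ny), (px_x - positions$x_um[i])^2)
    dy <- outer((px_y - positions$y_um[i])^2, rep(1, nx))
    inside <- (dx + dy) <= radius_um^2
    labels[inside] <- i
  }

  nt <- length(times)
  cfp <- array(background, dim = c(nt, ny, nx))
  fret <- array(background, dim = c(nt, ny, nx))
  tr_split <- if (n > 0) split_traces(traces) else list()
  ids <- as.character(positions$cell_id)
  for (t_i in seq_len(nt)) {
    cfp_f <- matrix(background, ny, nx)
    fret_f <- matrix(background, ny, nx)
    for (i in seq_len(n)) {
      tr <- tr_split[[ids[i]]]
      v <- tr$value[match(times[t_i], tr$time_min)]
      sel <- labels == i
      cfp_f[sel] <- cfp_level + background
      fret_f[sel] <- cfp_level * v + background
    }
    if (noise_sd > 0) {
      cfp_f <- cfp_f + matrix(stats::rnorm(ny * nx, 0, noise_sd), ny, nx)
      fret_f <- fret_f + matrix(stats::rnorm(ny * nx, 0, noise_sd), ny, nx)
    }
    cfp[t_i, , ] <- pmax(cfp_f, 0)
    fret[t_i, , ] <- pmax(fret_f, 0)
  }
  mask <- label_mask(labels)
  attr(mask, "cell_ids") <- ids
  list(stack = image_stack(cfp, fret, pixel_size = pixel_size,
                           interval = interval),
       mask = mask)
}
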