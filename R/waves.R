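#' Pulse onsets from fitted traces
#'
#' The onset of each fitted pulse is taken as the start of its support,
#' `center - pi / omega` (half a duration before the peak); the alternative
#' half-maximum definition is `center - pi / (2 * omega)`.
#'
#' @param fits List of `pulse_fit` objects.
#' @param definition `"support"` (default) or `"half_max"`.
#' @return Data frame `cell_id`, `onset_min`, `amplitude`.
#' @export
pulse_onsets <- function(fits, definition = c("support", "half_max")) {
  definition <- match.arg(definition)
  out <- do.call(rbind, lapply(fits, function(f) {
    if (f$n_pulses == 0L) return(NULL)
    off <- if (definition == "support") pi / f$pulses$omega else
      pi / (2 * f$pulses$omega)
    data.frame(cell_id = f$cell_id,
               onset_min = f$pulses$center - off,
               amplitude = f$pulses$amplitude)
  }))
  if (is.null(out)) {
    return(data.frame(cell_id = character(), onset_min = numeric(),
                      amplitude = numeric()))
  }
  rownames(out) <- NULL
  out
}

#' Detect propagating pulse waves between adjacent cells
#'
#' A wave is a maximal chain of neighbouring cells whose pulse onsets
#' increase by `0 < delta <= max_lag` minutes per hop. Cells are neighbours
#' when their centroids lie within `neighbour_radius` (default 1.5 times the
#' median nearest-neighbour spacing). Chains are extracted greedily from the
#' directed onset graph, longest first, each pulse joining at most one wave;
#' only chains with at least `min_cells` cells are reported, so that chance
#' coincidences of sporadic pulses in two or three adjacent cells are not
#' called waves. The velocity of a wave is the total centroid path length
#' divided by the onset span.
#'
#' @param onsets Data frame `cell_id`, `onset_min` (one row per pulse), as
#'   from [pulse_onsets()] or ground truth.
#' @param positions Data frame `cell_id`, `x_um`, `y_um`.
#' @param neighbour_radius Micrometres; `NULL` for the default above.
#' @param max_lag Maximum onset delay per hop in minutes (default 3).
#' @param min_cells Minimum chain length reported (default 4).
#' @return A list: `waves` (data frame `event_id`, `n_cells`,
#'   `velocity_um_per_min`, `onset_span_min`, `path_um`) and `events` (long
#'   data frame `event_id`, `step`, `cell_id`, `onset_min`). Fewer than two
#'   positioned cells yield an empty result.
#' @export
detect_propagation <- function(onsets, positions, neighbour_radius = NULL,
                               max_lag = 3, min_cells = 4) {
  empty <- list(waves = data.frame(event_id = integer(), n_cells = integer(),
                                   velocity_um_per_min = numeric(),
                                   onset_span_min = numeric(),
                                   path_um = numeric()),
                events = data.frame(event_id = integer(), step = integer(),
                                    cell_id = character(),
                                    onset_min = numeric()))
  if (nrow(positions) < 2 || nrow(onsets) < 2) return(empty)
  if (max_lag <= 0) stop("`max_lag` must be > 0", call. = FALSE)
  if (min_cells < 2) stop("`min_cells` must be >= 2", call. = FALSE)
  pos <- positions[match(onsets$cell_id, positions$cell_id), ]
  if (anyNA(pos$x_um)) {
    stop("positions missing for some cells in `onsets`", call. = FALSE)
  }
  dmat <- as.matrix(stats::dist(positions[, c("x_um", "y_um")]))
  if (is.null(neighbour_radius)) {
    diag(dmat) <- Inf
    neighbour_radius <- 1.5 * stats::median(apply(dmat, 1, min))
    diag(dmat) <- 0
  }
  cell_idx <- match(onsets$cell_id, positions$cell_id)
  n_ev <- nrow(onsets)
  ord <- order(onsets$onset_min)
  # directed edges u -> v between neighbour cells with 0 < dt <= max_lag
  adj <- vector("list", n_ev)
  for (u in seq_len(n_ev)) {
    dt <- onsets$onset_min - onsets$onset_min[u]
    dd <- dmat[cell_idx[u], cell_idx]
    targets <- which(dt > 0 & dt <= max_lag & dd <= neighbour_radius &
                       dd > 0)
    adj[[u]] <- targets
  }

  used <- rep(FALSE, n_ev)
  waves <- list()
  events <- list()
  ev_id <- 0L
  repeat {
    # longest-path DP over the (acyclic) onset-ordered event graph
    len <- rep(1L, n_ev)
    pred <- rep(NA_integer_, n_ev)
    len[used] <- 0L
    for (u in ord) {
      if (used[u]) next
      for (v in adj[[u]]) {
        if (used[v]) next
        if (len[u] + 1L > len[v]) {
          len[v] <- len[u] + 1L
          pred[v] <- u
        }
      }
    }
    best <- which.max(len)
    if (len[best] < min_cells) break
    chain <- best
    while (!is.na(pred[chain[1]])) chain <- c(pred[chain[1]], chain)
    used[chain] <- TRUE
    ev_id <- ev_id + 1L
    ci <- cell_idx[chain]
    path <- sum(sqrt(diff(positions$x_um[ci])^2 +
                       diff(positions$y_um[ci])^2))
    span <- onsets$onset_min[chain[length(chain)]] -
      onsets$onset_min[chain[1]]
    waves[[ev_id]] <- data.frame(event_id = ev_id,
                                 n_cells = length(chain),
                                 velocity_um_per_min = path / span,
                                 onset_span_min = span, path_um = path)
    events[[ev_id]] <- data.frame(event_id = ev_id,
                                  step = seq_along(chain),
                                  cell_id = onsets$cell_id[chain],
                                  onset_min = onsets$onset_min[chain])
  }
  if (ev_id == 0L) return(empty)
  list(waves = do.call(rbind, c(waves, list(make.row.names = FALSE))),
       events = do.call(rbind, c(events, list(make.row.names = FALSE))))
}
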