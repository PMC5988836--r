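# Independent oracles, written against the model definition directly so they
# never share code with the implementation under test.

# Model value at time t for basal b and pulse table p (amplitude, center,
# omega): plain loop over pulses, max composition.
oracle_model <- function(t, b, p) {
  vapply(t, function(tt) {
    best <- 0
    for (i in seq_len(nrow(p))) {
      s <- tt - p$center[i]
      if (abs(s) <= pi / p$omega[i]) {
        best <- max(best, p$amplitude[i] * (cos(p$omega[i] * s) + 1))
      }
    }
    b + best
  }, numeric(1))
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (tie-free samples only). U = #{(i, j): a_i > b_j}.
oracle_mw_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pool <- c(a, b)
  idx <- utils::combn(n1 + n2, n1)
  u_obs <- sum(outer(a, b, ">"))
  mu <- n1 * n2 / 2
  us <- apply(idx, 2, function(ii) {
    sum(outer(pool[ii], pool[-ii], ">"))
  })
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Coarse exhaustive grid search for a single-pulse fit; basal solved in
# closed form given the pulse (LS: b = mean(y - pulse)).
oracle_grid_sse <- function(t, y) {
  best <- sum((y - mean(y))^2)
  for (A in seq(0.02, 0.3, length.out = 8)) {
    for (tc in seq(min(t), max(t), by = 3)) {
      for (d in c(8, 12, 16, 20, 28, 40)) {
        w <- 2 * pi / d
        s <- t - tc
        phi <- ifelse(abs(s) <= pi / w, cos(w * s) + 1, 0)
        pulse <- A * phi
        b <- mean(y - pulse)
        sse <- sum((y - b - pulse)^2)
        if (sse < best) best <- sse
      }
    }
  }
  best
}

# Convenience: a smoothed-trace fit config matching a 6-min moving average
# at 1.5-min sampling.
smoothed_config <- function(...) {
  cfg <- fit_config(...)
  cfg$smooth_window <- 5L
  cfg
}
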