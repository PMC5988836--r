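#' Cosine pulse basis function
#'
#' Radial basis used to model a single ERK activity pulse: one period of a
#' raised cosine, `phi(s) = cos(omega * s) + 1` for `-pi/omega <= s <= pi/omega`
#' and 0 outside that support. Its peak value is 2 (at `s = 0`), so a pulse
#' with amplitude `A` rises `2 * A` ratio units above basal activity, and the
#' pulse duration is `2 * pi / omega` minutes.
#'
#' @param s Numeric vector of times relative to the pulse centre, in minutes.
#' @param omega Angular frequency in rad/min; must be a single positive value.
#' @return Numeric vector of basis values in `[0, 2]`.
#' @examples
#' pulse_basis(0, pi / 10)           # 2 at the centre
#' pulse_basis(c(-10, 5, 10), pi / 10)
#' @export
pulse_basis <- function(s, omega) {
  if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) ||
      omega <= 0) {
    stop("`omega` must be a single positive number (rad/min)", call. = FALSE)
  }
  if (!is.numeric(s)) stop("`s` must be numeric (minutes)", call. = FALSE)
  out <- numeric(length(s))
  inside <- is.finite(s) & abs(s) <= pi / omega
  out[inside] <- cos(omega * s[inside]) + 1
  out[!is.finite(s)] <- NA_real_
  out
}

#' Construct a table of pulse parameters
#'
#' @param amplitude Pulse amplitudes `A_i` in ratio units (>= 0). The peak of a
#'   pulse lies `2 * A_i` above basal activity.
#' @param center Pulse timings `t_i` in minutes.
#' @param omega Angular frequencies in rad/min (> 0); pulse duration is
#'   `2 * pi / omega` minutes.
#' @return A `data.frame` with columns `amplitude`, `center`, `omega` and
#'   `duration`, ordered by `center`.
#' @export
pulse_params <- function(amplitude = numeric(), center = numeric(),
                         omega = numeric()) {
  n <- length(amplitude)
  if (length(center) != n || length(omega) != n) {
    stop("`amplitude`, `center` and `omega` must have equal length",
         call. = FALSE)
  }
  if (n > 0) {
    if (any(!is.finite(amplitude)) || any(amplitude < 0)) {
      stop("pulse amplitudes must be finite and >= 0", call. = FALSE)
    }
    if (any(!is.finite(omega)) || any(omega <= 0)) {
      stop("pulse angular frequencies must be finite and > 0", call. = FALSE)
    }
    if (any(!is.finite(center))) {
      stop("pulse centers must be finite", call. = FALSE)
    }
  }
  out <- data.frame(amplitude = as.numeric(amplitude),
                    center = as.numeric(center),
                    omega = as.numeric(omega))
  out$duration <- 2 * pi / out$omega
  out[order(out$center), , drop = FALSE]
}

# Vectorised model values: basal + max-composition of cosine pulses.
# amplitude/center/omega are parallel vectors (possibly length 0).
model_values <- function(t, basal, amplitude, center, omega) {
  np <- length(amplitude)
  if (np == 0L) return(rep(basal, length(t)))
  best <- numeric(length(t))   # pulses are >= 0, so 0 is the identity
  for (i in seq_len(np)) {
    s <- t - center[i]
    inside <- abs(s) <= pi / omega[i]
    if (any(inside)) {
      yi <- numeric(length(t))
      yi[inside] <- amplitude[i] * (cos(omega[i] * s[inside]) + 1)
      best <- pmax(best, yi)
    }
  }
  basal + best
}

#' Evaluate the multi-peak pulse model
#'
#' Computes `y(t) = omega_0` when there are no pulses, and
#' `y(t) = max(y_1(t), ..., y_N(t)) + omega_0` otherwise, where
#' `y_i(t) = A_i * phi_i(t - t_i)` and `phi_i` is [pulse_basis()]. Overlapping
#' pulses combine through the pointwise maximum, never the sum, so two
#' coincident unit-amplitude pulses peak at `omega_0 + 2`, not `omega_0 + 4`.
#'
#' @param fit A [pulse_fit] object, or any list with elements `basal` (a
#'   single number) and `pulses` (a data frame as returned by
#'   [pulse_params()]).
#' @param t Times at which to evaluate the model, in minutes.
#' @return Numeric vector of model values at `t`.
#' @examples
#' flat <- list(basal = 1, pulses = pulse_params())
#' evaluate_model(flat, 0:10)
#' one <- list(basal = 1, pulses = pulse_params(0.5, 45, pi / 10))
#' evaluate_model(one, c(35, 45, 55))   # 1, 2, 1
#' @export
evaluate_model <- function(fit, t) {
  if (!is.list(fit) || is.null(fit$basal) || is.null(fit$pulses)) {
    stop("`fit` must be a pulse_fit or a list with `basal` and `pulses`",
         call. = FALSE)
  }
  p <- fit$pulses
  model_values(as.numeric(t), fit$basal, p$amplitude, p$center, p$omega)
}
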