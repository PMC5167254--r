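#' Mitral-granule model parameters
#'
#' Parameters of the coupled rate dynamics
#' \deqn{\dot X = -H g_y(Y) - X/\tau_x + c \, L g_x(X) + I(t)}
#' \deqn{\dot Y = W g_x(X) - Y/\tau_y + I_c}
#' with `I(t)` the sniff drive plus a constant background. The membrane
#' potential functions `g_x`, `g_y` are two-branch saturating tanh curves
#' with unit slope at the shared threshold (see [mitral_activation()]).
#'
#' @param tau_x,tau_y Membrane time constants, ms (defaults 7).
#' @param zeta_thresh Activation threshold (default 1.0).
#' @param sx_lo,sx_hi Mitral saturation constants below/above threshold
#'   (defaults 0.14, 1.4).
#' @param sy_lo,sy_hi Granule saturation constants (defaults 0.29, 2.9).
#' @param c_gain Gain on the lateral mitral-mitral term (default 1.0).
#' @param i_background Constant background drive added to every mitral
#'   unit (default 0.1).
#' @param i_cortex Constant excitatory cortical drive to every granule
#'   unit (default 0.1).
#' @param dt Integration step, ms (default 0.1; the 7 ms time constants
#'   are then resolved by 70 steps).
#' @param diverge_bound States exceeding this magnitude abort integration
#'   with a divergence error (default 1e6).
#' @return An object of class `"bulb_params"`.
#' @export
bulb_params <- function(tau_x = 7, tau_y = 7, zeta_thresh = 1.0,
                        sx_lo = 0.14, sx_hi = 1.4,
                        sy_lo = 0.29, sy_hi = 2.9,
                        c_gain = 1.0, i_background = 0.1, i_cortex = 0.1,
                        dt = 0.1, diverge_bound = 1e6) {
  stopifnot(tau_x > 0, tau_y > 0, dt > 0,
            sx_lo > 0, sx_hi > 0, sy_lo > 0, sy_hi > 0)
  structure(list(tau_x = tau_x, tau_y = tau_y, zeta_thresh = zeta_thresh,
                 sx_lo = sx_lo, sx_hi = sx_hi, sy_lo = sy_lo, sy_hi = sy_hi,
                 c_gain = c_gain, i_background = i_background,
                 i_cortex = i_cortex, dt = dt, diverge_bound = diverge_bound),
            class = "bulb_params")
}

two_branch_tanh <- function(v, zeta, s_lo, s_hi) {
  ifelse(v < zeta,
         s_lo + s_lo * tanh((v - zeta) / s_lo),
         s_lo + s_hi * tanh((v - zeta) / s_hi))
}

#' Membrane-potential (activation) functions
#'
#' Saturating output nonlinearity of the mitral (`g_x`) and granule
#' (`g_y`) units: below the threshold `zeta` the curve is
#' `S' + S' tanh((v - zeta)/S')`, above it `S' + S tanh((v - zeta)/S)`.
#' Both branches have unit slope at the threshold, so the function is
#' continuously differentiable there, with value `S'` (0.14 for mitral,
#' 0.29 for granule units at the defaults) and range `(0, S' + S)`.
#'
#' @param x,y Internal state values (vectorized).
#' @param params A [bulb_params()].
#' @return Activation values.
#' @examples
#' mitral_activation(1.0)   # 0.14 at threshold
#' granule_activation(1.0)  # 0.29 at threshold
#' @export
mitral_activation <- function(x, params = bulb_params()) {
  two_branch_tanh(x, params$zeta_thresh, params$sx_lo, params$sx_hi)
}

#' @rdname mitral_activation
#' @export
granule_activation <- function(y, params = bulb_params()) {
  two_branch_tanh(y, params$zeta_thresh, params$sy_lo, params$sy_hi)
}

#' Time derivative of the mitral-granule state
#'
#' Evaluates the coupled rate equations at one instant. The granule->mitral
#' matrix `H` enters with a minus sign (inhibition); the granule equation
#' depends on neither `H` nor `L`.
#'
#' @param x,y Internal state vectors (mitral, granule).
#' @param syn A `"synaptic_matrices"` object.
#' @param drive Per-unit glomerular drive at this instant.
#' @param params A [bulb_params()].
#' @return List with components `dx` and `dy`.
#' @export
bulb_derivative <- function(x, y, syn, drive, params = bulb_params()) {
  stopifnot(inherits(syn, "synaptic_matrices"))
  n <- syn$geom$n_units
  stopifnot(length(x) == n, length(y) == n, length(drive) %in% c(1L, n))
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite state passed to bulb_derivative")
  }
  gx <- mitral_activation(x, params)
  gy <- granule_activation(y, params)
  dx <- as.numeric(-syn$H %*% gy) - x / params$tau_x +
    params$c_gain * as.numeric(syn$L %*% gx) + drive + params$i_background
  dy <- as.numeric(syn$W %*% gx) - y / params$tau_y + params$i_cortex
  list(dx = dx, dy = dy)
}

#' Integrate the mitral-granule dynamics
#'
#' Advances the network with a fixed-step 4th-order Runge-Kutta scheme over
#' the duration of a sniff trace, interpolating the glomerular drive
#' linearly between its samples. With `learn = TRUE` the Hebbian equation
#' for the granule->mitral weights is co-integrated on the stored support
#' of `H` (see [hebbian_derivative()]).
#'
#' @param syn A `"synaptic_matrices"` object.
#' @param sniff A [sniff_waveform()] trace; integration runs over its full
#'   time span.
#' @param params A [bulb_params()] (step size `params$dt`).
#' @param state0 Optional list with starting vectors `x`, `y` (default
#'   zeros) and optionally `t` (start time, default the sniff start).
#' @param record_stride Record every this-many steps (default 10; with
#'   `dt = 0.1` ms that is a 1 ms trace grid).
#' @param learn Co-integrate the Hebbian weight ODE (default `FALSE`).
#' @param learning A [learning_config()] supplying `eta1`, `eta2` when
#'   `learn = TRUE`.
#' @param record_y Also record the granule trace (default `FALSE`).
#' @return A `"sim_trace"`: list with `times`, `x_trace`
#'   (`n_units x n_times`), optional `y_trace`, final `x`, `y`, the final
#'   `syn` (with updated `H` when learning), and `params`.
#' @examples
#' g <- bulb_geometry(6, 4)
#' syn <- build_synapses(g, 1.5, 1.5, seed = 1)
#' mix <- mix_odorants(list(binarize_pattern(
#'   glomerular_pattern(rep(1, 24), g), 0.5)))
#' tr <- integrate_bulb(syn, sniff_waveform(mix))
#' range(tr$x_trace)
#' @export
integrate_bulb <- function(syn, sniff, params = bulb_params(), state0 = NULL,
                           record_stride = 10L, learn = FALSE,
                           learning = learning_config(), record_y = FALSE) {
  stopifnot(inherits(syn, "synaptic_matrices"), inherits(sniff, "sniff_trace"))
  n <- syn$geom$n_units
  stopifnot(nrow(sniff$drive) == n)
  record_stride <- as.integer(record_stride)
  if (is.na(record_stride) || record_stride < 1L) stop("record_stride must be >= 1")
  t0 <- sniff$times[1L]
  span <- sniff$times[length(sniff$times)] - t0
  n_steps <- as.integer(round(span / params$dt))
  if (n_steps < 1L) stop("sniff trace shorter than one integration step")
  x0 <- if (is.null(state0)) numeric(n) else state0$x
  y0 <- if (is.null(state0)) numeric(n) else state0$y
  stopifnot(length(x0) == n, length(y0) == n)

  out <- rk4_bulb_cpp(syn$H, syn$W, syn$L, sniff$drive, t0, sniff$dt,
                      params[c("tau_x", "tau_y", "zeta_thresh", "sx_lo",
                               "sx_hi", "sy_lo", "sy_hi", "c_gain",
                               "i_background", "i_cortex")],
                      t0, params$dt, n_steps, record_stride,
                      x0, y0, isTRUE(learn),
                      if (isTRUE(learn)) learning$eta1 else 0,
                      if (isTRUE(learn)) learning$eta2 else 0,
                      isTRUE(record_y), params$diverge_bound)

  syn_out <- syn
  if (isTRUE(learn)) syn_out$H@x <- out$h_values
  structure(list(times = out$times, x_trace = out$x_trace,
                 y_trace = out$y_trace, x = out$x, y = out$y,
                 syn = syn_out, params = params, resp = sniff$resp),
            class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf("Simulation trace: %d units, %d samples over [%g, %g] ms\n",
              nrow(x$x_trace), length(x$times), min(x$times), max(x$times)))
  invisible(x)
}
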