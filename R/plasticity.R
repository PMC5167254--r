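#' Hebbian learning configuration
#'
#' Settings for the reward-conditioning rule on the granule->mitral
#' weights,
#' \deqn{\dot H_{ij} = -\eta_1 H_{ij}^2 + \eta_2\, g_x(x_i)\, g_y(y_j),}
#' a quadratic weight decay balanced by an activity-product potentiation.
#' Rates are per ms, on the same clock as the network ODE.
#'
#' @param eta1 Decay rate (default 1e-5).
#' @param eta2 Potentiation rate (default 1e-3).
#' @param max_cycles Cap on conditioning respiratory cycles (default 20).
#' @param conv_tol Per-cycle relative-change tolerance declaring
#'   convergence (default 1e-2).
#' @param mask_to_existing Restrict the update to the existing synaptic
#'   support of `H`, i.e. no new synapses (default `TRUE`). With `FALSE`
#'   the support is expanded to every off-diagonal pair before learning,
#'   which densifies `H` and is practical only on small lattices.
#' @return An object of class `"learning_config"`.
#' @export
learning_config <- function(eta1 = 1e-5, eta2 = 1e-3, max_cycles = 20L,
                            conv_tol = 1e-2, mask_to_existing = TRUE) {
  stopifnot(eta1 >= 0, eta2 >= 0, conv_tol > 0, max_cycles >= 1)
  structure(list(eta1 = eta1, eta2 = eta2,
                 max_cycles = as.integer(max_cycles), conv_tol = conv_tol,
                 mask_to_existing = isTRUE(mask_to_existing)),
            class = "learning_config")
}

#' Instantaneous Hebbian weight derivative
#'
#' Evaluates `dH_ij = -eta1 H_ij^2 + eta2 gx_i gy_j` for a weight matrix
#' and activation vectors. When `cfg$mask_to_existing` is `TRUE` the
#' derivative is zeroed wherever `support` (default: the nonzero pattern
#' of `H`) is zero, so no new synapses form.
#'
#' @param H Weight matrix (dense or `Matrix` sparse).
#' @param gx_vals,gy_vals Mitral/granule activation vectors.
#' @param cfg A [learning_config()].
#' @param support Optional logical/0-1 matrix marking allowed synapses.
#' @return Matrix `dH` of the same shape as `H`.
#' @export
hebbian_derivative <- function(H, gx_vals, gy_vals, cfg = learning_config(),
                               support = NULL) {
  dH <- -cfg$eta1 * H * H + cfg$eta2 * (gx_vals %o% gy_vals)
  if (cfg$mask_to_existing) {
    if (is.null(support)) support <- H != 0
    dH <- dH * (support != 0)
  }
  dH
}

# one-cycle sniff drive; `first` selects the from-zero ramp of cycle 1
sniff_cycle <- function(mixture, resp, dt_sniff = 1, first = TRUE) {
  if (first) return(sniff_waveform(mixture, resp, n_cycles = 1L, dt = dt_sniff))
  two <- sniff_waveform(mixture, resp, n_cycles = 2L, dt = dt_sniff)
  keep <- two$times >= resp$t_exhale
  structure(list(times = two$times[keep] - resp$t_exhale,
                 drive = two$drive[, keep, drop = FALSE],
                 dt = dt_sniff, resp = resp, n_cycles = 1L),
            class = "sniff_trace")
}

#' Condition the bulb model on a rewarded odor mixture
#'
#' Simulates reward training: the rewarded mixture is presented over
#' repeated 400-ms respiratory cycles while the granule->mitral weights
#' `H` follow the Hebbian rule, co-integrated with the network dynamics
#' (RK4 on the joint system). After each cycle the convergence statistic
#' `max_ij |dH_ij| / max(H_ij, eps)` (change over the cycle, relative to
#' the cycle-end weight) is evaluated; conditioning stops when it falls
#' below `learning$conv_tol` or after `learning$max_cycles` cycles.
#'
#' The returned fit freezes the learned `H` and also scores the rewarded
#' odor itself with the frozen weights (the reference response for
#' dissimilarity evaluation).
#'
#' @param syn Initial `"synaptic_matrices"`.
#' @param mixture Rewarded odor `"mixture_input"`.
#' @param resp A [respiration_params()].
#' @param params A [bulb_params()].
#' @param learning A [learning_config()].
#' @param score_cycles Respiratory cycles simulated (with frozen weights)
#'   when scoring an odor; the last cycle is evaluated (default 2).
#' @param sniff_dt Sample spacing of the generated drive, ms (default 1;
#'   the integrator interpolates linearly in between).
#' @return An object of class `"bulb_fit"`: list with `syn` (learned),
#'   `syn0` (initial), `cycles_used`, `convergence` (per-cycle statistic),
#'   `converged`, `response` (rewarded-odor [mitral_response()] under the
#'   learned weights), `mixture`, `resp`, `params`, `learning`.
#' @seealso [predict.bulb_fit()] to score discrimination targets.
#' @export
condition_bulb <- function(syn, mixture, resp = respiration_params(),
                           params = bulb_params(),
                           learning = learning_config(),
                           score_cycles = 2L, sniff_dt = 1) {
  stopifnot(inherits(syn, "synaptic_matrices"),
            inherits(mixture, "mixture_input"))
  cl <- match.call()
  if (!learning$mask_to_existing) {
    syn$H <- expand_support(syn$H)
  }
  eps <- 1e-8
  first <- sniff_cycle(mixture, resp, sniff_dt, first = TRUE)
  later <- sniff_cycle(mixture, resp, sniff_dt, first = FALSE)
  state <- NULL
  conv <- numeric(0)
  converged <- FALSE
  cycles <- 0L
  for (cyc in seq_len(learning$max_cycles)) {
    h_start <- syn$H@x
    tr <- integrate_bulb(syn, if (cyc == 1L) first else later, params,
                         state0 = state, learn = TRUE, learning = learning)
    syn <- tr$syn
    state <- list(x = tr$x, y = tr$y)
    stat <- if (length(h_start)) {
      max(abs(syn$H@x - h_start) / pmax(syn$H@x, eps))
    } else 0
    conv <- c(conv, stat)
    cycles <- cyc
    if (stat < learning$conv_tol) { converged <- TRUE; break }
  }

  fit <- structure(
    list(syn = syn, syn0 = NULL, cycles_used = cycles, convergence = conv,
         converged = converged, response = NULL, mixture = mixture,
         resp = resp, params = params, learning = learning,
         score_cycles = as.integer(score_cycles), sniff_dt = sniff_dt,
         call = cl),
    class = "bulb_fit")
  fit$response <- score_odor(fit, mixture)
  fit
}

# simulate an odor with the fit's frozen weights and return its spatial
# mitral response (last scored cycle)
score_odor <- function(fit, mixture) {
  sniff <- sniff_waveform(mixture, fit$resp, n_cycles = fit$score_cycles,
                          dt = fit$sniff_dt)
  tr <- integrate_bulb(fit$syn, sniff, fit$params)
  mitral_response(tr, fit$resp)
}

# expand a sparse matrix's stored support to every off-diagonal entry
expand_support <- function(H) {
  n <- nrow(H)
  full <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = n - 1L),
    j = unlist(lapply(seq_len(n), function(i) setdiff(seq_len(n), i))),
    x = 0, dims = c(n, n))
  full + H
}

#' @export
print.bulb_fit <- function(x, ...) {
  cat("Hebbian-conditioned olfactory bulb model\n")
  cat(sprintf("  rewarded mixture: [%s]\n",
              paste(attr(x$mixture, "component_ids"), collapse = ", ")))
  cat(sprintf("  %d units, zeta_m = %g, zeta_g = %g, seed %d\n",
              x$syn$geom$n_units, x$syn$zeta_m, x$syn$zeta_g, x$syn$seed))
  cat(sprintf("  conditioning: %d cycle(s), %s (final statistic %.3g, tol %g)\n",
              x$cycles_used,
              if (x$converged) "converged" else "NOT converged",
              x$convergence[length(x$convergence)], x$learning$conv_tol))
  invisible(x)
}

#' @export
summary.bulb_fit <- function(object, ...) {
  h <- object$syn$H@x
  s <- as.numeric(object$response)
  out <- list(fit = object,
              h_summary = summary(h),
              response_summary = summary(s),
              n_responding = sum(s > 0))
  class(out) <- "summary.bulb_fit"
  out
}

#' @export
print.summary.bulb_fit <- function(x, ...) {
  print(x$fit)
  cat("  learned H weights:\n")
  print(x$h_summary)
  cat(sprintf("  rewarded-odor response: %d/%d responding units\n",
              x$n_responding, length(as.numeric(x$fit$response))))
  print(x$response_summary)
  invisible(x)
}

#' @export
coef.bulb_fit <- function(object, ...) object$syn$H

#' @export
fitted.bulb_fit <- function(object, ...) object$response

#' Plot the conditioning convergence curve
#'
#' Per-cycle maximum relative weight change of `H` during Hebbian
#' conditioning, on a log scale, with the convergence tolerance marked.
#'
#' @param x A `"bulb_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bulb_fit <- function(x, ...) {
  graphics::plot(seq_along(x$convergence), x$convergence, type = "b",
                 log = "y", xlab = "respiratory cycle",
                 ylab = "max relative change in H", ...)
  graphics::abline(h = x$learning$conv_tol, lty = 2)
  invisible(x)
}

#' Score discrimination-target odors against the rewarded odor
#'
#' Runs the discrimination step: each target mixture is presented to the
#' conditioned model (frozen weights), its spatial mitral response is
#' computed, and the dissimilarity index `E = 1 - r` against the rewarded
#' odor's response is reported.
#'
#' @param object A `"bulb_fit"`.
#' @param odors A single `"mixture_input"` or a (named) list of them.
#' @param ... Unused.
#' @return A data frame with columns `odor` and `E`, with the per-odor
#'   [mitral_response()] objects attached as attribute `"responses"`.
#' @export
predict.bulb_fit <- function(object, odors, ...) {
  if (inherits(odors, "mixture_input")) odors <- list(odors)
  nm <- names(odors)
  if (is.null(nm)) {
    nm <- vapply(seq_along(odors), function(k) {
      id <- attr(odors[[k]], "mixture_id")
      if (is.null(id)) paste0("odor", k) else id
    }, character(1))
  }
  responses <- lapply(odors, function(o) score_odor(object, o))
  e <- vapply(responses, function(s) dissimilarity(object$response, s), 0)
  out <- data.frame(odor = nm, E = e, row.names = NULL)
  names(responses) <- nm
  attr(out, "responses") <- responses
  out
}
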