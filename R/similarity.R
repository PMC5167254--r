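#' Time-averaged spatial mitral response
#'
#' Reduces a simulation trace to one number per mitral unit: the internal
#' state, normalized by its own per-cycle maximum, integrated over the
#' last full respiratory cycle,
#' \deqn{S_i = \int_0^{t_{exhale}} x_i(t) / \max_t x_i(t)\, dt}
#' (rectangle rule on the recorded grid, so a constant-positive trace over
#' a 400-ms cycle gives exactly 400). The per-unit normalization makes
#' `S_i` invariant to positive rescaling of the trace. Units whose maximum
#' never exceeds `guard_eps` are scored 0.
#'
#' @param trace A `"sim_trace"` spanning at least one full cycle; the last
#'   full cycle is evaluated.
#' @param resp A [respiration_params()] (defaults to the trace's own).
#' @param guard_eps Positivity guard on the per-unit maximum (default 1e-9).
#' @return A `"mitral_response"`: numeric vector of per-unit scores (ms).
#' @export
mitral_response <- function(trace, resp = NULL, guard_eps = 1e-9) {
  stopifnot(inherits(trace, "sim_trace"))
  if (is.null(resp)) resp <- trace$resp
  stopifnot(inherits(resp, "respiration_params"))
  t_end <- trace$times[length(trace$times)]
  span <- t_end - trace$times[1L]
  if (span < resp$t_exhale - 1e-9) {
    stop("trace spans less than one full respiratory cycle")
  }
  keep <- trace$times > t_end - resp$t_exhale + 1e-9 & trace$times <= t_end + 1e-9
  xs <- trace$x_trace[, keep, drop = FALSE]
  h <- diff(trace$times[1:2])
  mx <- apply(xs, 1L, max)
  s <- ifelse(mx < guard_eps, 0, rowSums(xs / ifelse(mx < guard_eps, 1, mx)) * h)
  structure(as.numeric(s), class = "mitral_response")
}

#' @export
print.mitral_response <- function(x, ...) {
  v <- as.numeric(x)
  cat(sprintf("Mitral spatial response: %d units, %d responding, range [%.3g, %.3g] ms\n",
              length(v), sum(v != 0), min(v), max(v)))
  invisible(x)
}

#' Dissimilarity index between two spatial responses
#'
#' `E = 1 - r`, with `r` the Pearson correlation between the two per-unit
#' response vectors. `E` is 0 for identical spatial patterns, 1 for
#' uncorrelated ones and 2 for perfectly anticorrelated ones.
#'
#' @param s1,s2 `"mitral_response"` objects (or plain numeric vectors) of
#'   equal length; each must have nonzero variance.
#' @return The dissimilarity index in `[0, 2]`.
#' @examples
#' dissimilarity(c(1, 2, 3), c(3, 2, 1))  # 2
#' @export
dissimilarity <- function(s1, s2) {
  s1 <- as.numeric(s1); s2 <- as.numeric(s2)
  if (length(s1) != length(s2)) stop("response vectors differ in length")
  v1 <- stats::var(s1); v2 <- stats::var(s2)
  if (!isTRUE(v1 > 0) || !isTRUE(v2 > 0)) {
    bad <- c("first", "second")[c(!isTRUE(v1 > 0), !isTRUE(v2 > 0))]
    stop("undefined correlation: zero variance in the ", paste(bad, collapse = " and "),
         " response vector")
  }
  1 - stats::cor(s1, s2)
}

#' Correlation between dissimilarity and behavioral discrimination
#'
#' Pearson correlation across odors between the model's per-odor mean
#' dissimilarity index and the observed discrimination rates, with the
#' two-sided p-value from the t statistic `r * sqrt(n-2) / sqrt(1-r^2)` on
#' `n - 2` degrees of freedom.
#'
#' @param e_means Per-odor mean dissimilarity indices (length >= 3).
#' @param rates Per-odor discrimination rates.
#' @return List with `r`, `p` and `n`.
#' @export
behavior_correlation <- function(e_means, rates) {
  e_means <- as.numeric(e_means); rates <- as.numeric(rates)
  if (length(e_means) != length(rates)) stop("input lengths differ")
  if (length(e_means) < 3L) stop("need at least 3 odors")
  if (stats::var(e_means) == 0 || stats::var(rates) == 0) {
    stop("undefined correlation: constant input vector")
  }
  ct <- stats::cor.test(e_means, rates, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(e_means))
}

#' Bonferroni-corrected pairwise comparisons of dissimilarity samples
#'
#' Welch two-sample t-tests between every pair of odors' dissimilarity
#' replicates (one value per connectivity seed), with Bonferroni
#' correction over all `choose(n_odors, 2)` pairs.
#'
#' @param samples Named list: per odor, the vector of `E` values over
#'   replicate seeds (>= 2 each).
#' @param alpha Significance level applied to the adjusted p-values
#'   (default 0.01).
#' @return Data frame with columns `odor_a`, `odor_b`, `raw_p`, `adj_p`,
#'   `significant`.
#' @export
pairwise_bonferroni <- function(samples, alpha = 0.01) {
  if (!is.list(samples) || length(samples) < 2L) stop("need at least 2 odors")
  if (any(vapply(samples, length, 1L) < 2L)) {
    stop("need at least 2 replicates per odor")
  }
  nm <- names(samples)
  if (is.null(nm)) nm <- paste0("odor", seq_along(samples))
  pairs <- utils::combn(length(samples), 2L)
  raw <- apply(pairs, 2L, function(ij) {
    a <- samples[[ij[1L]]]; b <- samples[[ij[2L]]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (isTRUE(all.equal(mean(a), mean(b)))) return(1) # identical samples
      return(0)
    }
    stats::t.test(a, b, var.equal = FALSE)$p.value
  })
  adj <- stats::p.adjust(raw, method = "bonferroni")
  data.frame(odor_a = nm[pairs[1L, ]], odor_b = nm[pairs[2L, ]],
             raw_p = raw, adj_p = adj, significant = adj < alpha)
}
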