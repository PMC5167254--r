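#' Specification for a synthetic odorant-map panel
#'
#' Describes a panel of 2-DG-style glomerular activity images: each
#' odorant activates a sparse set of smooth foci (isotropic Gaussian
#' bumps) on the standard 357 x 197 canvas, with amplitudes on the
#' z-score scale. Foci sit on lattice-cell centers so that the fraction
#' of foci shared between odorants translates directly into shared
#' supra-threshold units after lattice filtering. `overlap` is the target
#' fraction of each odorant's foci drawn from a pool common to the whole
#' panel.
#'
#' @param n_odorants Number of odorants (default 3, the conditioning
#'   study's panel size).
#' @param image_shape Image rows x columns in pixels (default
#'   `c(197, 357)`).
#' @param n_foci Activation foci per odorant (default 12).
#' @param focus_sd Gaussian focus width in pixels (default 10).
#' @param amplitude_range Focus amplitudes, z-score units, drawn uniformly
#'   (default `c(1.5, 3.5)`; with min-max normalization the 0.60 threshold
#'   then keeps the strong cores).
#' @param overlap Fraction of shared foci between odorants in `[0, 1]`
#'   (default 0.25).
#' @param seed Integer master seed for the panel.
#' @param geom Lattice geometry the maps will be filtered onto (default
#'   [bulb_geometry()]); used to place foci on cell centers.
#' @return An object of class `"synth_panel_spec"`.
#' @export
synth_spec <- function(n_odorants = 3L, image_shape = c(197L, 357L),
                       n_foci = 12L, focus_sd = 10,
                       amplitude_range = c(1.5, 3.5), overlap = 0.25,
                       seed = 1L, geom = bulb_geometry()) {
  stopifnot(n_foci >= 0, overlap >= 0, overlap <= 1, focus_sd > 0,
            length(image_shape) == 2L, inherits(geom, "bulb_geometry"),
            image_shape[1] >= geom$n_beta, image_shape[2] >= geom$n_alpha)
  structure(list(n_odorants = as.integer(n_odorants),
                 image_shape = as.integer(image_shape),
                 n_foci = as.integer(n_foci), focus_sd = focus_sd,
                 amplitude_range = amplitude_range, overlap = overlap,
                 seed = as.integer(seed), geom = geom),
            class = "synth_panel_spec")
}

# pixel centers (row, col) of every lattice cell, row-major unit order
cell_centers <- function(spec) {
  g <- spec$geom
  rg <- partition_edges(spec$image_shape[1L], g$n_beta)
  cg <- partition_edges(spec$image_shape[2L], g$n_alpha)
  rc <- vapply(seq_len(g$n_beta), function(k) mean(which(rg == k)), 0)
  cc <- vapply(seq_len(g$n_alpha), function(k) mean(which(cg == k)), 0)
  cbind(row = rc[g$beta + 1L], col = cc[g$alpha + 1L])
}

# focus cells for one odorant: shared pool (same for the whole panel,
# first n_shared) plus odorant-specific cells
focus_cells <- function(spec, odorant_index) {
  n_shared <- round(spec$overlap * spec$n_foci)
  n_units <- spec$geom$n_units
  with_seed(spec$seed, {
    pool <- sample.int(n_units, min(n_units, spec$n_foci * (spec$n_odorants + 1L)))
  })
  shared <- pool[seq_len(n_shared)]
  rest <- setdiff(seq_len(n_units), shared)
  own <- with_seed(spec$seed + 7919L * odorant_index, {
    sample(rest, spec$n_foci - n_shared)
  })
  c(shared, own)
}

with_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Generate one synthetic odorant activity map
#'
#' Sums isotropic Gaussian bumps at the odorant's focus cells (see
#' [synth_spec()]), amplitudes drawn uniformly from the spec's range, and
#' clips to the representable gray range `[0, max(amplitude_range)]`.
#' Deterministic per `(seed, odorant_index)`.
#'
#' @param spec A [synth_spec()].
#' @param odorant_index 1-based odorant index within the panel.
#' @return Numeric matrix (`image_shape`) of z-score gray levels.
#' @export
synth_odorant_map <- function(spec, odorant_index) {
  stopifnot(inherits(spec, "synth_panel_spec"))
  nr <- spec$image_shape[1L]; nc <- spec$image_shape[2L]
  img <- matrix(0, nr, nc)
  if (spec$n_foci == 0L) return(img)
  cells <- focus_cells(spec, odorant_index)
  ctr <- cell_centers(spec)[cells, , drop = FALSE]
  amps <- with_seed(spec$seed + 7919L * odorant_index + 104729L, {
    stats::runif(length(cells), spec$amplitude_range[1L], spec$amplitude_range[2L])
  })
  rr <- seq_len(nr); cc <- seq_len(nc)
  for (f in seq_along(cells)) {
    gr <- exp(-(rr - ctr[f, "row"])^2 / (2 * spec$focus_sd^2))
    gc <- exp(-(cc - ctr[f, "col"])^2 / (2 * spec$focus_sd^2))
    img <- img + amps[f] * (gr %o% gc)
  }
  pmin(img, max(spec$amplitude_range))
}

#' Generate a full synthetic odor panel
#'
#' Produces the odorant maps, passes them through the lattice filter and
#' min-max normalization, binarizes at the respiration threshold, and
#' assembles the standard odor definitions of a conditioning study: the
#' full mixture of all components is the rewarded odor and every proper
#' non-empty component subset is a discrimination target (for the default
#' 3-odorant panel: rewarded `[A,B,C]` plus targets `[A,B]`, `[A,C]`,
#' `[B,C]`, `[A]`, `[B]`, `[C]` - 7 odor definitions).
#'
#' @param spec A [synth_spec()].
#' @param theta Binarization threshold (default 0.60).
#' @return A list of class `"synth_panel"` with `patterns` (normalized
#'   [glomerular_pattern()]s), `binaries`, `mixtures` (named list of
#'   [mix_odorants()] inputs, rewarded first), `rewarded` (its name),
#'   `components` (per-odor component letters) and `spec`.
#' @export
synth_panel <- function(spec, theta = 0.60) {
  stopifnot(inherits(spec, "synth_panel_spec"), spec$n_odorants >= 2L)
  ids <- LETTERS[seq_len(spec$n_odorants)]
  patterns <- lapply(seq_len(spec$n_odorants), function(q) {
    normalize_pattern(lattice_filter(synth_odorant_map(spec, q), spec$geom,
                                     odorant_id = ids[q]))
  })
  names(patterns) <- ids
  binaries <- lapply(patterns, binarize_pattern, theta = theta)
  subsets <- unlist(lapply(seq(spec$n_odorants, 1L), function(k) {
    utils::combn(seq_len(spec$n_odorants), k, simplify = FALSE)
  }), recursive = FALSE)
  mixtures <- lapply(subsets, function(s) {
    mix_odorants(binaries[s], mixture_id = paste(ids[s], collapse = "+"))
  })
  names(mixtures) <- vapply(mixtures, attr, "", which = "mixture_id")
  structure(list(patterns = patterns, binaries = binaries,
                 mixtures = mixtures, rewarded = names(mixtures)[1L],
                 components = lapply(subsets, function(s) ids[s]),
                 spec = spec, theta = theta),
            class = "synth_panel")
}

#' @export
print.synth_panel <- function(x, ...) {
  cat(sprintf("Synthetic odor panel: %d odorants, %d odor definitions (rewarded: %s)\n",
              x$spec$n_odorants, length(x$mixtures), x$rewarded))
  invisible(x)
}

#' Synthetic behavioral discrimination rates
#'
#' Emulates a behavioral panel for recovery tests: rates are a noisy
#' affine function of the true dissimilarities, clipped to the 0-100
#' percent scale.
#'
#' @param e_true Per-odor true dissimilarity indices.
#' @param slope,intercept Affine map from dissimilarity to rate.
#' @param noise_sd Gaussian noise sd on the rate scale.
#' @param seed Integer seed.
#' @return Per-odor rates in `[0, 100]`.
#' @export
synth_behavior <- function(e_true, slope = 30, intercept = 50, noise_sd = 5,
                           seed = 1L) {
  e_true <- as.numeric(e_true)
  with_seed(seed, {
    pmin(pmax(intercept + slope * e_true +
                stats::rnorm(length(e_true), 0, noise_sd), 0), 100)
  })
}
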