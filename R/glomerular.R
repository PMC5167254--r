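#' Convert an activity-map image into per-unit glomerular input
#'
#' Partitions a grayscale activity image (2-DG style odor map) into
#' `n_alpha x n_beta` near-equal rectangular cells, one per lattice unit,
#' and assigns each unit the mean normalized pixel value of its cell.
#' Image columns map to the alpha axis and rows to the beta axis. When a
#' dimension does not divide evenly the remainder pixels are spread one per
#' cell starting from the low-index edge.
#'
#' Pixel gray levels are mapped to the activation (z-score) scale by the
#' linear map `slope * gray + intercept`; the identity default suits
#' synthetic maps already on that scale. For database images supply the
#' color-bar calibration here.
#'
#' @param image Numeric matrix of gray levels, `nrow >= n_beta` rows and
#'   `ncol >= n_alpha` columns; all values finite.
#' @param geom A [bulb_geometry()].
#' @param slope,intercept Linear gray-to-z-score map (defaults 1, 0).
#' @param odorant_id Optional label stored on the pattern.
#' @return A `"glomerular_pattern"`: numeric vector of length
#'   `geom$n_units` with attributes `odorant_id` and `geom`.
#' @examples
#' img <- matrix(runif(357 * 197), nrow = 197)
#' p <- lattice_filter(img, bulb_geometry())
#' length(p)  # 1805
#' @export
lattice_filter <- function(image, geom, slope = 1, intercept = 0,
                           odorant_id = NULL) {
  stopifnot(inherits(geom, "bulb_geometry"))
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix")
  }
  if (nrow(image) < geom$n_beta || ncol(image) < geom$n_alpha) {
    stop("image smaller than the lattice: need at least n_beta rows and n_alpha columns")
  }
  if (any(!is.finite(image))) stop("image contains non-finite pixel values")
  z <- slope * image + intercept
  row_grp <- partition_edges(nrow(image), geom$n_beta)
  col_grp <- partition_edges(ncol(image), geom$n_alpha)
  # cell means via grouped row/col sums
  sums <- rowsum(z, row_grp, reorder = TRUE)
  sums <- t(rowsum(t(sums), col_grp, reorder = TRUE))  # n_beta x n_alpha
  cnt <- tabulate(row_grp, geom$n_beta) %o% tabulate(col_grp, geom$n_alpha)
  means <- sums / cnt
  # row-major unit order: unit i at (alpha = col, beta = row)
  vals <- as.vector(t(means))
  glomerular_pattern(vals, geom, odorant_id)
}

# Assign n items to m near-equal groups; remainder goes one-per-group from
# the low-index edge. Returns a group id per item.
partition_edges <- function(n, m) {
  base <- n %/% m
  rem <- n %% m
  sizes <- rep(base, m) + c(rep(1L, rem), rep(0L, m - rem))
  rep.int(seq_len(m), sizes)
}

#' Construct a glomerular pattern from a per-unit activity vector
#'
#' Wraps a plain numeric vector (for instance read from delimited text) as
#' a `"glomerular_pattern"` tied to a lattice geometry.
#'
#' @param values Numeric vector of length `geom$n_units`, all finite.
#' @param geom A [bulb_geometry()].
#' @param odorant_id Optional label.
#' @return A `"glomerular_pattern"`.
#' @export
glomerular_pattern <- function(values, geom, odorant_id = NULL) {
  stopifnot(length(values) == geom$n_units, all(is.finite(values)))
  structure(as.numeric(values), odorant_id = odorant_id, geom = geom,
            class = "glomerular_pattern")
}

#' @export
print.glomerular_pattern <- function(x, ...) {
  id <- attr(x, "odorant_id")
  cat(sprintf("Glomerular pattern%s: %d units, range [%.3g, %.3g]\n",
              if (is.null(id)) "" else paste0(" '", id, "'"),
              length(x), min(x), max(x)))
  invisible(x)
}

#' Rescale a glomerular pattern to [0, 1]
#'
#' Min-max rescaling of a pattern's unit values, the normalization applied
#' to lattice-filtered activity maps before thresholding (the default
#' threshold 0.60 then picks out the strongly activated part of the map,
#' corresponding to a 2-DG z-score above about 2).
#'
#' @param pattern A `"glomerular_pattern"`.
#' @return The rescaled pattern. A constant pattern maps to all zeros.
#' @export
normalize_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "glomerular_pattern"))
  rng <- range(pattern)
  v <- if (diff(rng) == 0) rep(0, length(pattern)) else (pattern - rng[1]) / diff(rng)
  glomerular_pattern(v, attr(pattern, "geom"), attr(pattern, "odorant_id"))
}

#' Threshold a glomerular pattern to a binary activation map
#'
#' Applies the contrast-enhancing threshold: units at or above `theta`
#' become 1, the rest 0. The boundary is inclusive (`>= theta` -> 1).
#'
#' @param pattern A `"glomerular_pattern"`.
#' @param theta Threshold (default 0.60).
#' @return A binary `"glomerular_pattern"`.
#' @export
binarize_pattern <- function(pattern, theta = 0.60) {
  stopifnot(inherits(pattern, "glomerular_pattern"))
  glomerular_pattern(as.numeric(pattern >= theta), attr(pattern, "geom"),
                     attr(pattern, "odorant_id"))
}

#' Combine binary component patterns into an odorant-mixture input
#'
#' The peak glomerular drive of a k-component mixture is the per-unit mean
#' of the components' binary activation maps, so every unit value is a
#' multiple of `1/k` in `[0, 1]` (linear-combination assumption for mixture
#' maps).
#'
#' @param binaries List of k binary `"glomerular_pattern"`s (same length).
#' @param mixture_id Optional label.
#' @return A `"mixture_input"`: numeric vector `peaks` of per-unit maxima
#'   in `[0, 1]` with attributes `component_ids` and `geom`.
#' @export
mix_odorants <- function(binaries, mixture_id = NULL) {
  if (!is.list(binaries) || length(binaries) < 1L) {
    stop("binaries must be a non-empty list of binary patterns")
  }
  n <- length(binaries[[1L]])
  if (any(vapply(binaries, length, 1L) != n)) {
    stop("component patterns differ in length")
  }
  peaks <- Reduce(`+`, lapply(binaries, as.numeric)) / length(binaries)
  ids <- vapply(binaries, function(b) {
    id <- attr(b, "odorant_id")
    if (is.null(id)) NA_character_ else as.character(id)
  }, character(1))
  structure(peaks, component_ids = ids, mixture_id = mixture_id,
            geom = attr(binaries[[1L]], "geom"), class = "mixture_input")
}

#' @export
print.mixture_input <- function(x, ...) {
  cat(sprintf("Mixture input%s: %d components [%s], %d of %d units driven\n",
              if (is.null(attr(x, "mixture_id"))) "" else
                paste0(" '", attr(x, "mixture_id"), "'"),
              length(attr(x, "component_ids")),
              paste(attr(x, "component_ids"), collapse = ", "),
              sum(x > 0), length(x)))
  invisible(x)
}

#' Respiration (sniff) cycle parameters
#'
#' One respiratory cycle lasts `t_exhale` ms: glomerular drive ramps up
#' over the inhalation phase `[0, t_inhale]` and decays exponentially with
#' time constant `tau_exhale` during exhalation. Defaults follow the
#' rabbit-derived breath function used in rate models of the bulb:
#' `t_inhale = 220` ms, `t_exhale = 400` ms, `tau_exhale = 33` ms. The
#' binarization threshold `theta = 0.60` rides along because it defines,
#' together with the breath function, the glomerular front end.
#'
#' @param t_inhale Inhalation end, ms.
#' @param t_exhale Cycle end, ms.
#' @param tau_exhale Exhalation decay constant, ms.
#' @param theta Binarization threshold.
#' @return An object of class `"respiration_params"`.
#' @export
respiration_params <- function(t_inhale = 220, t_exhale = 400,
                               tau_exhale = 33, theta = 0.60) {
  if (!(t_inhale > 0 && t_exhale > t_inhale)) {
    stop("need 0 < t_inhale < t_exhale")
  }
  if (tau_exhale <= 0) stop("tau_exhale must be positive")
  structure(list(t_inhale = t_inhale, t_exhale = t_exhale,
                 tau_exhale = tau_exhale, theta = theta),
            class = "respiration_params")
}

#' Respiration-locked glomerular drive
#'
#' Generates the time course of glomerular input over `n_cycles`
#' respiratory cycles. Within each cycle the drive of unit i rises
#' linearly from the cycle-start value to its mixture peak `P_i` at
#' `t_inhale`, then decays exponentially with constant `tau_exhale`
#' (referenced to `t_inhale`). The trace is continuous across the phase
#' boundary and across cycles: cycle 1 starts from 0, later cycles ramp up
#' from the previous cycle's end value.
#'
#' @param mixture A `"mixture_input"` (peak drive per unit).
#' @param resp A [respiration_params()].
#' @param n_cycles Number of cycles (>= 1).
#' @param dt Sample spacing in ms (<= 1 ms recommended; drive is
#'   interpolated linearly between samples during integration).
#' @return A `"sniff_trace"`: list with `times` (ms, from 0 to
#'   `n_cycles * t_exhale`) and `drive` (`n_units x n_times` matrix).
#' @examples
#' g <- bulb_geometry(4, 3)
#' mix <- mix_odorants(list(binarize_pattern(
#'   glomerular_pattern(rep(1, 12), g), 0.5)))
#' tr <- sniff_waveform(mix, respiration_params(), n_cycles = 1, dt = 1)
#' max(tr$drive)  # 1 at t = t_inhale
#' @export
sniff_waveform <- function(mixture, resp = respiration_params(),
                           n_cycles = 1L, dt = 1) {
  stopifnot(inherits(mixture, "mixture_input"),
            inherits(resp, "respiration_params"))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  n_cycles <- as.integer(n_cycles)
  if (is.na(n_cycles) || n_cycles < 1L) stop("n_cycles must be >= 1")
  times <- seq(0, n_cycles * resp$t_exhale, by = dt)
  p <- as.numeric(mixture)
  # end-of-cycle value (start of every cycle after the first)
  tail_frac <- exp(-(resp$t_exhale - resp$t_inhale) / resp$tau_exhale)
  cyc <- pmin(floor(times / resp$t_exhale), n_cycles - 1L)  # cycle index, 0-based
  s <- times - cyc * resp$t_exhale                          # local time in (0, t_exhale]
  # t = k * t_exhale belongs to the end of cycle k (s = t_exhale), except t = 0
  at_end <- s == 0 & times > 0
  cyc[at_end] <- cyc[at_end] - 1L
  s[at_end] <- resp$t_exhale
  ramp_frac <- s / resp$t_inhale
  decay_frac <- exp(-(s - resp$t_inhale) / resp$tau_exhale)
  v0_frac <- ifelse(cyc == 0L, 0, tail_frac)
  frac <- ifelse(s <= resp$t_inhale,
                 v0_frac + (1 - v0_frac) * ramp_frac,
                 decay_frac)
  drive <- p %o% frac
  structure(list(times = times, drive = drive, dt = dt, resp = resp,
                 n_cycles = n_cycles),
            class = "sniff_trace")
}

#' @export
print.sniff_trace <- function(x, ...) {
  cat(sprintf("Sniff trace: %d units, %d samples over %g ms (dt = %g ms)\n",
              nrow(x$drive), length(x$times), max(x$times), x$dt))
  invisible(x)
}

#' Read a grayscale activity image from PNG or TIFF
#'
#' Thin wrapper over the png/tiff readers returning a numeric matrix of
#' gray levels in `[0, 1]` (multi-channel images are averaged to gray).
#'
#' @param path Image file path; format chosen by extension.
#' @return Numeric matrix (rows = image rows).
#' @export
read_activity_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE)) stop("package 'png' required")
      png::readPNG(path)
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' required")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext)
  )
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE], c(1, 2), mean)
  img
}

#' Write/read a glomerular pattern as delimited text
#'
#' Four tab-separated columns: `unit` (1-based), `alpha`, `beta` (0-based
#' lattice coordinates) and `value`.
#'
#' @param pattern A `"glomerular_pattern"`.
#' @param path File path.
#' @param geom Geometry used when reading (defaults to the standard bulb
#'   lattice).
#' @return `write_pattern` returns `path` invisibly; `read_pattern` a
#'   `"glomerular_pattern"`.
#' @export
write_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "glomerular_pattern"))
  geom <- attr(pattern, "geom")
  df <- data.frame(unit = seq_along(pattern), alpha = geom$alpha,
                   beta = geom$beta, value = as.numeric(pattern))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pattern
#' @export
read_pattern <- function(path, geom = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (is.null(geom)) {
    geom <- bulb_geometry(max(df$alpha) + 1L, max(df$beta) + 1L)
  }
  glomerular_pattern(df$value[order(df$unit)], geom)
}
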