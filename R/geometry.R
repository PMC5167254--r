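#' Lattice geometry of the bulb surface
#'
#' Places glomerular/mitral/granule unit columns on a 2-D `alpha x beta`
#' lattice wrapped on itself, the discrete stand-in for the (roughly
#' spherical) olfactory-bulb surface. Units are indexed row-major and
#' 0-based in coordinates: unit `i` (1-based R index) sits at
#' `alpha = (i - 1) %% n_alpha`, `beta = (i - 1) %/% n_alpha`.
#'
#' The default `95 x 19 = 1805` units matches the approximate number of
#' glomeruli on a mouse olfactory bulb. 1805 = 5 * 19^2 admits few integer
#' factorizations; 95 x 19 keeps the granule connection radius (default 15)
#' smaller than half the larger extent.
#'
#' @param n_alpha Number of lattice columns (alpha extent). Must be >= 2.
#' @param n_beta Number of lattice rows (beta extent). Must be >= 2.
#' @return An object of class `"bulb_geometry"`: a list with `n_alpha`,
#'   `n_beta`, `n_units`, and integer vectors `alpha`, `beta` giving each
#'   unit's 0-based coordinates.
#' @examples
#' geom <- bulb_geometry()
#' geom$n_units  # 1805
#' @export
bulb_geometry <- function(n_alpha = 95L, n_beta = 19L) {
  n_alpha <- as.integer(n_alpha)
  n_beta <- as.integer(n_beta)
  if (length(n_alpha) != 1L || length(n_beta) != 1L ||
      is.na(n_alpha) || is.na(n_beta) || n_alpha < 2L || n_beta < 2L) {
    stop("n_alpha and n_beta must be single integers >= 2")
  }
  n <- n_alpha * n_beta
  i <- seq_len(n) - 1L
  structure(
    list(n_alpha = n_alpha, n_beta = n_beta, n_units = n,
         alpha = i %% n_alpha, beta = i %/% n_alpha),
    class = "bulb_geometry"
  )
}

#' @export
print.bulb_geometry <- function(x, ...) {
  cat(sprintf("Bulb lattice geometry: %d x %d = %d units (row-major, 0-based)\n",
              x$n_alpha, x$n_beta, x$n_units))
  invisible(x)
}

# Per-axis wrapped separation: min(direct, extent - direct).
wrap_axis_dist <- function(d_direct, extent) pmin(d_direct, extent - d_direct)

#' Wrap-around distance between lattice units
#'
#' Distance on the wrapped lattice: connections that run off one edge fold
#' back to the opposite edge, emulating the closed bulb surface. In the
#' default `"torus"` mode both axes use the per-axis wrap minimum
#' `d_axis = min(|a_i - a_j|, extent - |a_i - a_j|)` and
#' `d = sqrt(d_alpha^2 + d_beta^2)`. Mode `"reflect-beta"` wraps alpha but
#' folds beta back with reflection (`extent` replaced by `2 * (n_beta - 1)`
#' mirror images), closer to a spherical cap along the short axis.
#'
#' @param geom A [bulb_geometry()].
#' @param i,j Unit indices (1-based), possibly vectors (recycled).
#' @param mode `"torus"` (default) or `"reflect-beta"`.
#' @return Non-negative distances; zero iff `i == j`.
#' @examples
#' g <- bulb_geometry(95, 19)
#' toroidal_distance(g, 1, 95)  # (0,0) to (94,0): wraps to 1
#' @export
toroidal_distance <- function(geom, i, j, mode = c("torus", "reflect-beta")) {
  mode <- match.arg(mode)
  stopifnot(inherits(geom, "bulb_geometry"))
  if (any(i < 1L | i > geom$n_units) || any(j < 1L | j > geom$n_units)) {
    stop("unit index out of range")
  }
  da <- wrap_axis_dist(abs(geom$alpha[i] - geom$alpha[j]), geom$n_alpha)
  db_direct <- abs(geom$beta[i] - geom$beta[j])
  db <- if (mode == "torus") {
    wrap_axis_dist(db_direct, geom$n_beta)
  } else {
    # reflect at both beta edges: images of beta_j at 2*(n_beta-1)*k +/- beta_j
    bi <- geom$beta[i]; bj <- geom$beta[j]; per <- 2L * (geom$n_beta - 1L)
    pmin(db_direct, abs(bi - (per - bj)), abs(bi - (-bj)))
  }
  sqrt(da^2 + db^2)
}

# Full n x n distance matrix (used by build_synapses); torus or reflect-beta.
lattice_distance_matrix <- function(geom, mode = "torus") {
  da <- outer(geom$alpha, geom$alpha, function(a, b) abs(a - b))
  da <- pmin(da, geom$n_alpha - da)
  db <- outer(geom$beta, geom$beta, function(a, b) abs(a - b))
  if (mode == "torus") {
    db <- pmin(db, geom$n_beta - db)
  } else {
    per <- 2L * (geom$n_beta - 1L)
    refl <- outer(geom$beta, geom$beta, function(a, b) pmin(abs(a - (per - b)), a + b))
    db <- pmin(db, refl)
  }
  sqrt(da^2 + db^2)
}

#' Randomized range-limited synaptic connection matrices
#'
#' Builds the three connection matrices on the unit lattice:
#' * `H` (granule -> mitral, inhibitory in the dynamics): entries
#'   `R / zeta_m` for unit pairs with `0 < d < zeta_m`;
#' * `W` (mitral -> granule): `R / zeta_g` for `0 < d < zeta_g`;
#' * `L` (mitral -> mitral, lateral excitation): `R` (no radius division)
#'   within the mitral radius.
#'
#' Every nonzero entry gets a fresh weight `R ~ Normal(1.0, sd 0.05)`,
#' truncated at zero. Division by the radius keeps per-connection input
#' strength tied to the connection range. The strict inequalities `0 < d <
#' zeta` exclude self-connections, so all diagonals are exactly zero.
#'
#' @param geom A [bulb_geometry()].
#' @param zeta_m Mitral connection radius in lattice units (default 4).
#' @param zeta_g Granule connection radius in lattice units (default 15).
#' @param seed Integer RNG seed; the same seed reproduces the matrices
#'   bitwise.
#' @param mode Distance mode, see [toroidal_distance()].
#' @param l_radius_follows_printed_eq If `TRUE`, the mitral-mitral matrix
#'   `L` uses the granule radius `zeta_g` instead of `zeta_m`. Default
#'   `FALSE`: lateral mitral connections share the mitral radius.
#' @return An object of class `"synaptic_matrices"`: list with sparse
#'   `Matrix::dgCMatrix` members `H`, `W`, `L` plus `zeta_m`, `zeta_g`,
#'   `seed`, `geom`.
#' @examples
#' syn <- build_synapses(bulb_geometry(10, 6), zeta_m = 2, zeta_g = 3, seed = 1)
#' mean(syn$H@x)  # close to 1 / zeta_m
#' @export
build_synapses <- function(geom, zeta_m = 4, zeta_g = 15, seed = 1L,
                           mode = c("torus", "reflect-beta"),
                           l_radius_follows_printed_eq = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(geom, "bulb_geometry"))
  if (!is.numeric(zeta_m) || !is.numeric(zeta_g) || zeta_m <= 0 || zeta_g <= 0) {
    stop("connection radii must be positive")
  }
  if (zeta_m < 1 || zeta_g < 1) stop("connection radii must be >= 1")
  half_min <- min(geom$n_alpha, geom$n_beta) / 2
  if (max(zeta_m, zeta_g) >= half_min) {
    warning(sprintf(
      "connection radius %g is not below half the smaller lattice extent (%g); neighborhoods overlap themselves around the wrap",
      max(zeta_m, zeta_g), half_min))
  }
  d <- lattice_distance_matrix(geom, mode)
  zeta_l <- if (l_radius_follows_printed_eq) zeta_g else zeta_m

  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))

  ranged <- function(radius, divisor) {
    idx <- which(d > 0 & d < radius, arr.ind = TRUE)
    idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
    w <- pmax(stats::rnorm(nrow(idx), mean = 1.0, sd = 0.05), 0) / divisor
    Matrix::sparseMatrix(i = idx[, 1L], j = idx[, 2L], x = w,
                         dims = c(geom$n_units, geom$n_units))
  }
  H <- ranged(zeta_m, zeta_m)
  W <- ranged(zeta_g, zeta_g)
  L <- ranged(zeta_l, 1)

  structure(
    list(H = H, W = W, L = L, zeta_m = zeta_m, zeta_g = zeta_g,
         seed = as.integer(seed), mode = mode, geom = geom),
    class = "synaptic_matrices"
  )
}

#' @export
print.synaptic_matrices <- function(x, ...) {
  cat(sprintf(
    "Synaptic matrices on %d units (seed %d): zeta_m = %g, zeta_g = %g\n",
    x$geom$n_units, x$seed, x$zeta_m, x$zeta_g))
  cat(sprintf("  nonzeros: H %d, W %d, L %d\n",
              length(x$H@x), length(x$W@x), length(x$L@x)))
  invisible(x)
}

#' Write/read synaptic matrices as sparse coordinate text
#'
#' Persists the three matrices as a single delimited text file with columns
#' `matrix` (H/W/L), `row`, `col`, `weight` (1-based indices), preceded by
#' comment-prefixed header lines recording the geometry and radii.
#'
#' @param syn A `"synaptic_matrices"` object.
#' @param path Output (or input) file path.
#' @return `write_synapses` returns `path` invisibly; `read_synapses`
#'   returns a `"synaptic_matrices"` object.
#' @export
write_synapses <- function(syn, path) {
  stopifnot(inherits(syn, "synaptic_matrices"))
  hdr <- c(
    sprintf("# n_alpha %d", syn$geom$n_alpha),
    sprintf("# n_beta %d", syn$geom$n_beta),
    sprintf("# zeta_m %g", syn$zeta_m),
    sprintf("# zeta_g %g", syn$zeta_g),
    sprintf("# seed %d", syn$seed),
    sprintf("# mode %s", syn$mode),
    "# indexing row-major 1-based"
  )
  rows <- function(m, tag) {
    tm <- methods::as(m, "TsparseMatrix")
    data.frame(matrix = tag, row = tm@i + 1L, col = tm@j + 1L, weight = tm@x)
  }
  df <- rbind(rows(syn$H, "H"), rows(syn$W, "W"), rows(syn$L, "L"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_synapses
#' @export
read_synapses <- function(path) {
  hdr <- readLines(path, n = 7L)
  val <- function(key) sub(paste0("^# ", key, " "), "", grep(paste0("^# ", key), hdr, value = TRUE))
  geom <- bulb_geometry(as.integer(val("n_alpha")), as.integer(val("n_beta")))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  pick <- function(tag) {
    s <- df[df$matrix == tag, ]
    Matrix::sparseMatrix(i = s$row, j = s$col, x = s$weight,
                         dims = c(geom$n_units, geom$n_units))
  }
  structure(
    list(H = pick("H"), W = pick("W"), L = pick("L"),
         zeta_m = as.numeric(val("zeta_m")), zeta_g = as.numeric(val("zeta_g")),
         seed = as.integer(val("seed")), mode = val("mode"), geom = geom),
    class = "synaptic_matrices"
  )
}
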