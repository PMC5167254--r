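# Shared fixtures: small lattices and a reduced-scale synthetic panel so
# the heavy dynamics tests stay fast. The reduced geometry keeps the
# standard connection radii (so its granule neighborhoods wrap onto
# themselves; build calls are wrapped to absorb the resulting warning).

small_geom <- function() bulb_geometry(10, 6)

reduced_geom <- function() bulb_geometry(19, 10)

reduced_spec <- function(seed = 1) {
  synth_spec(n_odorants = 3, image_shape = c(60L, 95L), n_foci = 8,
             focus_sd = 4, seed = seed, geom = reduced_geom())
}

reduced_panel <- function(seed = 1) synth_panel(reduced_spec(seed))

quiet_synapses <- function(...) suppressWarnings(build_synapses(...))

# independent brute-force wrap distance: minimum over all 9 translated
# images of j on the doubly periodic lattice
brute_torus_distance <- function(geom, i, j) {
  ai <- geom$alpha[i]; bi <- geom$beta[i]
  aj <- geom$alpha[j]; bj <- geom$beta[j]
  best <- Inf
  for (ka in -1:1) for (kb in -1:1) {
    d <- sqrt((ai - (aj + ka * geom$n_alpha))^2 +
              (bi - (bj + kb * geom$n_beta))^2)
    best <- min(best, d)
  }
  best
}

# hand-constructed constant-drive sniff trace (for closed-form ODE checks)
constant_drive_trace <- function(n_units, value, duration, dt = 1,
                                 resp = respiration_params()) {
  times <- seq(0, duration, by = dt)
  structure(list(times = times,
                 drive = matrix(value, n_units, length(times)),
                 dt = dt, resp = resp, n_cycles = 1L),
            class = "sniff_trace")
}

# synapses with empty connectivity (all matrices structurally zero)
empty_synapses <- function(geom) {
  z <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(geom$n_units, geom$n_units))
  structure(list(H = z, W = z, L = z, zeta_m = 1, zeta_g = 1,
                 seed = 0L, mode = "torus", geom = geom),
            class = "synaptic_matrices")
}
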