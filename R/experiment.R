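#' Configuration of a replicated conditioning/discrimination experiment
#'
#' Bundles everything needed to repeat the two-step protocol (Hebbian
#' conditioning on the rewarded mixture, then discrimination scoring of
#' target odors) across replicate draws of the initial connectivity.
#' Replicate r uses connectivity seed `master_seed + r - 1`.
#'
#' @param panel A [synth_panel()] or a compatible list with `mixtures`
#'   (named list of `"mixture_input"`s) and `rewarded` (name of the
#'   rewarded mixture).
#' @param geom Lattice geometry (default: the panel's).
#' @param zeta_m,zeta_g Connection radii (defaults 4, 15).
#' @param n_seeds Number of replicate connectivity draws (default 20).
#' @param master_seed Base seed (default 1).
#' @param targets Names of target odors scored against the rewarded odor
#'   (default: every panel mixture except the rewarded one).
#' @param resp,params,learning Component parameter objects.
#' @param score_cycles Cycles simulated per scored odor (default 2).
#' @param mode Lattice distance mode (see [toroidal_distance()]).
#' @return An object of class `"experiment_config"`.
#' @export
experiment_config <- function(panel, geom = NULL, zeta_m = 4, zeta_g = 15,
                              n_seeds = 20L, master_seed = 1L,
                              targets = NULL,
                              resp = respiration_params(),
                              params = bulb_params(),
                              learning = learning_config(),
                              score_cycles = 2L,
                              mode = c("torus", "reflect-beta")) {
  mode <- match.arg(mode)
  stopifnot(is.list(panel), !is.null(panel$mixtures), !is.null(panel$rewarded))
  if (is.null(geom)) {
    geom <- if (!is.null(panel$spec)) panel$spec$geom else
      attr(panel$mixtures[[1L]], "geom")
  }
  if (is.null(targets)) targets <- setdiff(names(panel$mixtures), panel$rewarded)
  if (panel$rewarded %in% targets) stop("rewarded odor cannot be a target")
  stopifnot(all(targets %in% names(panel$mixtures)), n_seeds >= 1L)
  structure(list(panel = panel, geom = geom, zeta_m = zeta_m, zeta_g = zeta_g,
                 n_seeds = as.integer(n_seeds),
                 master_seed = as.integer(master_seed), targets = targets,
                 resp = resp, params = params, learning = learning,
                 score_cycles = as.integer(score_cycles), mode = mode),
            class = "experiment_config")
}

#' Run the replicated conditioning/discrimination experiment
#'
#' For each replicate seed: draw fresh connection matrices, condition on
#' the rewarded mixture (adapting the granule->mitral weights), freeze the
#' learned weights, score every target odor plus the rewarded odor itself,
#' and record the dissimilarity index of each target against the rewarded
#' response. Aggregates per-odor mean and sd over seeds; if behavioral
#' `rates` are supplied (one per target, in target order or named), also
#' reports the Pearson correlation with the per-odor means and the
#' Bonferroni-corrected pairwise comparison table.
#'
#' Replicates in which the integration diverges are recorded in
#' `$diverged` and excluded from the aggregates with a warning, never
#' silently.
#'
#' @param cfg An [experiment_config()].
#' @param rates Optional per-target behavioral discrimination rates.
#' @param include_rewarded_check Also score the rewarded odor against
#'   itself per seed (its `E` is ~0; a pipeline self-check). Default
#'   `TRUE`.
#' @return An object of class `"odor_experiment"`: list with `table`
#'   (odor, seed, E), `summary` (odor, mean_E, sd_E, n), `correlation`
#'   (NULL without rates), `pairwise`, `diverged`, `fits` (per-seed
#'   conditioning diagnostics) and `cfg`.
#' @export
run_experiment <- function(cfg, rates = NULL, include_rewarded_check = TRUE) {
  stopifnot(inherits(cfg, "experiment_config"))
  panel <- cfg$panel
  rewarded_mix <- panel$mixtures[[panel$rewarded]]
  score_names <- c(if (include_rewarded_check) panel$rewarded, cfg$targets)
  rows <- list()
  diverged <- list()
  fits <- list()
  for (r in seq_len(cfg$n_seeds)) {
    seed_r <- cfg$master_seed + r - 1L
    res <- tryCatch({
      syn <- build_synapses(cfg$geom, cfg$zeta_m, cfg$zeta_g, seed = seed_r,
                            mode = cfg$mode)
      fit <- condition_bulb(syn, rewarded_mix, cfg$resp, cfg$params,
                            cfg$learning, score_cycles = cfg$score_cycles)
      pred <- predict(fit, panel$mixtures[score_names])
      list(fit = fit, pred = pred)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      diverged[[length(diverged) + 1L]] <-
        data.frame(seed = seed_r, error = conditionMessage(res))
      warning(sprintf("replicate seed %d failed and was excluded: %s",
                      seed_r, conditionMessage(res)))
      next
    }
    fits[[as.character(seed_r)]] <- list(
      cycles_used = res$fit$cycles_used, converged = res$fit$converged,
      convergence = res$fit$convergence)
    rows[[length(rows) + 1L]] <-
      data.frame(odor = res$pred$odor, seed = seed_r, E = res$pred$E)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(odor = character(), seed = integer(), E = numeric())
  diverged <- if (length(diverged)) do.call(rbind, diverged) else
    data.frame(seed = integer(), error = character())

  target_tab <- tab[tab$odor %in% cfg$targets, , drop = FALSE]
  agg <- if (nrow(target_tab)) {
    data.frame(
      odor = cfg$targets,
      mean_E = vapply(cfg$targets, function(o) mean(target_tab$E[target_tab$odor == o]), 0),
      sd_E = vapply(cfg$targets, function(o) stats::sd(target_tab$E[target_tab$odor == o]), 0),
      n = vapply(cfg$targets, function(o) sum(target_tab$odor == o), 0L),
      row.names = NULL)
  } else data.frame(odor = character(), mean_E = numeric(), sd_E = numeric(),
                    n = integer())

  correlation <- NULL
  if (!is.null(rates)) {
    if (!is.null(names(rates))) rates <- rates[agg$odor]
    correlation <- behavior_correlation(agg$mean_E, rates)
  }
  pairwise <- NULL
  if (nrow(agg) >= 2L && all(agg$n >= 2L)) {
    samples <- lapply(cfg$targets, function(o) target_tab$E[target_tab$odor == o])
    names(samples) <- cfg$targets
    pairwise <- pairwise_bonferroni(samples)
  }
  structure(list(table = tab, summary = agg, correlation = correlation,
                 pairwise = pairwise, diverged = diverged, fits = fits,
                 rates = rates, cfg = cfg),
            class = "odor_experiment")
}

#' @export
print.odor_experiment <- function(x, ...) {
  cat(sprintf("Odor discrimination experiment: %d target odor(s), %d/%d replicate seed(s) completed\n",
              length(x$cfg$targets),
              length(unique(x$table$seed)), x$cfg$n_seeds))
  print(x$summary, row.names = FALSE, digits = 3)
  if (!is.null(x$correlation)) {
    cat(sprintf("Correlation with discrimination rates: r = %.3f, p = %.4f (n = %d)\n",
                x$correlation$r, x$correlation$p, x$correlation$n))
  }
  if (nrow(x$diverged)) {
    cat(sprintf("Excluded replicates: %s\n", paste(x$diverged$seed, collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.odor_experiment <- function(object, ...) object$summary

#' Plot per-odor dissimilarity with replicate spread
#'
#' Bar plot of per-target mean dissimilarity `E` with one-sd error bars
#' over the replicate connectivity seeds.
#'
#' @param x An `"odor_experiment"`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.odor_experiment <- function(x, ...) {
  s <- x$summary
  sd <- ifelse(is.finite(s$sd_E), s$sd_E, 0)  # single-replicate runs have no sd
  bp <- graphics::barplot(s$mean_E, names.arg = s$odor,
                          ylab = "dissimilarity index E",
                          ylim = c(0, max(s$mean_E + sd) * 1.1), ...)
  if (any(sd > 0)) {
    graphics::arrows(bp[sd > 0], (s$mean_E - sd)[sd > 0],
                     bp[sd > 0], (s$mean_E + sd)[sd > 0],
                     angle = 90, code = 3, length = 0.04)
  }
  invisible(x)
}

#' Sweep the connection radii and map prediction accuracy
#'
#' Repeats [run_experiment()] over a grid of mitral and granule connection
#' radii and records, per cell, the Pearson correlation between the
#' per-odor mean dissimilarity and the supplied behavioral rates. The
#' default grid (mitral 3..7 x granule 13..17) has 25 cells.
#'
#' @param cfg An [experiment_config()] (its radii are overridden cell by
#'   cell; the same replicate seeds are reused across cells).
#' @param zeta_m_range,zeta_g_range Radius grids (defaults 3:7 and 13:17).
#' @param rates Per-target behavioral rates (required).
#' @param n_seeds Optional reduced replicate count for the sweep.
#' @return An object of class `"radius_sweep"`: list with `grid` (data
#'   frame zeta_m, zeta_g, r, p) and `best` (the argmax-r row).
#' @export
sweep_parameters <- function(cfg, zeta_m_range = 3:7, zeta_g_range = 13:17,
                             rates, n_seeds = NULL) {
  stopifnot(inherits(cfg, "experiment_config"),
            length(zeta_m_range) >= 1L, length(zeta_g_range) >= 1L)
  if (missing(rates) || is.null(rates)) stop("behavioral rates are required for a sweep")
  if (!is.null(n_seeds)) cfg$n_seeds <- as.integer(n_seeds)
  cells <- expand.grid(zeta_m = zeta_m_range, zeta_g = zeta_g_range)
  res <- lapply(seq_len(nrow(cells)), function(k) {
    ck <- cfg
    ck$zeta_m <- cells$zeta_m[k]
    ck$zeta_g <- cells$zeta_g[k]
    ex <- run_experiment(ck, rates = rates, include_rewarded_check = FALSE)
    c(r = ex$correlation$r, p = ex$correlation$p)
  })
  grid <- cbind(cells, do.call(rbind, res))
  best <- grid[which.max(grid$r), , drop = FALSE]
  structure(list(grid = grid, best = best, rates = rates),
            class = "radius_sweep")
}

#' @export
print.radius_sweep <- function(x, ...) {
  cat(sprintf("Connection-radius sweep: %d cell(s)\n", nrow(x$grid)))
  print(x$grid, row.names = FALSE, digits = 3)
  cat(sprintf("Best cell: zeta_m = %g, zeta_g = %g (r = %.3f)\n",
              x$best$zeta_m, x$best$zeta_g, x$best$r))
  invisible(x)
}
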