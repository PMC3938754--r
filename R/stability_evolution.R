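#' Configuration for stability-distribution evolution
#'
#' The folding free energy of a protein is discretised on a uniform grid in
#' kcal/mol (default -15 to -0.5 in steps of 0.05; the upper bound keeps
#' every state at least marginally stable, and states near 0 are so costly
#' that truncating proposals beyond the grid is inert). Iteration stops when
#' the total-variation distance between successive phases falls below
#' `convergence_tol`.
#'
#' @param grid_min,grid_max,grid_step Grid bounds and spacing, kcal/mol.
#' @param max_iterations Iteration cap.
#' @param convergence_tol Total-variation convergence tolerance.
#' @param ks_alpha Significance level for the Kolmogorov-Smirnov convergence
#'   diagnostic.
#' @return A list of class `evolve_config`.
#' @export
evolve_config <- function(grid_min = -15, grid_max = -0.5, grid_step = 0.05,
                          max_iterations = 10000, convergence_tol = 1e-6,
                          ks_alpha = 0.05) {
  if (grid_min >= grid_max) abort("`grid_min` must be below `grid_max`.")
  if (grid_step <= 0) abort("`grid_step` must be > 0.")
  if (convergence_tol <= 0) abort("`convergence_tol` must be > 0.")
  structure(list(grid_min = grid_min, grid_max = grid_max,
                 grid_step = grid_step, max_iterations = max_iterations,
                 convergence_tol = convergence_tol, ks_alpha = ks_alpha),
            class = "evolve_config")
}

#' @rdname evolve_config
#' @param config An `evolve_config`.
#' @return `stability_grid()` returns the ascending grid of dG values.
#' @export
stability_grid <- function(config = evolve_config()) {
  seq(config$grid_min, config$grid_max, by = config$grid_step)
}

#' Discretised distribution over folding free energies
#'
#' @param grid Ascending, uniformly spaced dG values, kcal/mol.
#' @param pmf Non-negative masses summing to 1 (renormalised on input).
#' @return An object of class `stability_distribution`.
#' @export
stability_distribution <- function(grid, pmf) {
  if (length(grid) != length(pmf)) abort("`grid` and `pmf` lengths differ.")
  if (any(pmf < 0)) abort("Masses must be >= 0.")
  steps <- diff(grid)
  if (length(steps) > 0 &&
      (any(steps <= 0) || diff(range(steps)) > 1e-9 * steps[1])) {
    abort("`grid` must be ascending with constant spacing.")
  }
  total <- sum(pmf)
  if (total <= 0) abort("`pmf` must carry positive total mass.")
  structure(list(grid = grid, pmf = pmf / total),
            class = "stability_distribution")
}

#' @rdname stability_distribution
#' @param at dG at which to place a point mass (snapped to the nearest grid
#'   point).
#' @export
delta_distribution <- function(grid, at) {
  pmf <- numeric(length(grid))
  pmf[which.min(abs(grid - at))] <- 1
  stability_distribution(grid, pmf)
}

#' @export
print.stability_distribution <- function(x, ...) {
  cat(sprintf(
    "<stability_distribution> %d points on [%.2f, %.2f] kcal/mol; mode %.2f, mean %.3f\n",
    length(x$grid), min(x$grid), max(x$grid), dist_mode(x), dist_mean(x)))
  invisible(x)
}

#' Mode and mean of a stability distribution
#'
#' @param dist A [stability_distribution()].
#' @return The grid value carrying maximal mass, resp. the pmf-weighted mean
#'   (kcal/mol).
#' @export
dist_mode <- function(dist) {
  stopifnot(inherits(dist, "stability_distribution"))
  dist$grid[which.max(dist$pmf)]
}

#' @rdname dist_mode
#' @export
dist_mean <- function(dist) {
  stopifnot(inherits(dist, "stability_distribution"))
  sum(dist$grid * dist$pmf)
}

#' Total-variation and Kolmogorov-Smirnov distances between distributions
#'
#' Both require the two distributions to live on the same grid.
#' `tv_distance()` is half the L1 distance between the pmfs; `ks_distance()`
#' is the maximum absolute difference between the two CDFs.
#'
#' @param d1,d2 [stability_distribution()] objects on a shared grid.
#' @return A distance in [0, 1].
#' @export
tv_distance <- function(d1, d2) {
  check_shared_grid(d1, d2)
  0.5 * sum(abs(d1$pmf - d2$pmf))
}

#' @rdname tv_distance
#' @export
ks_distance <- function(d1, d2) {
  check_shared_grid(d1, d2)
  max(abs(cumsum(d1$pmf) - cumsum(d2$pmf)))
}

check_shared_grid <- function(d1, d2) {
  stopifnot(inherits(d1, "stability_distribution"),
            inherits(d2, "stability_distribution"))
  if (length(d1$grid) != length(d2$grid) ||
      any(abs(d1$grid - d2$grid) > 1e-9)) {
    abort("Distributions live on different grids.")
  }
  invisible(TRUE)
}

#' Fixation-weighted transition kernel over the stability grid
#'
#' Entry (i, j) is proportional to the probability that the next *fixed*
#' mutation moves the protein from dG_i to dG_j: the mutational proposal
#' density at ddG = dG_j - dG_i (positive = destabilising) times the
#' fixation probability of the resulting selection coefficient. Each row is
#' normalised to sum to 1, i.e. the kernel is conditioned on one fixation
#' per phase; proposal mass falling outside the grid is truncated before
#' normalisation. Selection coefficients come from [s_stability()] with the
#' grid converted from kcal/mol to kJ/mol, and fixation probabilities from
#' [fixation_probability()] with the cell model's population sizes.
#'
#' @param grid dG grid, kcal/mol (see [stability_grid()]).
#' @param template One-row proteome tibble supplying abundance, length,
#'   turnover and costs.
#' @param cell A [cell_model()] (supplies RT, reproductive power, N_eff, N).
#' @param ddg A [ddg_model()].
#' @return A row-stochastic matrix of class `transition_kernel` with the
#'   grid attached as attribute `grid`.
#' @examples
#' cfg <- evolve_config(grid_min = -10, grid_max = -1, grid_step = 0.5)
#' K <- transition_kernel(stability_grid(cfg), protein_spec(abundance = 4096),
#'                        cell_model(), ddg_model())
#' range(rowSums(K))
#' @export
transition_kernel <- function(grid, template, cell, ddg) {
  template <- validate_proteome(template)
  if (nrow(template) != 1) abort("`template` must be a single-row proteome.")
  stopifnot(inherits(ddg, "ddg_model"))
  rt <- thermal_energy(cell)
  ci <- cost_coefficient(template, cell)
  boltz <- exp(grid * .KJ_PER_KCAL / rt)
  # s[i, j] for the move dG_i -> dG_j (approximate-U closed form)
  s <- -ci * template$abundance * outer(boltz, boltz, function(bi, bj) bj - bi)
  p_fix <- matrix(
    fixation_probability(as.vector(s), cell$n_eff, cell$n_census),
    nrow = length(grid)
  )
  prop <- ddg_density(outer(grid, grid, function(gi, gj) gj - gi), ddg)
  kern <- prop * p_fix
  row_sums <- rowSums(kern)
  if (any(row_sums <= 0)) {
    abort(sprintf("No fixable mutation from grid state(s) dG = %s kcal/mol.",
                  paste(signif(grid[row_sums <= 0], 4), collapse = ", ")))
  }
  kern <- kern / row_sums
  attr(kern, "grid") <- grid
  class(kern) <- c("transition_kernel", class(kern))
  kern
}

#' Iterate a stability distribution under the transition kernel
#'
#' Applies P_{t+1} = K^T P_t, each phase representing one newly fixed
#' non-synonymous mutation, until the total-variation distance between
#' successive phases drops below `config$convergence_tol` or
#' `config$max_iterations` is reached (in which case the result is flagged,
#' not silently returned). Every phase is renormalised to guard against
#' floating-point drift.
#'
#' @param p0 Initial [stability_distribution()] on the kernel's grid.
#' @param kernel A [transition_kernel()].
#' @param config An [evolve_config()].
#' @return An object of class `stability_trajectory`: list with `grid`,
#'   `phases` (matrix, one row per phase including phase 0), `converged`,
#'   `iterations` and `final_tv`.
#' @export
evolve_distribution <- function(p0, kernel, config = evolve_config()) {
  stopifnot(inherits(p0, "stability_distribution"),
            inherits(kernel, "transition_kernel"))
  grid <- attr(kernel, "grid")
  if (length(p0$grid) != length(grid) || any(abs(p0$grid - grid) > 1e-9)) {
    abort("`p0` is not on the kernel's grid.")
  }
  phases <- list(p0$pmf)
  p <- p0$pmf
  converged <- FALSE
  tv <- NA_real_
  kt <- t(unclass(kernel))
  for (it in seq_len(config$max_iterations)) {
    p_next <- as.vector(kt %*% p)
    p_next <- p_next / sum(p_next)
    phases[[it + 1]] <- p_next
    tv <- 0.5 * sum(abs(p_next - p))
    p <- p_next
    if (tv < config$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("No convergence after %d phases (final TV %.3g).",
                 config$max_iterations, tv))
  }
  structure(
    list(grid = grid, phases = do.call(rbind, phases),
         converged = converged, iterations = length(phases) - 1,
         final_tv = tv),
    class = "stability_trajectory"
  )
}

#' @export
print.stability_trajectory <- function(x, ...) {
  cat(sprintf("<stability_trajectory> %d phases on %d grid points; %s (final TV %.3g)\n",
              x$iterations, length(x$grid),
              if (x$converged) "converged" else "NOT converged", x$final_tv))
  invisible(x)
}

#' Extract one phase of a trajectory as a distribution
#'
#' @param trajectory A `stability_trajectory`.
#' @param phase Phase index (0 = initial distribution).
#' @return A [stability_distribution()].
#' @export
trajectory_phase <- function(trajectory, phase) {
  stopifnot(inherits(trajectory, "stability_trajectory"))
  if (phase < 0 || phase > trajectory$iterations) {
    abort(sprintf("Phase must lie in [0, %d].", trajectory$iterations))
  }
  stability_distribution(trajectory$grid, trajectory$phases[phase + 1, ])
}

#' Kolmogorov-Smirnov convergence diagnostic
#'
#' Reports the first phase at which the KS statistic between successive
#' phases falls below the two-sample critical value at level `alpha`
#' (`c(alpha) * sqrt(2/n)` with `n` pseudo-sample size), mirroring the
#' common practice of declaring trajectories converged once consecutive
#' distributions are statistically indistinguishable. This is a diagnostic:
#' the phase count depends on `alpha` and `n`, neither of which has a
#' canonical value.
#'
#' @param trajectory A `stability_trajectory`.
#' @param alpha Significance level (default 0.05).
#' @param n Pseudo-sample size per side (default 100).
#' @return The first phase index meeting the criterion (NA if none).
#' @export
ks_convergence_phase <- function(trajectory, alpha = 0.05, n = 100) {
  stopifnot(inherits(trajectory, "stability_trajectory"))
  c_alpha <- sqrt(-0.5 * log(alpha / 2))
  crit <- c_alpha * sqrt(2 / n)
  cdfs <- t(apply(trajectory$phases, 1, cumsum))
  for (it in seq_len(trajectory$iterations)) {
    if (max(abs(cdfs[it + 1, ] - cdfs[it, ])) < crit) return(it)
  }
  NA_integer_
}

#' Mutation-selection equilibrium of the stability distribution
#'
#' Builds the transition kernel for the given protein and cell, iterates
#' from a point mass at `init` (kcal/mol) to convergence, and returns the
#' limiting distribution together with summary statistics. The equilibrium
#' is independent of the starting point; a protein with 2^12 copies per
#' cell and otherwise default yeast parameters equilibrates with its mode
#' near -6.5 kcal/mol, the distribution tailing towards higher stability.
#'
#' @param template One-row proteome tibble.
#' @param cell A [cell_model()].
#' @param ddg A [ddg_model()].
#' @param config An [evolve_config()].
#' @param init Initial dG, kcal/mol (point mass, default -3).
#' @return An object of class `stability_equilibrium`: list with
#'   `distribution`, `mode`, `mean`, `iterations`, `converged` and the
#'   `trajectory`.
#' @examples
#' \donttest{
#' eq <- equilibrium(protein_spec(abundance = 2^12), cell_model())
#' eq$mode
#' }
#' @export
equilibrium <- function(template, cell, ddg = ddg_model(),
                        config = evolve_config(), init = -3) {
  grid <- stability_grid(config)
  kern <- transition_kernel(grid, template, cell, ddg)
  traj <- evolve_distribution(delta_distribution(grid, init), kern, config)
  final <- trajectory_phase(traj, traj$iterations)
  structure(
    list(distribution = final, mode = dist_mode(final),
         mean = dist_mean(final), iterations = traj$iterations,
         converged = traj$converged, trajectory = traj,
         template = template, cell = cell, ddg = ddg, config = config),
    class = "stability_equilibrium"
  )
}

#' @export
print.stability_equilibrium <- function(x, ...) {
  cat(sprintf(
    "<stability_equilibrium> mode %.2f kcal/mol, mean %.3f; %d phases (%s)\n",
    x$mode, x$mean, x$iterations,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Sweep the equilibrium distribution over a cell or protein parameter
#'
#' Recomputes the mutation-selection equilibrium across values of one
#' scenario parameter:
#' * `abundance` - protein copies per cell;
#' * `temperature` - absolute temperature (enters only through RT; dG
#'   itself is treated as temperature independent);
#' * `metabolic_rate` - total specific metabolic rate, which rescales the
#'   reproductive power and hence the cost coefficient inversely.
#'
#' Presets mirror the standard panels: `fig4b` abundances 10^4..10^7 at a
#' slow metabolic rate of 2.8e-2 J/s/g; `fig4c` temperatures 310-340 K at
#' 2^12 copies and the same rate; `fig4d` metabolic rates 0.9-900 J/s/g at
#' 2^12 copies. Higher abundance, higher temperature and lower metabolic
#' rate all shift the equilibrium towards more stable (more negative) dG.
#'
#' @param scenario One of `"abundance"`, `"temperature"`,
#'   `"metabolic_rate"`.
#' @param values Scenario parameter values.
#' @param template One-row proteome tibble.
#' @param cell A [cell_model()].
#' @param ddg A [ddg_model()].
#' @param config An [evolve_config()].
#' @return A tibble with one row per value: `scenario`, `value`, `mode`,
#'   `mean`, `iterations`, `converged` and a list column `distribution`.
#' @export
stability_sweep <- function(scenario = c("abundance", "temperature",
                                         "metabolic_rate"),
                            values, template = protein_spec(abundance = 2^12),
                            cell = cell_model(), ddg = ddg_model(),
                            config = evolve_config()) {
  scenario <- match.arg(scenario)
  if (!all(is.finite(values))) abort("Scenario values must be finite.")
  purrr::map_dfr(values, function(v) {
    tpl <- template
    cl <- cell
    if (scenario == "abundance") {
      tpl$abundance <- v
      tpl$mrna <- 1e-4 * v
    } else if (scenario == "temperature") {
      cl$temperature <- v
      cl$rt_override <- NULL
    } else {
      cl$specific_rate <- v
    }
    eq <- equilibrium(tpl, cl, ddg, config)
    tibble::tibble(
      scenario = scenario, value = v, mode = eq$mode, mean = eq$mean,
      iterations = eq$iterations, converged = eq$converged,
      distribution = list(eq$distribution)
    )
  })
}

#' @rdname stability_sweep
#' @param preset One of `"fig4b"`, `"fig4c"`, `"fig4d"`.
#' @export
sweep_preset <- function(preset = c("fig4b", "fig4c", "fig4d"),
                         ddg = ddg_model(), config = evolve_config()) {
  preset <- match.arg(preset)
  slow <- cell_model(specific_rate = 2.8e-2)
  switch(preset,
    fig4b = stability_sweep("abundance", 10^(4:7),
                            template = protein_spec(abundance = 1e4),
                            cell = slow, ddg = ddg, config = config),
    fig4c = stability_sweep("temperature", c(310, 320, 330, 340),
                            template = protein_spec(abundance = 2^12),
                            cell = slow, ddg = ddg, config = config),
    fig4d = stability_sweep("metabolic_rate", c(0.9, 9, 90, 900),
                            template = protein_spec(abundance = 2^12),
                            cell = cell_model(), ddg = ddg, config = config)
  )
}
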