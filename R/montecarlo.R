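#' Configuration for the stochastic origin-fixation simulator
#'
#' @param n_replicates Number of independent trajectories (>= 1).
#' @param n_fixed_mutations Number of fixed mutations (phases) per
#'   trajectory.
#' @param seed Mandatory integer seed.
#' @param envelope_factor Safety multiplier on the rejection bound
#'   (default 1.1).
#' @return A list of class `mc_config`.
#' @export
mc_config <- function(n_replicates, n_fixed_mutations, seed,
                      envelope_factor = 1.1) {
  if (missing(seed)) abort("`seed` is mandatory.")
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  if (n_fixed_mutations < 0) abort("`n_fixed_mutations` must be >= 0.")
  if (envelope_factor < 1) abort("`envelope_factor` must be >= 1.")
  structure(list(n_replicates = as.integer(n_replicates),
                 n_fixed_mutations = as.integer(n_fixed_mutations),
                 seed = as.integer(seed),
                 envelope_factor = envelope_factor),
            class = "mc_config")
}

# rejection-sampling machinery shared by next_fixed_mutation() and
# simulate_population(): proposals are drawn from the ddG mixture, moves
# landing outside the grid are discarded (matching the kernel's truncation),
# and in-range moves are accepted with probability P_fix / M(source), where
# M(source) is the envelope-inflated maximum fixation probability over all
# destination grid points reachable from that source state. Because P_fix is
# monotone in s and s is monotone in the destination Boltzmann factor, the
# per-source grid maximum is a tight upper bound over the continuous
# proposal range. Accepted states are snapped to the nearest grid point so
# trajectories remain comparable with the deterministic kernel iteration.
.mc_setup <- function(grid, template, cell, ddg, envelope_factor) {
  template <- validate_proteome(template)
  if (nrow(template) != 1) abort("`template` must be a single-row proteome.")
  rt <- thermal_energy(cell)
  ci <- cost_coefficient(template, cell)
  boltz <- exp(grid * .KJ_PER_KCAL / rt)
  s_mat <- -ci * template$abundance * outer(boltz, boltz, function(bi, bj) bj - bi)
  p_mat <- matrix(fixation_probability(as.vector(s_mat), cell$n_eff,
                                       cell$n_census),
                  nrow = length(grid))
  envelope <- envelope_factor * apply(p_mat, 1, max)
  if (any(envelope <= 0)) abort("Fixation probability vanishes over the grid.")
  list(
    grid = grid, rt = rt,
    ci_a = ci * template$abundance,
    n_eff = cell$n_eff, n_census = cell$n_census,
    envelope = envelope
  )
}

# vectorised: one accepted move per element of `dg` (grid-snapped states)
.mc_step <- function(dg, setup, ddg, max_rounds = 10000) {
  n <- length(dg)
  out <- rep(NA_real_, n)
  idx0 <- vapply(dg, function(g) which.min(abs(setup$grid - g)), integer(1))
  pending <- seq_len(n)
  proposed <- 0
  accepted_total <- 0
  for (round in seq_len(max_rounds)) {
    m <- length(pending)
    if (m == 0) break
    dd <- .ddg_draw(ddg, m)
    dest <- setup$grid[idx0[pending]] + dd
    acc_u <- runif(m)
    in_range <- dest >= setup$grid[1] & dest <= setup$grid[length(setup$grid)]
    accept <- logical(m)
    if (any(in_range)) {
      src <- setup$grid[idx0[pending]][in_range]
      s <- -setup$ci_a * (exp(dest[in_range] * .KJ_PER_KCAL / setup$rt) -
                            exp(src * .KJ_PER_KCAL / setup$rt))
      p <- fixation_probability(s, setup$n_eff, setup$n_census)
      accept[in_range] <-
        acc_u[in_range] < p / setup$envelope[idx0[pending]][in_range]
    }
    proposed <- proposed + m
    accepted_total <- accepted_total + sum(accept)
    if (any(accept)) {
      snapped <- round((dest[accept] - setup$grid[1]) /
                         (setup$grid[2] - setup$grid[1]))
      out[pending[accept]] <- setup$grid[1 + pmax(0, pmin(length(setup$grid) - 1,
                                                          snapped))]
    }
    pending <- pending[!accept]
    if (proposed >= 1e6 && accepted_total / proposed < 1e-6) {
      abort("Rejection-sampling acceptance rate below 1e-6; check the selection parameters.")
    }
  }
  if (length(pending) > 0) {
    abort("Rejection sampling failed to accept a move; check the selection parameters.")
  }
  out
}

#' Draw the next fixed mutation of a protein's stability
#'
#' Stochastic counterpart of one row of the deterministic transition
#' kernel: proposes ddG values from the mutational mixture and accepts them
#' in proportion to the fixation probability of the implied selection
#' coefficient (rejection sampling with a per-state envelope). The returned
#' state is snapped to the grid.
#'
#' @param dg Current folding free energies, kcal/mol (vectorised).
#' @param template One-row proteome tibble.
#' @param cell A [cell_model()].
#' @param ddg A [ddg_model()].
#' @param grid dG grid, kcal/mol.
#' @param seed Mandatory integer seed.
#' @param envelope_factor Safety multiplier on the rejection bound.
#' @return New dG value(s) on the grid.
#' @export
next_fixed_mutation <- function(dg, template, cell, ddg,
                                grid = stability_grid(), seed,
                                envelope_factor = 1.1) {
  if (missing(seed)) abort("`seed` is mandatory.")
  setup <- .mc_setup(grid, template, cell, ddg, envelope_factor)
  withr::with_seed(seed, .mc_step(dg, setup, ddg))
}

#' Simulate origin-fixation trajectories of protein stability
#'
#' Runs `mc$n_replicates` independent trajectories, each a sequence of
#' `mc$n_fixed_mutations` fixed mutations starting from `dg0`, using the
#' rejection sampler of [next_fixed_mutation()]. This is the independent
#' stochastic check on the deterministic kernel iteration: the empirical
#' distribution of replicate states at phase k estimates the kernel's
#' phase-k distribution.
#'
#' @param dg0 Initial folding free energy, kcal/mol.
#' @param template One-row proteome tibble.
#' @param cell A [cell_model()].
#' @param ddg A [ddg_model()].
#' @param mc An [mc_config()].
#' @param grid dG grid, kcal/mol.
#' @return An object of class `mc_trajectory`: list with `grid` and
#'   `samples`, a matrix of dim `n_replicates x (n_fixed_mutations + 1)`
#'   whose column k+1 holds the phase-k states.
#' @export
simulate_population <- function(dg0, template, cell, ddg, mc,
                                grid = stability_grid()) {
  stopifnot(inherits(mc, "mc_config"))
  setup <- .mc_setup(grid, template, cell, ddg, mc$envelope_factor)
  start <- grid[which.min(abs(grid - dg0))]
  samples <- matrix(NA_real_, nrow = mc$n_replicates,
                    ncol = mc$n_fixed_mutations + 1)
  samples[, 1] <- start
  withr::with_seed(mc$seed, {
    for (k in seq_len(mc$n_fixed_mutations)) {
      samples[, k + 1] <- .mc_step(samples[, k], setup, ddg)
    }
  })
  structure(list(grid = grid, samples = samples, config = mc),
            class = "mc_trajectory")
}

#' @export
print.mc_trajectory <- function(x, ...) {
  cat(sprintf("<mc_trajectory> %d replicates, %d fixed mutations (seed %d)\n",
              nrow(x$samples), ncol(x$samples) - 1, x$config$seed))
  invisible(x)
}

#' Phase samples of a Monte-Carlo trajectory
#'
#' @param trajectory An `mc_trajectory`.
#' @param phase Phase index (0 = start).
#' @return Numeric vector of replicate states at that phase.
#' @export
mc_phase_samples <- function(trajectory, phase) {
  stopifnot(inherits(trajectory, "mc_trajectory"))
  if (phase < 0 || phase > ncol(trajectory$samples) - 1) {
    abort("Phase out of range.")
  }
  trajectory$samples[, phase + 1]
}
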