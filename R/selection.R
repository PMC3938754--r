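#' Dimensionless per-copy fitness cost of a protein
#'
#' The empirical "cost of one misfolded copy" resolves, under the energy
#' model, into the protein's turnover and handling parameters divided by the
#' power the cell devotes to reproduction:
#'
#'   c_i = n_aa * k_d * (2 c_s + c_d) * 1000 / (N_A * dEr/dt)
#'
#' so the cost is protein-specific: large, short-lived, synthetically
#' expensive proteins pay more per unfolded copy. With the yeast defaults
#' c_i = 3.10e-7.
#'
#' @param proteome A proteome tibble.
#' @param cell A [cell_model()].
#' @return Dimensionless cost per steady-state unfolded copy, per protein.
#' @examples
#' cost_coefficient(protein_spec(), cell_model()) # 3.10e-7
#' @export
cost_coefficient <- function(proteome, cell) {
  proteome <- validate_proteome(proteome)
  der <- reproductive_power(cell)
  proteome$n_aa * proteome$k_d * (2 * proteome$c_s + proteome$c_d) * 1000 /
    (.AVOG * der)
}

#' Fitness as chemical energy available for reproduction
#'
#' In `self_consistent` mode fitness is the proteome power minus the kinetic
#' maintenance cost of the given proteome (a literal reading of the energy
#' balance). In `paper` mode the fitness is the fixed reproductive power
#' minus the maintenance cost *in excess of* a reference (wild-type)
#' proteome; with `reference` equal to `proteome` this is simply the
#' reproductive power. Negative fitness is allowed but flagged with a
#' warning: it corresponds to a cell that can no longer fund reproduction
#' and enters a dormant phase.
#'
#' @param proteome A proteome tibble.
#' @param cell A [cell_model()].
#' @param mode `"paper"` (fixed reproductive-power baseline) or
#'   `"self_consistent"` (full energy balance).
#' @param reference Reference proteome for `paper` mode (default: `proteome`
#'   itself).
#' @param approximate Use the approximate unfolded count.
#' @return Fitness in J/s.
#' @export
fitness <- function(proteome, cell, mode = c("paper", "self_consistent"),
                    reference = NULL, approximate = FALSE) {
  mode <- match.arg(mode)
  proteome <- validate_proteome(proteome)
  phi <- if (mode == "self_consistent") {
    proteome_power(cell) - proteome_maintenance(proteome, cell, approximate)
  } else {
    ref <- reference %||% proteome
    reproductive_power(cell) -
      (proteome_maintenance(proteome, cell, approximate) -
         proteome_maintenance(ref, cell, approximate))
  }
  if (phi < 0) {
    warn("Fitness is negative: maintenance exceeds the energy budget (dormant phase).")
  }
  phi
}

#' Selection coefficient between two proteomes
#'
#' Compares a mutant proteome against the wild type. Any number of proteins
#' may differ: compensatory expression of related genes (epistasis) is
#' expressed simply as abundance edits in the mutant table. Because all
#' shared terms cancel, in `paper` mode the coefficient is the change in
#' maintenance power normalised by the reproductive power,
#' s = -(M' - M) / (dEr/dt); `self_consistent` mode evaluates
#' (Phi' - Phi)/Phi on the full energy balance instead.
#'
#' @param wt,mut Wild-type and mutant proteome tibbles.
#' @param cell A [cell_model()].
#' @param mode `"paper"` or `"self_consistent"`.
#' @param approximate Use the approximate unfolded count throughout.
#' @return A one-row tibble of class `selection_result` with columns `s`,
#'   `c_i` (cost coefficient of the single changed protein, NA if several
#'   changed), `delta_u` (change in total unfolded copies), `delta_cost`
#'   (change in maintenance power, J/s) and `mode`.
#' @examples
#' wt <- protein_spec(abundance = 1e4)
#' mut <- protein_spec(abundance = 1e5)
#' selection_coefficient(wt, mut, cell_model(rt_override = 2.5))
#' @export
selection_coefficient <- function(wt, mut, cell,
                                  mode = c("paper", "self_consistent"),
                                  approximate = FALSE) {
  mode <- match.arg(mode)
  wt <- validate_proteome(wt)
  mut <- validate_proteome(mut)
  m_wt <- proteome_maintenance(wt, cell, approximate)
  m_mut <- proteome_maintenance(mut, cell, approximate)
  delta_cost <- m_mut - m_wt
  delta_u <- sum(unfolded_count(mut, cell, approximate)) -
    sum(unfolded_count(wt, cell, approximate))
  s <- if (mode == "paper") {
    -delta_cost / reproductive_power(cell)
  } else {
    phi <- proteome_power(cell) - m_wt
    if (phi <= 0) abort("Wild-type fitness is not positive; cannot normalise s.")
    -delta_cost / phi
  }
  ci <- changed_protein_cost(wt, mut, cell)
  new_selection_result(s, ci, delta_u, delta_cost, mode)
}

new_selection_result <- function(s, c_i, delta_u, delta_cost, mode) {
  out <- tibble::tibble(s = s, c_i = c_i, delta_u = delta_u,
                        delta_cost = delta_cost, mode = mode)
  class(out) <- c("selection_result", class(out))
  out
}

# c_i of the single protein whose parameters differ; NA when 0 or >1 differ
# in the cost-relevant parameters
changed_protein_cost <- function(wt, mut, cell) {
  if (nrow(wt) != nrow(mut)) return(NA_real_)
  cols <- c("n_aa", "abundance", "dg_fold", "k_d", "c_s", "c_d")
  diff <- vapply(seq_len(nrow(wt)), function(i) {
    any(unlist(wt[i, cols]) != unlist(mut[i, cols]))
  }, logical(1))
  if (sum(diff) != 1) return(NA_real_)
  cost_coefficient(mut[diff, ], cell)
}

#' Selection coefficient of a stability-changing mutation
#'
#' Closed form for the special case where only the folding free energy of a
#' single protein changes. Using the approximate unfolded count
#' U = A exp(dG/RT),
#'
#'   s = -c_i * A * (exp(dG'/RT) - exp(dG/RT))
#'
#' so destabilising mutations (dG' > dG) carry negative s and stabilising
#' ones positive s, each scaled by the protein's per-copy cost c_i.
#'
#' @param protein A one-row proteome tibble (the wild type).
#' @param dg_mut Mutant folding free energy (kJ/mol); may be a vector.
#' @param cell A [cell_model()].
#' @return A `selection_result` tibble with one row per `dg_mut`.
#' @examples
#' cell <- cell_model(rt_override = 2.5)
#' s_stability(protein_spec(abundance = 1e5), -25, cell) # s ~ -1.4e-6
#' @export
s_stability <- function(protein, dg_mut, cell) {
  protein <- validate_proteome(protein)
  if (nrow(protein) != 1) abort("`protein` must be a single-row proteome.")
  rt <- thermal_energy(cell)
  ci <- cost_coefficient(protein, cell)
  e_wt <- exp(protein$dg_fold / rt)
  e_mut <- exp(dg_mut / rt)
  s <- -ci * protein$abundance * (e_mut - e_wt)
  du <- protein$abundance * (e_mut - e_wt)
  new_selection_result(s, ci, du, -s * reproductive_power(cell), "paper")
}

#' Selection against unfolded copies in the legacy log form
#'
#' The earlier misfolding-cost model writes the selection coefficient of a
#' change in unfolded copies as a log fitness ratio; for realistic (small)
#' coefficients it linearises to -c * dU. Both forms are returned; whenever
#' |s| < 0.01 they agree to within 1e-4 (four decimal digits, the error
#' being of order s^2/2), and in the realistic regime c*U << 1e-4 they agree
#' to four significant digits as well.
#'
#' @param c Dimensionless per-copy cost (>= 0).
#' @param u_wt,u_mut Steady-state unfolded copies of wild type and mutant.
#' @return A tibble with columns `s_log` (`log1p(c u_wt) - log1p(c u_mut)`)
#'   and `s_linear` (`-c (u_mut - u_wt)`).
#' @export
s_misfolding_legacy <- function(c, u_wt, u_mut) {
  if (any(c < 0)) abort("`c` must be >= 0.")
  tibble::tibble(
    s_log = log1p(c * u_wt) - log1p(c * u_mut),
    s_linear = -c * (u_mut - u_wt)
  )
}

#' Selection landscape over two protein parameters
#'
#' Evaluates the selection coefficient of an expression-changing mutation
#' (wild-type abundance versus mutant abundance) over a grid of two varying
#' parameters. Axis names are drawn from `abundance_mut`, `abundance_wt`,
#' `k_d`, `n_aa` and `c_s`; parameters other than the mutant abundance are
#' shared by wild type and mutant (a mutation changes expression, not the
#' protein's intrinsic handling costs). Presets reproduce the standard four
#' panels: `fig1a` mutant vs wild-type abundance, `fig1b` mutant abundance vs
#' turnover, `fig1c` vs length and `fig1d` vs synthesis cost (the latter two
#' for a short-lived protein, k_d = 0.01 s^-1).
#'
#' @param template A one-row proteome tibble supplying all fixed parameters.
#' @param cell A [cell_model()].
#' @param x_spec,y_spec Lists `list(name =, values =)` naming the two axes.
#' @param mode Passed to [selection_coefficient()].
#' @return A `landscape_grid` object: axis vectors plus a matrix of s values
#'   (rows index x, columns index y). Use [tidy()] for a long tibble or
#'   [autoplot()] for a raster plot.
#' @examples
#' grid <- landscape_preset("fig1a", n = 11)
#' tidy(grid)
#' @export
selection_landscape <- function(template, cell, x_spec, y_spec,
                                mode = "paper") {
  template <- validate_proteome(template)
  if (nrow(template) != 1) abort("`template` must be a single-row proteome.")
  check_axis <- function(spec, arg) {
    ok <- c("abundance_mut", "abundance_wt", "k_d", "n_aa", "c_s")
    if (!is.list(spec) || is.null(spec$name) || is.null(spec$values)) {
      abort(sprintf("`%s` must be list(name =, values =).", arg))
    }
    if (!spec$name %in% ok) {
      abort(sprintf("Unknown axis name '%s'; must be one of %s.",
                    spec$name, paste(ok, collapse = ", ")))
    }
    if (!all(is.finite(spec$values))) abort("Axis values must be finite.")
    spec
  }
  x_spec <- check_axis(x_spec, "x_spec")
  y_spec <- check_axis(y_spec, "y_spec")
  values <- matrix(NA_real_, nrow = length(x_spec$values),
                   ncol = length(y_spec$values))
  apply_axis <- function(wt, mut, name, value) {
    if (name == "abundance_mut") {
      mut$abundance <- value
      mut$mrna <- 1e-4 * max(value, 1)
    } else if (name == "abundance_wt") {
      wt$abundance <- value
      wt$mrna <- 1e-4 * max(value, 1)
    } else {
      wt[[name]] <- value
      mut[[name]] <- value
    }
    list(wt = wt, mut = mut)
  }
  for (i in seq_along(x_spec$values)) {
    for (j in seq_along(y_spec$values)) {
      wt <- template
      mut <- template
      p <- apply_axis(wt, mut, x_spec$name, x_spec$values[i])
      p <- apply_axis(p$wt, p$mut, y_spec$name, y_spec$values[j])
      values[i, j] <- selection_coefficient(p$wt, p$mut, cell, mode = mode)$s
    }
  }
  new_landscape_grid(x_spec, y_spec, values, "s",
                     list(template = template, cell = cell))
}

new_landscape_grid <- function(x_spec, y_spec, values, quantity, metadata) {
  stopifnot(nrow(values) == length(x_spec$values),
            ncol(values) == length(y_spec$values))
  structure(
    list(x_name = x_spec$name, x_values = x_spec$values,
         y_name = y_spec$name, y_values = y_spec$values,
         values = values, quantity = quantity, metadata = metadata),
    class = "landscape_grid"
  )
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("<landscape_grid> %s over %s (%d) x %s (%d)\n",
              x$quantity, x$x_name, length(x$x_values),
              x$y_name, length(x$y_values)))
  cat(sprintf("  range: [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @rdname selection_landscape
#' @param preset One of `"fig1a"`, `"fig1b"`, `"fig1c"`, `"fig1d"`.
#' @param n Grid resolution per axis.
#' @export
landscape_preset <- function(preset = c("fig1a", "fig1b", "fig1c", "fig1d"),
                             template = protein_spec(), cell = cell_model(),
                             n = 41) {
  preset <- match.arg(preset)
  a_mut <- list(name = "abundance_mut", values = seq(0, 1e5, length.out = n))
  spec <- switch(
    preset,
    fig1a = list(x = a_mut,
                 y = list(name = "abundance_wt",
                          values = seq(0, 1e5, length.out = n))),
    fig1b = list(x = a_mut,
                 y = list(name = "k_d",
                          values = 10^seq(-5, -1, length.out = n))),
    fig1c = list(x = a_mut,
                 y = list(name = "n_aa", values = seq(50, 2000, length.out = n)),
                 k_d = 0.01),
    fig1d = list(x = a_mut,
                 y = list(name = "c_s", values = seq(100, 3000, length.out = n)),
                 k_d = 0.01)
  )
  if (!is.null(spec$k_d)) template$k_d <- spec$k_d
  selection_landscape(template, cell, spec$x, spec$y)
}

#' Round a selection coefficient to its nearest power of ten
#'
#' Convention for order-of-magnitude statements about selection strength:
#' the magnitude is rounded as `10^round(log10(|s|))` and the sign kept.
#'
#' @param s Selection coefficient(s).
#' @return Signed powers of ten (0 stays 0).
#' @examples
#' signed_order_of_magnitude(-1.04e-8) # -1e-8
#' @export
signed_order_of_magnitude <- function(s) {
  out <- sign(s) * 10^round(log10(abs(s)))
  out[s == 0] <- 0
  out
}
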