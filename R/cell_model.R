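#' Organism-level energy bookkeeping
#'
#' A `cell_model` collects the cell-physiological parameters that convert
#' per-protein turnover costs into a selection coefficient: temperature, cell
#' mass, the total specific metabolic rate, the fraction of that rate spent
#' outside the proteome, the fraction devoted to reproduction, and the
#' population sizes used for fixation probabilities. Defaults describe a
#' yeast cell at 37 C: mass 3.4e-11 g, total respiration 0.9 J/s/g of which
#' one third is non-proteome cost, and 10% of proteome energy devoted to
#' reproduction, which yields a reproductive power of 2.04e-12 J/s.
#'
#' `rt_override` replaces the physical RT (gas constant times temperature) in
#' every Boltzmann factor. It exists because several classic worked numbers
#' in the literature (0.037 unfolded copies at -37 kJ/mol, 4.5 at -25) are
#' quoted at the round value RT = 2.5 kJ/mol rather than the 2.579 kJ/mol of
#' 37 C; set `rt_override = 2.5` to reproduce them.
#'
#' @param temperature Absolute temperature, K.
#' @param rt_override Optional RT in kJ/mol replacing `gas_constant *
#'   temperature` everywhere.
#' @param cell_mass Cell mass, g.
#' @param specific_rate Total metabolic rate per gram, J s^-1 g^-1.
#' @param nonproteome_fraction Fraction of the total rate spent on
#'   non-proteome processes (RNA metabolism, ion pumps, ...).
#' @param repro_fraction Fraction F of proteome energy devoted to
#'   reproduction, strictly inside (0, 1).
#' @param der_override Optional fixed reproductive power, J/s, bypassing the
#'   `repro_fraction * cell_mass * specific_rate * (1 - nonproteome_fraction)`
#'   product.
#' @param n_eff Effective population size.
#' @param n_census Census population size (defaults to `n_eff`).
#' @return An object of class `cell_model`.
#' @examples
#' cell <- cell_model()
#' reproductive_power(cell) # 2.04e-12 J/s
#' @export
cell_model <- function(temperature = 310.15,
                       rt_override = NULL,
                       cell_mass = 3.4e-11,
                       specific_rate = 0.9,
                       nonproteome_fraction = 1 / 3,
                       repro_fraction = 0.10,
                       der_override = NULL,
                       n_eff = 1e7,
                       n_census = n_eff) {
  if (!is.numeric(temperature) || temperature <= 0) {
    abort("`temperature` must be a positive number of Kelvin.")
  }
  if (!is.null(rt_override) && (!is.numeric(rt_override) || rt_override <= 0)) {
    abort("`rt_override` must be a positive energy in kJ/mol.")
  }
  if (cell_mass <= 0 || specific_rate <= 0) {
    abort("`cell_mass` and `specific_rate` must be positive.")
  }
  if (repro_fraction <= 0 || repro_fraction >= 1) {
    abort("`repro_fraction` must lie strictly between 0 and 1.")
  }
  if (nonproteome_fraction < 0 || nonproteome_fraction >= 1) {
    abort("`nonproteome_fraction` must lie in [0, 1).")
  }
  if (n_eff < 1) abort("`n_eff` must be at least 1.")
  if (n_census < n_eff) abort("`n_census` must be at least `n_eff`.")
  structure(
    list(
      temperature = temperature,
      rt_override = rt_override,
      cell_mass = cell_mass,
      specific_rate = specific_rate,
      nonproteome_fraction = nonproteome_fraction,
      repro_fraction = repro_fraction,
      der_override = der_override,
      n_eff = n_eff,
      n_census = n_census
    ),
    class = "cell_model"
  )
}

#' @export
print.cell_model <- function(x, ...) {
  cat("<cell_model>\n")
  cat(sprintf("  T = %.2f K (RT = %.4g kJ/mol%s)\n",
              x$temperature, thermal_energy(x),
              if (!is.null(x$rt_override)) ", override" else ""))
  cat(sprintf("  mass = %.3g g, specific rate = %.3g J/s/g (non-proteome %.3g)\n",
              x$cell_mass, x$specific_rate, x$nonproteome_fraction))
  cat(sprintf("  F = %.3g, reproductive power = %.4g J/s\n",
              x$repro_fraction, reproductive_power(x)))
  cat(sprintf("  N_eff = %.3g, N = %.3g\n", x$n_eff, x$n_census))
  invisible(x)
}

#' Thermal energy RT of a cell model
#'
#' Returns `rt_override` when it is set, otherwise the gas constant times the
#' temperature, in kJ/mol.
#'
#' @param cell A [cell_model()].
#' @return RT in kJ/mol.
#' @export
thermal_energy <- function(cell) {
  stopifnot(inherits(cell, "cell_model"))
  cell$rt_override %||% (.R_GAS * cell$temperature)
}

#' Power devoted to the proteome, reproduction and maintenance
#'
#' `proteome_power()` is the share of the total metabolic rate spent on the
#' proteome, `cell_mass * specific_rate * (1 - nonproteome_fraction)`.
#' `reproductive_power()` is the fraction F of that devoted to reproduction
#' (the fitness denominator), and `maintenance_budget()` the complementary
#' `(1 - F)` share. With the yeast defaults these are 2.04e-11, 2.04e-12 and
#' 1.84e-11 J/s.
#'
#' @param cell A [cell_model()].
#' @return Power in J/s.
#' @export
proteome_power <- function(cell) {
  stopifnot(inherits(cell, "cell_model"))
  cell$cell_mass * cell$specific_rate * (1 - cell$nonproteome_fraction)
}

#' @rdname proteome_power
#' @export
reproductive_power <- function(cell) {
  stopifnot(inherits(cell, "cell_model"))
  out <- cell$der_override %||% (cell$repro_fraction * proteome_power(cell))
  if (out <= 0) {
    abort("Reproductive power must be positive: it is the fitness denominator.")
  }
  out
}

#' @rdname proteome_power
#' @export
maintenance_budget <- function(cell) {
  stopifnot(inherits(cell, "cell_model"))
  (1 - cell$repro_fraction) * proteome_power(cell)
}

#' Load a cell model from a flat JSON document
#'
#' Reads a JSON object whose keys are a subset of the [cell_model()]
#' arguments; missing keys are filled with the yeast defaults. Unknown keys
#' are an error so that typos cannot silently fall back to defaults. The
#' effective parameter values are echoed as a message.
#'
#' @param path Path to a JSON file.
#' @return A [cell_model()].
#' @export
load_cell_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(cell_model))
  unknown <- setdiff(names(doc), allowed)
  if (length(unknown) > 0) {
    abort(paste0("Unknown cell-model key(s): ", paste(unknown, collapse = ", ")))
  }
  cell <- do.call(cell_model, doc)
  if (!is.null(cell$rt_override)) {
    inform(sprintf("cell model: RT override %.4g kJ/mol in force", cell$rt_override))
  }
  inform(sprintf(
    "cell model: T=%.2fK mass=%.3g rate=%.3g F=%.3g -> dEr/dt=%.4g J/s",
    cell$temperature, cell$cell_mass, cell$specific_rate,
    cell$repro_fraction, reproductive_power(cell)
  ))
  cell
}
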