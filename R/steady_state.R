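#' Steady-state unfolded copy number
#'
#' At steady state a two-state protein partitions its `abundance` A between
#' folded and unfolded copies according to the Boltzmann ratio
#' U/F = exp(dG/RT). The exact form is U = A exp(dG/RT) / (1 + exp(dG/RT));
#' since most proteins are far more stable than -RT, the approximation
#' U = A exp(dG/RT) (the form used in the analytic selection expressions) is
#' available via `approximate = TRUE`. Both forms are clamped to [0, A] so
#' that strongly destabilised inputs saturate instead of overflowing.
#'
#' @param proteome A proteome tibble (see [protein_spec()]).
#' @param cell A [cell_model()].
#' @param approximate Use the single-exponential approximation.
#' @return Unfolded copies per protein (numeric vector).
#' @examples
#' cell <- cell_model(rt_override = 2.5)
#' unfolded_count(protein_spec(abundance = 1e5), cell) # ~0.037 copies
#' @export
unfolded_count <- function(proteome, cell, approximate = FALSE) {
  proteome <- validate_proteome(proteome)
  x <- proteome$dg_fold / thermal_energy(cell)
  u <- if (approximate) {
    pmin(exp(x), 1)
  } else {
    stats::plogis(x)
  }
  proteome$abundance * u
}

#' Steady-state folded copy number
#'
#' The folded complement of [unfolded_count()]; in exact mode
#' `folded_count + unfolded_count` equals the abundance.
#'
#' @inheritParams unfolded_count
#' @return Folded copies per protein.
#' @export
folded_count <- function(proteome, cell, approximate = FALSE) {
  proteome <- validate_proteome(proteome)
  proteome$abundance - unfolded_count(proteome, cell, approximate = approximate)
}

#' Probability that a protein copy is folded
#'
#' P_F = 1 / (1 + exp(dG/RT)); tends to 1 for very stable proteins and to
#' 1/2 at dG = 0.
#'
#' @inheritParams unfolded_count
#' @return Probabilities in [0, 1].
#' @export
prob_folded <- function(proteome, cell) {
  proteome <- validate_proteome(proteome)
  stats::plogis(-proteome$dg_fold / thermal_energy(cell))
}

#' Steady-state synthesis rate constant
#'
#' The steady-state flux balance of the turnover scheme gives
#' k_s = 2 k_d U / mRNA. The physically attainable ceiling,
#' `min(ribosome_rate_constant(n_aa), k_fold)`, is reported alongside as
#' `k_s_cap`; the flux form drives all energetics.
#'
#' @inheritParams unfolded_count
#' @return A tibble with columns `k_s` and `k_s_cap` (both s^-1).
#' @export
synthesis_rate <- function(proteome, cell, approximate = FALSE) {
  proteome <- validate_proteome(proteome)
  u <- unfolded_count(proteome, cell, approximate = approximate)
  tibble::tibble(
    k_s = 2 * proteome$k_d * u / proteome$mrna,
    k_s_cap = pmin(ribosome_rate_constant(proteome$n_aa), proteome$k_fold)
  )
}

#' Proteostatic maintenance power of each protein
#'
#' At steady state the degradation flux k_d U (copies/s) is matched by an
#' equal synthesis flux, and every cycled copy costs `n_aa * (2 c_s + c_d)`
#' kJ/mol (each synthesised copy passes the unfolded pool twice under the
#' flux balance, hence the factor 2 on the synthesis cost). Dividing by
#' Avogadro's number converts to Joules per second per cell:
#'
#'   power = n_aa * k_d * U * (2 c_s + c_d) * 1000 / N_A
#'
#' @inheritParams unfolded_count
#' @return Maintenance power per protein, J/s.
#' @export
maintenance_power <- function(proteome, cell, approximate = FALSE) {
  proteome <- validate_proteome(proteome)
  u <- unfolded_count(proteome, cell, approximate = approximate)
  proteome$n_aa * proteome$k_d * u *
    (2 * proteome$c_s + proteome$c_d) * 1000 / .AVOG
}

#' Total proteome maintenance power
#'
#' @inheritParams unfolded_count
#' @return Summed maintenance power, J/s (0 for an empty proteome).
#' @export
proteome_maintenance <- function(proteome, cell, approximate = FALSE) {
  proteome <- validate_proteome(proteome)
  if (nrow(proteome) == 0) return(0)
  sum(maintenance_power(proteome, cell, approximate = approximate))
}

#' Full per-protein steady state
#'
#' Convenience wrapper returning the proteome table augmented with the
#' steady-state quantities: unfolded (`u`) and folded (`f`) copies, folded
#' probability (`p_folded`), synthesis rate constant and its cap (`k_s`,
#' `k_s_cap`), and maintenance power (`cost_power`, J/s).
#'
#' @inheritParams unfolded_count
#' @return The input tibble with the steady-state columns appended.
#' @examples
#' steady_state(protein_spec(abundance = 1e5), cell_model(rt_override = 2.5))
#' @export
steady_state <- function(proteome, cell, approximate = FALSE) {
  proteome <- validate_proteome(proteome)
  ks <- synthesis_rate(proteome, cell, approximate = approximate)
  dplyr::mutate(
    proteome,
    u = unfolded_count(proteome, cell, approximate = approximate),
    f = .data$abundance - .data$u,
    p_folded = prob_folded(proteome, cell),
    k_s = ks$k_s,
    k_s_cap = ks$k_s_cap,
    cost_power = maintenance_power(proteome, cell, approximate = approximate)
  )
}
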