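#' Kimura fixation probability of a new mutant
#'
#' Haploid diffusion approximation for the fixation probability of a single
#' new mutant with selection coefficient s:
#'
#'   P_fix = (1 - exp(-2 s N_eff / N)) / (1 - exp(-2 N_eff s))
#'
#' where N_eff and N are the effective and census population sizes. The
#' function is continuous at s = 0 with the neutral limit 1/N, strictly
#' increasing in s, and bounded in [0, 1]. Both tails are evaluated through
#' `expm1()` so that the near-neutral regime (|2 N_eff s| down to the
#' smallest representable values) is computed without 0/0 cancellation.
#'
#' @param s Selection coefficient(s); must exceed -1 (values at or below -1
#'   return 0 with a warning).
#' @param n_eff Effective population size.
#' @param n_census Census population size (default `n_eff`).
#' @return Fixation probabilities in [0, 1].
#' @examples
#' fixation_probability(0, 1e7)     # neutral: 1e-7
#' fixation_probability(1e-6, 1e7)  # beneficial: ~2e-6
#' @export
fixation_probability <- function(s, n_eff, n_census = n_eff) {
  if (n_eff < 1) abort("`n_eff` must be >= 1.")
  if (n_census < n_eff) abort("`n_census` must be >= `n_eff`.")
  out <- rep(NA_real_, length(s))
  lethal <- s <= -1
  if (any(lethal)) {
    warn("Selection coefficient(s) <= -1 treated as lethal: P_fix = 0.")
    out[lethal] <- 0
  }
  ok <- !lethal
  x <- -2 * s[ok] * n_eff / n_census
  y <- -2 * n_eff * s[ok]
  p <- ifelse(s[ok] == 0, 1 / n_census, -expm1(x) / -expm1(y))
  # strongly deleterious: denominator overflows to Inf, ratio underflows to 0
  p[is.nan(p)] <- 0
  out[ok] <- pmin(pmax(p, 0), 1)
  out
}

#' Fixation-probability surface over two protein parameters
#'
#' Applies [fixation_probability()] elementwise to a selection landscape of
#' expression-changing mutations (see [selection_landscape()]). Presets
#' `fig2_left` (mutant abundance vs length) and `fig2_right` (mutant
#' abundance vs turnover constant) use a wild-type abundance of 10^4 copies.
#'
#' @inheritParams selection_landscape
#' @param n_eff,n_census Population sizes.
#' @return A `landscape_grid` whose values are fixation probabilities.
#' @export
fixation_surface <- function(template, cell, x_spec, y_spec,
                             n_eff = cell$n_eff, n_census = cell$n_census,
                             mode = "paper") {
  grid <- selection_landscape(template, cell, x_spec, y_spec, mode = mode)
  grid$values <- matrix(
    fixation_probability(as.vector(grid$values), n_eff, n_census),
    nrow = nrow(grid$values)
  )
  grid$quantity <- "p_fix"
  grid$metadata$n_eff <- n_eff
  grid$metadata$n_census <- n_census
  grid
}

#' @rdname fixation_surface
#' @param preset `"fig2_left"` or `"fig2_right"`.
#' @param n Grid resolution per axis.
#' @export
fixation_surface_preset <- function(preset = c("fig2_left", "fig2_right"),
                                    template = protein_spec(abundance = 1e4),
                                    cell = cell_model(), n = 41) {
  preset <- match.arg(preset)
  x <- list(name = "abundance_mut", values = seq(0, 1e5, length.out = n))
  y <- switch(preset,
    fig2_left = list(name = "n_aa", values = seq(50, 2000, length.out = n)),
    fig2_right = list(name = "k_d", values = 10^seq(-5, -1, length.out = n))
  )
  fixation_surface(template, cell, x, y)
}

#' Fixation probability of stability-changing mutations
#'
#' Tabulates P_fix for mutations that move a protein's folding free energy
#' from the wild-type value to each value of `dg_mut_grid`, across levels of
#' one varied parameter (`abundance` or `k_d`). Destabilising mutations in
#' abundant or short-lived proteins approach zero fixation probability,
#' while in low-cost proteins they fix at nearly the neutral rate 1/N.
#'
#' @param template One-row proteome tibble; its `dg_fold` is the wild type
#'   (-37 kJ/mol for the standard preset).
#' @param cell A [cell_model()].
#' @param dg_mut_grid Mutant folding free energies, kJ/mol.
#' @param vary Named list with one element, `abundance` or `k_d`, giving the
#'   levels to sweep.
#' @param n_eff,n_census Population sizes.
#' @return A tibble with columns `dg_mut`, the varied parameter's name and
#'   value, `s` and `p_fix`.
#' @examples
#' cell <- cell_model(rt_override = 2.5)
#' fixation_vs_stability(protein_spec(), cell, dg_mut_grid = c(-37, -32),
#'                       vary = list(abundance = c(1e3, 1e5)))
#' @export
fixation_vs_stability <- function(template, cell,
                                  dg_mut_grid = seq(-50, -5, by = 1),
                                  vary = list(abundance = 10^(3:6)),
                                  n_eff = cell$n_eff,
                                  n_census = cell$n_census) {
  template <- validate_proteome(template)
  if (nrow(template) != 1) abort("`template` must be a single-row proteome.")
  if (length(vary) != 1 || !names(vary) %in% c("abundance", "k_d")) {
    abort("`vary` must be a one-element named list: abundance or k_d.")
  }
  param <- names(vary)
  purrr::map_dfr(vary[[1]], function(v) {
    prot <- template
    prot[[param]] <- v
    if (param == "abundance") prot$mrna <- 1e-4 * v
    s <- s_stability(prot, dg_mut_grid, cell)$s
    tibble::tibble(
      dg_mut = dg_mut_grid, param = param, value = v, s = s,
      p_fix = fixation_probability(s, n_eff, n_census)
    )
  })
}
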