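#' Construct a one-protein proteome table
#'
#' Proteomes are plain tibbles with one row per protein and the columns
#' `name`, `n_aa` (residues), `abundance` (copies per cell), `dg_fold`
#' (folding free energy, kJ/mol, negative for stable proteins), `k_d`
#' (degradation rate constant, s^-1), `c_s` and `c_d` (synthesis and
#' degradation cost per residue, kJ/mol), `mrna` (mRNA copies) and `k_fold`
#' (folding rate constant, s^-1). `protein_spec()` builds a single row with
#' the average-yeast-protein defaults: 467 residues, 10^4 copies, -37 kJ/mol,
#' 43-minute half-life (k_d = 2.69e-4 s^-1), synthesis cost 1500 and
#' degradation cost 30 kJ/mol per residue, and mRNA at 1e-4 of abundance.
#'
#' @param name Protein identifier.
#' @param n_aa Residue count (>= 1).
#' @param abundance Copies per cell (>= 0).
#' @param dg_fold Folding free energy, kJ/mol; <= 0 for stable proteins.
#' @param k_d Degradation rate constant, s^-1 (> 0).
#' @param c_s Synthesis cost per residue, kJ/mol.
#' @param c_d Degradation cost per residue, kJ/mol.
#' @param mrna mRNA copies (default 1e-4 * abundance).
#' @param k_fold Folding rate constant, s^-1.
#' @return A one-row tibble.
#' @examples
#' protein_spec(abundance = 1e5)
#' @export
protein_spec <- function(name = "protein",
                         n_aa = 467,
                         abundance = 1e4,
                         dg_fold = -37,
                         k_d = 2.69e-4,
                         c_s = 1500,
                         c_d = 30,
                         mrna = 1e-4 * abundance,
                         k_fold = 1e-5) {
  tb <- tibble::tibble(
    name = as.character(name), n_aa = n_aa, abundance = abundance,
    dg_fold = dg_fold, k_d = k_d, c_s = c_s, c_d = c_d,
    mrna = mrna, k_fold = k_fold
  )
  validate_proteome(tb)
}

#' Validate a proteome table
#'
#' Checks the column set and the per-protein invariants (positive lengths and
#' rates, non-negative abundances and costs, finite free energies, mRNA
#' present wherever abundance is positive). Positive `dg_fold` is allowed
#' here (a genuinely unstable protein); stabilities quoted with the positive
#' sign convention are negated at the I/O boundary by [read_proteome()].
#'
#' @param proteome A data frame of proteins.
#' @return The validated proteome as a tibble.
#' @export
validate_proteome <- function(proteome) {
  proteome <- tibble::as_tibble(proteome)
  required <- c("name", "n_aa", "abundance", "dg_fold", "k_d", "c_s", "c_d")
  missing <- setdiff(required, names(proteome))
  if (length(missing) > 0) {
    abort(paste0("Proteome is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"mrna" %in% names(proteome)) proteome$mrna <- 1e-4 * proteome$abundance
  if (!"k_fold" %in% names(proteome)) proteome$k_fold <- 1e-5
  if (nrow(proteome) == 0) return(proteome)
  bad <- function(cond, msg) {
    if (any(cond)) {
      abort(sprintf("Invalid proteome row(s) %s: %s",
                    paste(which(cond), collapse = ", "), msg))
    }
  }
  bad(proteome$n_aa < 1, "n_aa must be >= 1")
  bad(proteome$abundance < 0, "abundance must be >= 0")
  bad(proteome$k_d <= 0, "k_d must be > 0")
  bad(proteome$c_s < 0 | proteome$c_d < 0, "costs must be >= 0")
  bad(!is.finite(proteome$dg_fold), "dg_fold must be finite")
  bad(proteome$abundance > 0 & proteome$mrna <= 0,
      "mrna must be > 0 when abundance > 0")
  proteome
}

# column mapping between in-memory names and the TSV header
.proteome_tsv_cols <- c(
  name = "name", n_aa = "n_aa", abundance = "abundance",
  dg_fold = "dg_fold_kj", k_d = "k_d_s", c_s = "c_s_kj", c_d = "c_d_kj",
  mrna = "mrna", k_fold = "k_fold"
)

#' Read and write proteome tables as TSV
#'
#' The on-disk schema uses unit-suffixed headers: `name, n_aa, abundance,
#' dg_fold_kj, k_d_s, c_s_kj, c_d_kj, mrna, k_fold` (the last two optional).
#' Unknown columns are preserved with a warning; rows violating the proteome
#' invariants are rejected with their line numbers. Free energies quoted as
#' positive "stabilities" (a common convention) are negated on input, with a
#' loud message, so that in-memory tables always use dg_fold < 0 = stable.
#'
#' @param path File path.
#' @param proteome A proteome tibble.
#' @return `read_proteome()` returns a validated proteome tibble;
#'   `write_proteome()` returns `proteome` invisibly.
#' @export
read_proteome <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  attr(raw, "spec") <- NULL
  attr(raw, "problems") <- NULL
  known <- .proteome_tsv_cols
  extra <- setdiff(names(raw), unname(known))
  if (length(extra) > 0) {
    warn(paste0("Preserving unknown proteome column(s): ",
                paste(extra, collapse = ", ")))
  }
  present <- known[known %in% names(raw)]
  out <- raw
  names(out)[match(present, names(out))] <- names(present)
  required <- c("name", "n_aa", "abundance", "dg_fold", "k_d", "c_s", "c_d")
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    abort(paste0("Proteome TSV is missing column(s): ",
                 paste(.proteome_tsv_cols[missing], collapse = ", ")))
  }
  flip <- out$dg_fold > 0
  if (any(flip)) {
    inform(sprintf(
      "%d positive dg_fold value(s) in %s interpreted as stabilities and negated (stable proteins have dg_fold < 0).",
      sum(flip), path
    ))
    out$dg_fold[flip] <- -out$dg_fold[flip]
  }
  tryCatch(validate_proteome(out), error = function(e) {
    abort(paste0("While reading ", path, ": ", conditionMessage(e),
                 " (line numbers exclude the header)"))
  })
}

#' @rdname read_proteome
#' @export
write_proteome <- function(proteome, path) {
  proteome <- validate_proteome(proteome)
  out <- proteome
  known <- .proteome_tsv_cols[names(.proteome_tsv_cols) %in% names(out)]
  names(out)[match(names(known), names(out))] <- unname(known)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(proteome)
}

#' Generate a synthetic proteome
#'
#' Draws a proteome with the broad statistical structure of the yeast
#' proteome: abundances log-uniform across five orders of magnitude (so small
#' samples still cover the full expression range), lengths from a right-skewed
#' gamma distribution with mean 467 residues, half-lives lognormal around a
#' 43-minute median (k_d = ln 2 / half-life), and folding free energies
#' Gaussian around -37 kJ/mol truncated above -0.5 kJ/mol so every protein is
#' at least marginally stable. Per-residue handling costs are constant at
#' their defaults. The draw is fully reproducible from `seed`.
#'
#' @param n_proteins Number of proteins to generate.
#' @param abundance_log10_range Range of log10 abundance (default `c(0, 5)`).
#' @param length_mean Mean chain length in residues (default 467).
#' @param length_shape Gamma shape for the length distribution (default 4).
#' @param half_life_median_min Median half-life in minutes (default 43).
#' @param half_life_log_sd Lognormal sd of half-life (default 1).
#' @param dg_mean_kj,dg_sd_kj Mean and sd of the folding free energy, kJ/mol.
#' @param c_s_kj,c_d_kj Per-residue synthesis and degradation costs, kJ/mol.
#' @param seed Mandatory integer seed.
#' @return A validated proteome tibble with `n_proteins` rows.
#' @examples
#' prot <- generate_proteome(100, seed = 1)
#' mean(prot$n_aa)
#' @export
generate_proteome <- function(n_proteins,
                              abundance_log10_range = c(0, 5),
                              length_mean = 467,
                              length_shape = 4,
                              half_life_median_min = 43,
                              half_life_log_sd = 1,
                              dg_mean_kj = -37,
                              dg_sd_kj = 8,
                              c_s_kj = 1500,
                              c_d_kj = 30,
                              seed) {
  if (missing(seed)) abort("`seed` is mandatory for reproducible generation.")
  if (n_proteins < 1) abort("`n_proteins` must be >= 1.")
  if (!all(is.finite(abundance_log10_range)) ||
      diff(abundance_log10_range) < 0) {
    abort("`abundance_log10_range` must be a finite increasing range.")
  }
  withr::with_seed(seed, {
    abundance <- 10^runif(n_proteins, abundance_log10_range[1],
                          abundance_log10_range[2])
    n_aa <- pmax(1, round(rgamma(n_proteins, shape = length_shape,
                                 scale = length_mean / length_shape)))
    half_life_s <- rlnorm(n_proteins, meanlog = log(half_life_median_min * 60),
                          sdlog = half_life_log_sd)
    dg <- rnorm(n_proteins, dg_mean_kj, dg_sd_kj)
    # truncate: redraw anything less stable than -0.5 kJ/mol
    while (any(dg > -0.5)) {
      i <- dg > -0.5
      dg[i] <- rnorm(sum(i), dg_mean_kj, dg_sd_kj)
    }
    validate_proteome(tibble::tibble(
      name = sprintf("synth_%04d", seq_len(n_proteins)),
      n_aa = n_aa,
      abundance = abundance,
      dg_fold = dg,
      k_d = log(2) / half_life_s,
      c_s = c_s_kj,
      c_d = c_d_kj,
      mrna = 1e-4 * abundance,
      k_fold = 1e-5
    ))
  })
}
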