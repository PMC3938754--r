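# Cell model in "paper parity" mode: RT fixed at 2.5 kJ/mol, the round value
# at which the classic worked steady-state numbers are quoted.
paper_cell <- function(...) cell_model(rt_override = 2.5, ...)

# A coarse stability grid for fast kernel tests.
coarse_config <- function(...) {
  evolve_config(grid_min = -12, grid_max = -1, grid_step = 0.25, ...)
}

default_protein <- function(...) protein_spec(...)

# edit columns of a one-row proteome tibble
within_df <- function(df, ...) {
  edits <- list(...)
  for (nm in names(edits)) df[[nm]] <- edits[[nm]]
  df
}
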