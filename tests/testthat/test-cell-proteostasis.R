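test_that("thermal energy follows RT and honours the override", {
  expect_equal(thermal_energy(cell_model(temperature = 300.7)), 2.500, tolerance = 1e-3)
  expect_equal(thermal_energy(cell_model(temperature = 310.15)), 2.5786, tolerance = 1e-4)
  expect_identical(thermal_energy(cell_model(rt_override = 2.5)), 2.5)
})

test_that("cell model invariants are enforced", {
  expect_error(cell_model(temperature = -1), "temperature")
  expect_error(cell_model(repro_fraction = 0), "repro_fraction")
  expect_error(cell_model(repro_fraction = 1.5), "repro_fraction")
  expect_error(cell_model(nonproteome_fraction = 1), "nonproteome_fraction")
  expect_error(cell_model(n_eff = 0), "n_eff")
  expect_error(cell_model(n_eff = 100, n_census = 10), "n_census")
})

test_that("unfolded count matches the worked steady-state numbers", {
  cell <- paper_cell()
  expect_equal(
    signif(unfolded_count(protein_spec(abundance = 1e5), cell), 2), 0.037)
  expect_equal(
    signif(unfolded_count(protein_spec(abundance = 1e5, dg_fold = -25), cell), 2), 4.5)
  # 50 million average-stability copies carry ~19 unfolded copies in total
  expect_equal(
    round(unfolded_count(protein_spec(abundance = 5e7), cell)), 19)
})

test_that("unfolded count limits: dG = 0 gives A/2, A = 0 gives 0, saturation at A", {
  cell <- paper_cell()
  a <- 1234
  expect_equal(unfolded_count(protein_spec(abundance = a, dg_fold = 0), cell), a / 2)
  expect_equal(unfolded_count(protein_spec(abundance = 0, dg_fold = -10, mrna = 1), cell), 0)
  destab <- within_df(protein_spec(abundance = a), dg_fold = 5000)
  expect_equal(unfolded_count(destab, cell), a)
  expect_equal(unfolded_count(destab, cell, approximate = TRUE), a)
})

test_that("exact mode conserves copies and the approximation error is bounded", {
  cell <- cell_model()
  dgs <- seq(-60, -1, by = 3.7)
  prot <- validate_proteome(purrr::map_dfr(dgs, ~ protein_spec(dg_fold = .x)))
  u <- unfolded_count(prot, cell)
  f <- folded_count(prot, cell)
  expect_equal(u + f, prot$abundance, tolerance = 1e-12)
  u_app <- unfolded_count(prot, cell, approximate = TRUE)
  rel <- abs(u_app - u) / u
  # the over-estimate factor is exactly 1 + exp(dG/RT); allow float headroom
  # for the cancellation in (approx - exact) at very stable dG
  expect_true(all(rel <= exp(prot$dg_fold / thermal_energy(cell)) * (1 + 1e-3)))
})

test_that("unfolded count increases with dG and with temperature", {
  a <- 1e5
  dgs <- seq(-50, -5, by = 5)
  prot <- purrr::map_dfr(dgs, ~ protein_spec(abundance = a, dg_fold = .x))
  u <- unfolded_count(prot, cell_model())
  expect_true(all(diff(u) > 0))
  temps <- seq(280, 360, by = 10)
  u_t <- vapply(temps, function(tt) {
    unfolded_count(protein_spec(abundance = a), cell_model(temperature = tt))
  }, numeric(1))
  expect_true(all(diff(u_t) > 0))
})

test_that("folded probability follows the two-state Boltzmann form", {
  cell <- paper_cell()
  expect_equal(prob_folded(protein_spec(dg_fold = 0), cell), 0.5)
  expect_equal(prob_folded(protein_spec(dg_fold = -500), cell), 1)
  expect_equal(1 - prob_folded(protein_spec(), cell), 3.7e-7, tolerance = 0.01)
})

test_that("synthesis rate is the steady-state flux with the ribosome/folding cap alongside", {
  cell <- paper_cell()
  prot <- protein_spec(abundance = 1e5, dg_fold = 0, mrna = 1)
  ks <- synthesis_rate(prot, cell)
  u <- unfolded_count(prot, cell)
  expect_equal(ks$k_s, 2 * prot$k_d * u / prot$mrna)
  expect_equal(ks$k_s_cap, min(15 / 467, 1e-5))
  expect_equal(ribosome_rate_constant(467), 3.21e-2, tolerance = 1e-3)
  # zero unfolded pool means zero synthesis flux
  frozen <- protein_spec(abundance = 0, mrna = 1)
  expect_equal(synthesis_rate(frozen, cell)$k_s, 0)
  # an mRNA-free but expressed protein is an inconsistent specification
  expect_error(
    synthesis_rate(within_df(protein_spec(), mrna = 0), cell), "mrna")
})

test_that("maintenance power matches the hand-computed per-copy rate and is linear", {
  cell <- cell_model()
  prot <- protein_spec(abundance = 1e5)
  u <- unfolded_count(prot, cell)
  # per unfolded copy: 467 * 2.69e-4 * (2*1500 + 30) * 1000 / 6.022e23
  expect_equal(maintenance_power(prot, cell) / u, 6.32e-19, tolerance = 1e-3)
  expect_equal(maintenance_power(within_df(prot, abundance = 0, mrna = 1), cell), 0)
  # doubling c_s with c_d = 0 doubles the cost
  p1 <- within_df(prot, c_d = 0)
  p2 <- within_df(p1, c_s = 2 * p1$c_s)
  expect_equal(maintenance_power(p2, cell), 2 * maintenance_power(p1, cell))
  # linear in abundance at fixed dG
  expect_equal(maintenance_power(within_df(prot, abundance = 3e5, mrna = 30), cell),
               3 * maintenance_power(prot, cell))
})

test_that("proteome maintenance is additive and zero for an empty proteome", {
  cell <- cell_model()
  one <- protein_spec()
  two <- dplyr::bind_rows(one, one)
  expect_equal(proteome_maintenance(one[0, ], cell), 0)
  expect_equal(proteome_maintenance(one, cell), maintenance_power(one, cell))
  expect_equal(proteome_maintenance(two, cell), 2 * maintenance_power(one, cell))
})

test_that("steady_state appends consistent per-protein columns", {
  cell <- paper_cell()
  prot <- generate_proteome(20, seed = 42)
  ss <- steady_state(prot, cell)
  expect_equal(ss$u + ss$f, prot$abundance, tolerance = 1e-12)
  expect_true(all(ss$p_folded >= 0 & ss$p_folded <= 1))
  expect_true(all(ss$cost_power >= 0))
  expect_equal(ss$u, unfolded_count(prot, cell))
})

test_that("protein mass follows residue count", {
  expect_equal(protein_mass(467), 60710)
})

test_that("positive dg_fold on file is read as a stability and negated loudly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  prot <- protein_spec()
  prot$dg_fold <- 37 # positive "stability" convention
  readr::write_tsv(
    setNames(prot, proteocost:::.proteome_tsv_cols[names(prot)]), path)
  expect_message(out <- read_proteome(path), "negated")
  expect_equal(out$dg_fold, -37)
})
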