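test_that("energy budget matches the default yeast bookkeeping", {
  cell <- cell_model()
  expect_equal(reproductive_power(cell), 2.04e-12, tolerance = 1e-6)
  expect_equal(maintenance_budget(cell), 1.84e-11, tolerance = 1e-2)
  expect_equal(proteome_power(cell), 2.04e-11, tolerance = 1e-6)
  expect_equal(reproductive_power(cell_model(der_override = 3e-12)), 3e-12)
})

test_that("cost coefficient resolves into turnover and handling parameters", {
  cell <- cell_model()
  expect_equal(cost_coefficient(protein_spec(), cell), 3.10e-7, tolerance = 1e-2)
  # linear in k_d, zero when handling is free
  p <- protein_spec()
  expect_equal(cost_coefficient(within_df(p, k_d = 2 * p$k_d), cell),
               2 * cost_coefficient(p, cell))
  expect_equal(cost_coefficient(within_df(p, c_s = 0, c_d = 0), cell), 0)
})

test_that("fitness modes behave as energy balances", {
  cell <- cell_model()
  empty <- protein_spec()[0, ]
  expect_equal(fitness(empty, cell, mode = "self_consistent"), proteome_power(cell))
  wt <- protein_spec(abundance = 1e4)
  expect_equal(fitness(wt, cell, reference = wt), reproductive_power(cell))
  # adding expressed protein strictly decreases self-consistent fitness
  more <- dplyr::bind_rows(wt, protein_spec(name = "extra", abundance = 100))
  expect_lt(fitness(more, cell, mode = "self_consistent"),
            fitness(wt, cell, mode = "self_consistent"))
})

test_that("selection coefficient reproduces the compensatory-expression worked numbers", {
  cell <- paper_cell()
  wt <- protein_spec(abundance = 1e4)
  expect_equal(selection_coefficient(wt, wt, cell)$s, 0)
  s1 <- selection_coefficient(wt, protein_spec(abundance = 1e5), cell)
  expect_equal(signed_order_of_magnitude(s1$s), -1e-8)
  s2 <- selection_coefficient(protein_spec(abundance = 1e5),
                              protein_spec(abundance = 1e6), cell)
  expect_equal(signed_order_of_magnitude(s2$s), -1e-7)
  expect_lt(s1$s, 0)
  expect_equal(s1$delta_cost / reproductive_power(cell), -s1$s)
})

test_that("self-consistent mode obeys the swap identity s' = -s/(1+s)", {
  cell <- cell_model()
  wt <- protein_spec(abundance = 1e4, dg_fold = -10)
  mut <- protein_spec(abundance = 8e4, dg_fold = -10)
  s <- selection_coefficient(wt, mut, cell, mode = "self_consistent")$s
  s_swap <- selection_coefficient(mut, wt, cell, mode = "self_consistent")$s
  expect_equal(s_swap, -s / (1 + s), tolerance = 1e-12)
})

test_that("stability shortcut matches the worked destabilisation numbers", {
  cell <- paper_cell()
  prot <- protein_spec(abundance = 1e5)
  expect_equal(s_stability(prot, prot$dg_fold, cell)$s, 0)
  res <- s_stability(prot, -25, cell)
  expect_equal(abs(res$s), 1.39e-6, tolerance = 1e-2)
  expect_gte(abs(res$s), 1e-6)
  expect_equal(res$delta_u, 4.5, tolerance = 1e-2)
  # stabilising mutations are beneficial
  expect_gt(s_stability(prot, -45, cell)$s, 0)
})

test_that("stability shortcut equals the general two-proteome coefficient", {
  cell <- paper_cell()
  for (dg_mut in c(-40, -30, -25, -15)) {
    prot <- protein_spec(abundance = 1e5)
    s_short <- s_stability(prot, dg_mut, cell)$s
    mut <- within_df(prot, dg_fold = dg_mut)
    s_gen <- selection_coefficient(prot, mut, cell, approximate = TRUE)$s
    expect_equal(s_short, s_gen, tolerance = 1e-9)
    # exact-mode agreement is limited only by the U approximation itself
    s_exact <- selection_coefficient(prot, mut, cell)$s
    expect_equal(s_short, s_exact,
                 tolerance = 10 * exp(dg_mut / thermal_energy(cell)))
  }
})

test_that("legacy log and linear selection forms agree to four digits for small s", {
  forms <- s_misfolding_legacy(c = 1e-3, u_wt = 0, u_mut = 1)
  expect_equal(forms$s_log, forms$s_linear, tolerance = 1e-3)
  expect_equal(forms$s_linear, -1e-3)
  zero <- s_misfolding_legacy(c = 0.5, u_wt = 3, u_mut = 3)
  expect_equal(zero$s_log, 0)
  expect_equal(zero$s_linear, 0)
  # worked product: c = 3.10e-7 per copy, 4.5 extra copies
  prod <- s_misfolding_legacy(c = 3.10e-7, u_wt = 0, u_mut = 4.5)
  expect_equal(prod$s_linear, -1.39e-6, tolerance = 1e-2)
  # four-decimal-digit (absolute < 1e-4) agreement across |s| up to 0.01,
  # the linearisation error being of order s^2/2
  for (cu in 10^seq(-6, -2)) {
    f <- s_misfolding_legacy(c = cu, u_wt = 0, u_mut = 1)
    expect_lt(abs(f$s_log - f$s_linear), 1e-4)
    expect_lt(abs(f$s_log - f$s_linear), cu^2 * 0.51)
  }
  # in the realistic regime (c*U << 1) agreement is relative as well
  f_real <- s_misfolding_legacy(c = 3.1e-7, u_wt = 0.037, u_mut = 4.5)
  expect_lt(abs(f_real$s_log - f_real$s_linear) / abs(f_real$s_linear), 1e-4)
})

test_that("|s| factorises into the protein's cost product", {
  cell <- paper_cell()
  base_wt <- protein_spec(abundance = 1e4)
  base_mut <- protein_spec(abundance = 5e4)
  s_base <- selection_coefficient(base_wt, base_mut, cell, approximate = TRUE)$s
  scale_one <- function(col, factor) {
    wt <- within_df(base_wt); mut <- within_df(base_mut)
    wt[[col]] <- wt[[col]] * factor
    mut[[col]] <- mut[[col]] * factor
    selection_coefficient(wt, mut, cell, approximate = TRUE)$s
  }
  expect_equal(scale_one("n_aa", 3), 3 * s_base, tolerance = 1e-12)
  expect_equal(scale_one("k_d", 7), 7 * s_base, tolerance = 1e-12)
  # (2 c_s + c_d) scaling
  wt <- within_df(base_wt, c_s = 2 * base_wt$c_s, c_d = 2 * base_wt$c_d)
  mut <- within_df(base_mut, c_s = 2 * base_mut$c_s, c_d = 2 * base_mut$c_d)
  expect_equal(selection_coefficient(wt, mut, cell, approximate = TRUE)$s,
               2 * s_base, tolerance = 1e-12)
  # delta A scaling
  mut2 <- within_df(base_mut, abundance = 1e4 + 2 * (5e4 - 1e4), mrna = 10)
  expect_equal(selection_coefficient(base_wt, mut2, cell, approximate = TRUE)$s,
               2 * s_base, tolerance = 1e-12)
  # Boltzmann factor scaling via dG
  rt <- thermal_energy(cell)
  wt3 <- within_df(base_wt, dg_fold = base_wt$dg_fold + rt * log(2))
  mut3 <- within_df(base_mut, dg_fold = base_mut$dg_fold + rt * log(2))
  expect_equal(selection_coefficient(wt3, mut3, cell, approximate = TRUE)$s,
               2 * s_base, tolerance = 1e-9)
})

test_that("|s| scales inversely with the reproductive power", {
  wt <- protein_spec(abundance = 1e4)
  mut <- protein_spec(abundance = 1e5)
  s_slow <- selection_coefficient(wt, mut, paper_cell(specific_rate = 0.09))$s
  s_fast <- selection_coefficient(wt, mut, paper_cell(specific_rate = 0.9))$s
  expect_equal(s_slow, 10 * s_fast, tolerance = 1e-12)
})

test_that("selection landscape: zero diagonal, linearity in mutant abundance, turnover effect", {
  cell <- paper_cell()
  tpl <- protein_spec(abundance = 1e4)
  single <- selection_landscape(
    tpl, cell,
    list(name = "abundance_mut", values = 1e4),
    list(name = "abundance_wt", values = 1e4))
  expect_equal(as.vector(single$values), 0)
  grid <- selection_landscape(
    tpl, cell,
    list(name = "abundance_mut", values = seq(0, 1e5, length.out = 6)),
    list(name = "abundance_wt", values = 1e4))
  s_col <- grid$values[, 1]
  expect_equal(diff(s_col, differences = 2), rep(0, 4), tolerance = 1e-18)
  expect_true(all(diff(s_col) < 0))
  kd_grid <- selection_landscape(
    tpl, cell,
    list(name = "abundance_mut", values = 5e4),
    list(name = "k_d", values = c(1e-4, 1e-3, 1e-2)))
  expect_true(all(diff(as.vector(kd_grid$values)) < 0))
  expect_error(
    selection_landscape(tpl, cell,
                        list(name = "bogus", values = 1),
                        list(name = "k_d", values = 1e-3)),
    "Unknown axis")
})

test_that("landscape presets tidy into long tables with finite s", {
  grid <- landscape_preset("fig1b", n = 5)
  df <- tidy(grid)
  expect_named(df, c("abundance_mut", "k_d", "s"))
  expect_equal(nrow(df), 25)
  expect_true(all(is.finite(df$s)))
})
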