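---
title: "The proteostatic energy-cost model: turnover, selection, and the evolution of protein stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The proteostatic energy-cost model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteocost)
library(ggplot2)
```

# The model

`proteocost` treats organism fitness as the chemical energy left over for
reproduction after the cell has paid for maintaining its proteome. Every
protein $i$ is a two-state folder cycling through synthesis, folding,
unfolding and degradation at steady state. Its unfolded (more generally,
non-functional) pool follows the Boltzmann partition

$$U_i = A_i \frac{e^{\Delta G_i / RT}}{1 + e^{\Delta G_i / RT}}
      \approx A_i\, e^{\Delta G_i / RT},$$

where $A_i$ is the copy number, $\Delta G_i < 0$ the folding free energy,
and the single-exponential approximation is excellent for any protein more
stable than a few $RT$. Because degradation acts on the unfolded pool,
each protein drains maintenance power

$$P_i = N_{aa,i}\, k_{d,i}\, U_i\, (2 C_{s,i} + C_{d,i}) \cdot
        \frac{1000}{N_A} \quad [\mathrm{J\,s^{-1}}],$$

with $N_{aa,i}$ the chain length, $k_{d,i}$ the degradation rate constant,
and $C_{s,i}, C_{d,i}$ the per-residue synthesis and degradation costs in
kJ/mol (the factor 2 arises because the steady-state flux balance sends
each replaced copy through the unfolded pool twice). Summing over the
proteome and subtracting from the cell's proteome power budget gives the
fitness; comparing a mutant against the wild type, every shared term
cancels and the selection coefficient in `"paper"` mode is

$$s = -\frac{\Delta(\text{maintenance power})}{\mathrm{d}E_r/\mathrm{d}t},
\qquad
c_i = \frac{N_{aa,i}\, k_{d,i} (2C_{s,i}+C_{d,i})\cdot 1000}
           {N_A\, \mathrm{d}E_r/\mathrm{d}t},$$

where $\mathrm{d}E_r/\mathrm{d}t$ is the reproductive power and $c_i$ the
dimensionless fitness cost of carrying one extra unfolded copy of protein
$i$ at steady state. For a stability-changing mutation,
$s = -c_i A_i (e^{\Delta G'/RT} - e^{\Delta G/RT})$
(`s_stability()`). Fixation probabilities use the haploid Kimura diffusion
form

$$P_{fix}(s) = \frac{1 - e^{-2 s N_{eff}/N}}{1 - e^{-2 N_{eff} s}},$$

continuous at $s = 0$ with the neutral limit $1/N$.

Finally, long-term stability evolution is modelled as origin–fixation
dynamics on a discretised $\Delta G$ grid: the transition kernel weights
the bi-Gaussian distribution of mutational stability effects
($\Delta\Delta G$, kcal/mol, positive = destabilising) by the fixation
probability of each move, each row conditioned on one fixation per phase.
Iterating $P_{t+1} = K^\top P_t$ converges to the mutation–selection
equilibrium distribution of protein stabilities.

# Default parameters and their meaning

| parameter | default | units | meaning |
|---|---|---|---|
| `temperature` | 310.15 | K | 37 °C; enters only through $RT$ |
| `cell_mass` | 3.4e-11 | g | yeast cell |
| `specific_rate` | 0.9 | J s⁻¹ g⁻¹ | total metabolic rate |
| `nonproteome_fraction` | 1/3 | — | share of the rate spent outside the proteome |
| `repro_fraction` | 0.10 | — | fraction of proteome energy funding reproduction |
| `n_eff`, `n_census` | 1e7 | — | yeast-like effective population size |
| `n_aa` | 467 | residues | average yeast protein |
| `abundance` | 1e4 | copies | typical well-expressed protein |
| `dg_fold` | −37 | kJ/mol | average yeast protein stability |
| `k_d` | 2.69e-4 | s⁻¹ | 43-minute half-life |
| `c_s`, `c_d` | 1500, 30 | kJ/mol per residue | conservative synthesis cost; ~1 ATP to degrade |
| `mrna` | 1e-4 × abundance | copies | typical mRNA-to-protein ratio |
| ddG mixture | μ₁=0.56, μ₂=1.96, σ₁=0.90, σ₂=1.93 | kcal/mol | experimentally derived mutational-effect components |

These defaults give a reproductive power of 2.04e-12 J/s and a per-copy
cost $c_i \approx 3.1\times 10^{-7}$, so a mutation adding ~4.5 unfolded
copies is already visible to selection in a population of $10^7$.

Two parameters deserve comment.

**RT and "paper-parity" mode.** The physical $RT$ at 37 °C is
2.579 kJ/mol. Several classic worked numbers for unfolded copy counts
(0.037 copies at −37 kJ/mol and $A = 10^5$; 4.5 copies after a 12 kJ/mol
destabilisation; 19 copies in $5\times10^7$ average proteins) are quoted at
the round value $RT = 2.5$ kJ/mol. The package defaults to the physical
value; `cell_model(rt_override = 2.5)` reproduces the quoted numbers and is
what the worked-example tests use.

**The mixture weight `p1`.** The component means and widths of the
$\Delta\Delta G$ distribution are experimentally derived, but the weight on
the milder (surface) component is not. We default to $p_1 = 0.7$, which
places the mixture mean at 0.98 kcal/mol — matching the ~5 kJ/mol average
destabilisation of an arising mutation. Because this is a modelling choice,
the equilibrium-mode test verifies that the mode moves by less than
1 kcal/mol across $p_1 \in \{0.5, 0.7, 0.9\}$ (it does: the equilibrium is
set mainly by where selection overwhelms drift, not by the proposal shape).

# Numerical choices

* **Exact vs approximate $U$.** The logistic (exact) form is the default
  everywhere; the single-exponential approximation is available as
  `approximate = TRUE` and is the convention of the closed-form
  `s_stability()`. The two agree to a relative factor $e^{\Delta G/RT}$
  (~$10^{-7}$ for an average protein). Strongly destabilised inputs
  saturate at $U = A$ instead of overflowing.
* **Fixation near neutrality.** $P_{fix}$ is evaluated through `expm1()`,
  which is exact down to the smallest representable $|2 N_{eff} s|$; only
  $s = 0$ needs the explicit $1/N$ branch. At large $N$ the strongly
  deleterious tail underflows to exactly 0, which is the correct limit.
* **Grid and truncation.** The $\Delta G$ grid spans $[-15, -0.5]$ kcal/mol
  in 0.05 steps. Proposal mass falling outside the grid is truncated before
  row normalisation. The upper boundary is inert in practice: states near
  $-0.5$ kcal/mol are so costly that their fixation probabilities are
  effectively zero, so no probability current wants to cross it; the lower
  boundary is far below any equilibrium mass under the default scenarios.
* **Sign convention.** $\Delta\Delta G = \Delta G_j - \Delta G_i$ with
  positive = destabilising, consistent with the positive component means
  and the destabilising mutational drift. Grids are in kcal/mol (the unit
  in which stability distributions are usually reported); selection
  converts to kJ/mol internally with the factor 4.184.
* **Convergence.** Iteration stops when the total-variation distance
  between successive phases falls below $10^{-6}$ (hitting the cap flags
  the result instead of returning silently). The commonly quoted "~14
  mutations to convergence" depends on the significance level and sample
  size of the KS comparison used to declare convergence, so the package
  reports it only as a diagnostic (`ks_convergence_phase()`).
* **Monte-Carlo rejection envelope.** The origin–fixation sampler accepts
  a proposed move with probability $P_{fix}/M$. $M$ is computed per source
  state as 1.1 × the maximum $P_{fix}$ over destination grid points
  reachable from that state — a tight, valid bound because $P_{fix}$ is
  monotone in $s$ and $s$ is monotone in the destination Boltzmann factor.
  (A single global envelope would be dominated by the marginal-stability
  corner of the grid and push acceptance rates to ~$10^{-4}$ near
  equilibrium.) Accepted states are snapped to the nearest grid point so
  that the sampler and the kernel share one binning. One seeded vectorised
  RNG stream drives each `simulate_population()` call, which makes runs
  bitwise reproducible from the seed.

# What the synthetic proteome emulates — and what it does not

`generate_proteome()` draws abundances log-uniform over five orders of
magnitude (log-uniform rather than lognormal so that even small samples
cover the full expression range over which cost trends are claimed),
lengths from a gamma with mean 467 and shape 4 (right-skewed and positive;
only the mean is empirically constrained here), half-lives lognormal around
a 43-minute median, and stabilities Gaussian around −37 kJ/mol truncated at
−0.5 kJ/mol. It does **not** attempt to reproduce the empirical joint
distribution of abundance, length and stability in any real proteome — in
yeast these covary (abundant proteins are shorter and more stable), so
whole-proteome cost totals computed from synthetic tables are
order-of-magnitude exercises, not predictions. Tests passing on synthetic
proteomes demonstrate the bookkeeping and the trend structure of the model,
not agreement with any organism's measured proteome.

# Problem sizes used in the test-suite

The deterministic kernel is 291 × 291 and equilibrates in ~30–40 phases,
so full-accuracy equilibria are cheap; all equilibrium tests (including
the three-start independence and the `p1` sensitivity check) run at the
default grid. Monte-Carlo cross-checks use $10^4$ replicates for the
phase-wise KS comparisons and 3000 replicates for the long-run mode check;
the Wright–Fisher cross-check of the Kimura formula uses $N = 100$ and
30000 replicates. These sizes give comfortable statistical resolution for
every claim tested while keeping the whole suite in seconds.

# A worked session

```{r worked}
cell <- cell_model(rt_override = 2.5) # paper-parity RT
prot <- protein_spec(abundance = 1e5)
unfolded_count(prot, cell)
s_stability(prot, dg_mut = -25, cell)

eq <- equilibrium(protein_spec(abundance = 2^12), cell_model())
glance(eq)
```

```{r eqplot, fig.width = 6, fig.height = 3.5}
autoplot(eq$distribution)
```

```{r sweep, fig.width = 6, fig.height = 3.5}
sw <- stability_sweep("abundance", c(1e4, 1e6),
                      cell = cell_model(specific_rate = 2.8e-2))
plot_sweep(sw)
```

# Known limitations

* Folding kinetics enter only through the equilibrium ratio; there is no
  chaperone or refolding pathway and no time-dependent (non-steady-state)
  dynamics.
* Compensatory expression of hypomorphic mutants is an *input* (an
  abundance edit, possibly on several related genes), not something the
  package infers.
* Temperature sweeps treat $\Delta G$ as temperature-independent (no
  heat-capacity term): temperature acts only through $RT$.
* Whether the haploid or diploid Kimura variant should be used is not
  decidable from the model itself; the haploid form with
  $N = N_{eff}$ is the default, and the equilibrium results are
  insensitive to the factor of two near the drift boundary.
* Evolution is over the scalar $\Delta G$ only — no sequences, sites or
  codon structure, and strictly sequential origin–fixation dynamics (no
  clonal interference).
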