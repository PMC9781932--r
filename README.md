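# cosolve

Co-solvency modelling and green-solvent screening for drug-like solutes in
neat and binary aqueous–organic solvents.

Finding a solvent that dissolves an active pharmaceutical ingredient well
*and* is environmentally benign is a search problem over far more
solute–solvent–composition–temperature combinations than anyone can
measure. `cosolve` implements a screening workflow for this problem,
developed around acetaminophen and phenacetin as model aromatic amides: it
curates heterogeneous literature solubility data with classical
thermodynamic models, represents each saturated system by eight
COSMO-RS-style molecular descriptors, learns the descriptor-to-solubility
map with an admission-gated ensemble of shallow neural networks, and
screens candidate aqueous binaries under a strict environmental-index
filter, re-expressing the predictions as Jouyban–Acree parameters so they
can be used without the model.

It is aimed at physical-chemistry and pharmaceutics groups doing solubility
screening, and at anyone who needs the individual pieces: the λh and
Jouyban–Acree fitting machinery, a σ-profile/σ-potential toolkit, or a
reproducible gated-ensemble regressor with an applicability domain.

## The models

**Buchowski–Ksiazczak (λh)** — for one solute in one neat solvent, the
saturation mole fraction x at temperature T solves

    ln[1 + λ(1 − x)/x] = λ h (1/T − 1/T_m)

with adjustable λ (solute association) and h (solubilization energetics),
and T_m the melting temperature. The model passes through the pure melt
(x = 1 at T = T_m); `lambda_h_solubility()` finds the root by bisection and
`lambda_h_fit()` estimates (λ, h) by least squares in log10 x.

**Jouyban–Acree** — for a binary solvent with solute-free organic fraction
x₂\* (and x₃\* = 1 − x₂\*):

    ln x₁ = x₂* ln x₂,sat + x₃* ln x₃,sat + (x₂* x₃*/T) Σᵢ Jᵢ (x₂* − x₃*)ⁱ,  i = 0, 1, 2

linear in (J₀, J₁, J₂) once the neat anchors are fixed
(`jouyban_acree_fit()`, anchors from `ja_anchor()`). Both models drive the
two-pass outlier curation in `curate()`: fit, exclude records deviating by
more than 10 % from the back-computed values, refit — exactly twice, never
iterated.

**σ-profiles and descriptors** — each species is a histogram p(σ) of its
screening charge density. `sigma_potential()` solves the self-consistent
σ-potential μ_s(σ) of an environment (misfit + hydrogen-bond + dispersion
contact energies), and band averages over σ ∈ [−0.03, −0.01], [−0.01, 0.01]
and [0.01, 0.03] yield relative hydrogen-bond acceptance (HBA), donicity
(HBD) and hydrophobicity (HYD) descriptors. An iterative solid–liquid
equilibrium solver (`solve_saturation()`, anchored on T_m and ΔH_fus)
supplies a computed log-solubility descriptor, and profile-averaged contact
energies give total and relative interaction-energy descriptors — eight
inputs in all (`descriptor_vector()`).

**Gated ensemble** — `build_ensemble()` trains a pool of single-hidden-layer
networks (70/15/15 split, early stopping) and admits a member only if, on
validation data: RMSD < 0.06 log10 units, at most 2 % of residuals beyond
three standard deviations, and at least 99 % of predictions in the
physically admissible range (log10 x ≤ 0). Predictions are the member mean,
with a range-box + leverage applicability domain (h* = 3(p+1)/n).

**Screening** — `screen_system()` sweeps a composition grid, patches
spurious complete-miscibility points by linear extension of the last five
valid points, predicts with the ensemble, locates the optimal composition,
and `rank_solvents()` applies the strict EI < 0.5 green filter.

## Worked example

The package ships the measured solubility of acetaminophen (A) and
phenacetin (P) in aqueous DMSO, DMF and 4-formylmorpholine binaries:

```r
library(cosolve)
library(dplyr)

t1 <- table1_solubility()
a_dmso <- filter(t1, solute == "A", solvent1 == "DMSO")

optimal_composition(a_dmso)
#> [1] 0.8
to_log10(max(filter(a_dmso, temperature == 298.15)$x_solute))
#> [1] -0.5001755
```

The measured optimum for A in DMSO + water sits at 80 mol % DMSO with
log10 x ≈ −0.50 at 25 °C. The same series compresses into three
Jouyban–Acree parameters:

```r
fit <- jouyban_acree_fit(a_dmso,
  ja_anchor(filter(a_dmso, x2_star == 1)),   # neat DMSO anchor
  ja_anchor(filter(a_dmso, x2_star == 0)))   # neat water anchor
fit
#> Jouyban-Acree fit: J0 = 2651.37, J1 = -2243.25, J2 = 2017.45 (K)
#>   n = 24, back-fit MAPE = 8.92%
```

so the whole temperature-composition surface is reproduced within ~9 %
mean error by (J₀, J₁, J₂). Two-pass curation on synthetic data with two
planted gross outliers removes exactly those two records:

```r
syn <- make_solubility_dataset("lambda_h",
  list(lam = 0.4, h = 3000, t_m = 442.2),
  temperatures = seq(278.15, 338.15, 3), seed = 1, outliers = c(5, 15))
curate(syn$data, "lambda_h", t_m = 442.2)
#> curation report: 19 retained, 2 excluded (PE > 10%)
#>   MAPE 6.49% -> 1.11e-06%
```

Every result object supports `tidy()`, `glance()` and `autoplot()`.

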