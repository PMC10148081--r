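---
title: "Sorting partially occupied multienzyme particles and deriving assembly equilibrium attributes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sorting partially occupied multienzyme particles and deriving assembly equilibrium attributes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pccsort)
```

## The system and the model

Propionyl-CoA carboxylase (PCC) assembles as up to six α-subunits docked on
a stable β-homohexamer with D3 point-group symmetry: two trimeric rings of
α-β binding sites stacked on the β-core. Because α-subunits bind only to the
β-hexamer (no α–α contacts), each of the six sites is an independent binary
degree of freedom — occupied or unoccupied — and a particle's composition is
a 6-bit occupancy configuration. `pccsort` analyses the statistics of these
configurations in a cryoEM sample at equilibrium.

### Oligomeric isomers and formulae

The 2⁶ = 64 configurations are physically indistinguishable up to a
symmetry operation of the scaffold. The D3 group (order 6: identity, two
3-fold rotations, three 2-fold flips) acts on the sites; its orbits are the
*oligomeric isomers*, and orbits with the same number of bound α-subunits
share an *oligomeric formula* αₙβ₆. Brute-force orbit closure gives 16
isomers in 7 formulae (1, 1, 4, 4, 4, 1, 1 isomers for n = 0…6), and
Burnside's lemma supplies an independent count:
|G|⁻¹ Σ_g 2^{c(g)} = (2⁶ + 2·2² + 3·2³)/6 = 16,
where c(g) is the number of cycles of g on the six sites. Both routes are
implemented (`enumerate_orbits()`, `burnside_count()`) and tested against
each other for D3, C3, C2 and the trivial group.

**Site convention.** Sites are indexed `flat_index = 3·layer + position`
(layer ∈ {0,1}, position ∈ {0,1,2}). The 3-fold rotation advances
`position` mod 3; the 2-fold flip maps
`(layer, position) → (1 − layer, −position mod 3)`. Any conjugate choice of
2-fold axes (through-site vs between-site) yields the same orbit counts;
only the orbit *representatives* depend on it, so a single canonical
convention is exposed and representatives are defined as the
lexicographically minimal orbit member — stable identifiers across runs.
The group is stored extensionally (six explicit permutations) so closure is
trivially checkable.

### The sorting method

Real pipelines cannot classify 16 near-identical 3D isomers directly.
Instead each refined particle is symmetry-expanded into six copies (one per
D3 operator), a mask over a single α-subunit site is applied, and focused
two-class 3D classification labels each copy α-present or α-missing. The
number of α-missing labels k among a particle's six copies equals its
number of unoccupied sites, so the particle's formula is n = 6 − k.
`count_missing_per_particle()` implements exactly this count and
`formula_distribution()` tallies the formula histogram N₀…N₆. Malformed
particle records (≠ 6 copies, duplicated copy index, unknown label) error
by default — silent particle loss would bias the downstream count ratios —
with an explicit `skip_malformed` opt-out that warns with a count.

### Equilibrium attributes

The sample is at equilibrium, so each assembly step
αₙβ₆ + α ⇌ αₙ₊₁β₆ has an equilibrium constant
Kc = [αₙ₊₁β₆]/([αₙβ₆]·[α]). Free α-subunits are too small to be seen in
the images, so [α] is unobservable; it is assumed constant (continuous
assembly/disassembly at steady state), and only the product
Kc[α] = [αₙ₊₁β₆]/[αₙβ₆] is estimated — as the particle-count ratio
rₙ = Nₙ₊₁/Nₙ, since counts are proportional to concentrations and the
proportionality cancels in the ratio. `fit_exponential_decay()` fits
ln rₙ = ln A − λn by ordinary least squares, reporting R² on the log scale.

The null model against which decay is judged is *identical independent
sites*: if every site is occupied with odds θ = p/(1−p), then
Nₙ ∝ C(6,n)·θⁿ and rₙ = ((6−n)/(n+1))·θ — the classical statistical-factor
decline. `independent_site_ratios()` returns this sequence and
`estimate_theta()` inverts it by maximum likelihood
(p̂ = Σ n·Nₙ / (6·ΣNₙ), the Binomial(6, p) MLE), with a 95% CI formed on
the logit scale by normal approximation and mapped to the odds scale.
Whether observed decay *exceeds* the statistical-factor prediction (i.e.
cooperativity) is exposed as a comparison (`equilibrium_analysis()`,
`plot()`), not asserted as a conclusion.

## The synthetic generator: what it emulates, and what a green test shows

`sample_true_occupancy()` draws per-particle true occupancy either
independently per site at probability `p` (the stationary-occupancy reading
of constant [α] with identical sites) or from explicit formula weights
(configurations uniform within a formula — exchangeable sites).
`apply_classification_error()` then emits the six expanded records per
particle, copy k interrogating site `flat_index = k` (the simplest faithful
abstraction of one fixed focused mask applied after symmetry expansion),
with independent per-copy label flips at rates `eps_fn`/`eps_fp`.

Defaults are the stated world of the method: classification error defaults
to **zero**, because the real sorting procedure treats focused
classification as error-free; the noisy layer exists for robustness
analysis only, and no realistic error magnitude is asserted (none is
known). Worked examples use `p = 0.8` (θ = 4), chosen once as a realistic
mostly-assembled population — most particles α₅β₆/α₆β₆, matching the
qualitative composition reported for the real sample — and not tuned
thereafter.

The generator emulates classification *output*, not micrographs: no
projection images, CTF, orientation bias, or per-particle signal variation.
A green pipeline test therefore establishes that the counting, sorting and
equilibrium arithmetic are correct under the stated statistical model — it
says nothing about whether a real classifier achieves label error small
enough for the noiseless reading, nor about reconstruction quality.

## Numerical choices

- **Zero counts.** With pseudocount 0 (default), rₙ is flagged undefined
  when Nₙ = 0 rather than fabricated; a Haldane-style pseudocount 0.5 is
  available explicitly. The fit errors (rather than silently dropping to a
  degenerate line) when fewer than two usable positive ratios remain, or
  when a defined ratio is 0.
- **Fit weighting.** The exponential fit is unweighted OLS on the log scale
  by default (the fitting procedure behind the real figure is unstated); a
  count-weighted variant is available via the `weights` argument.
- **Error deconvolution.** The observed k-histogram is the true n-histogram
  mixed by M[k, n] = P(k missing labels | n occupied sites), the
  convolution of Binomial(n, eps_fn) and Binomial(6−n, 1−eps_fp).
  Correction solves M·x = observed by least squares, clips negative
  components to zero and rescales to preserve the total — an estimator
  returning real-valued expected counts, not a relabeling. It requires
  eps_fn + eps_fp < 1 and refuses condition numbers above 1e8.
- **Determinism.** Every stochastic operation takes an explicit seed and
  uses one global RNG stream per call; STAR/TSV/JSON writers produce
  byte-identical output for identical inputs, and the seed plus full
  configuration are echoed into output headers as comments.
- **CI method.** The θ interval is a normal approximation on logit(p);
  exact small-sample intervals are out of scope at the particle counts this
  method needs anyway (10⁴–10⁵).

## Degenerate inputs

All-empty or all-full samples leave θ unbounded (`estimate_theta()`
errors); distributions concentrated on one formula leave at most one ratio
defined (fit errors); `eps_fn + eps_fp ≥ 1` makes present/missing labels
uninformative (correction errors). These are hard errors by design: each
signals data that cannot support the quantity requested.

## Known limitations

- The formula, not the isomer, is the observable of the sorting method on
  real data: which of the four α₄/α₃/α₂ isomers a particle is remains
  simulation-only.
- β-hexamer stoichiometry is fixed at 6; β dissociation is not modelled.
- The STAR dialect is the minimal single-block `loop_` subset; real RELION
  tables need the documented adapter mapping duplicated image names to
  particle ids.
- Counts proxy concentrations up to a common factor; absolute Kc and [α]
  are not estimable from images alone.

## A small demonstration

```{r demo}
print(enumerate_orbits(point_group("D3")))

tr   <- sample_true_occupancy(binding_model(p = 0.8), 20000, seed = 1)
rec  <- apply_classification_error(tr, error_model(), seed = 2)
dist <- formula_distribution(count_missing_per_particle(rec))
res  <- equilibrium_analysis(dist)
print(res)
```

The fitted λ is positive and R² on the log scale is high: the ratio decay
is close to exponential, as the statistical-factor model predicts for this
generator, and θ̂ recovers the generating odds p/(1−p) = 4 within its CI.
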