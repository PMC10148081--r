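# pccsort

Statistical-mechanics analysis of compositional heterogeneity in a
D3-symmetric α6β6 multienzyme complex (propionyl-CoA carboxylase, PCC)
from symmetry-expanded cryoEM particle metadata.

PCC assembles as up to six α-subunits docked on a stable β-homohexamer.
In a cryoEM sample at equilibrium, particles coexist with different
numbers of bound α-subunits: each of the six α-β binding sites is either
occupied or unoccupied, giving 2⁶ = 64 occupancy configurations, which
collapse under the D3 point-group symmetry of the scaffold into **16
oligomeric isomers** sharing **7 oligomeric formulae** αₙβ₆ (n = 0…6).
`pccsort` provides, for structural biologists analysing such partial
occupancy:

- **Isomer enumeration** — orbits of binding-site occupancy patterns under
  D3 (with C3/C2/trivial subgroups as cross-checks), verified against
  Burnside's lemma: the orbit count is |G|⁻¹ Σ_g 2^{c(g)} where c(g) is the
  number of cycles of g on the six sites.
- **The sorting method** — each particle is symmetry-expanded into six
  copies, each copy focused-classified as α-present or α-missing; counting
  the α-missing labels k per particle assigns the formula n = 6 − k, and
  tallying particles gives the formula frequency distribution N₀…N₆.
- **Equilibrium mechanics** — for the stepwise reaction
  αₙβ₆ + α ⇌ αₙ₊₁β₆ with Kc = [αₙ₊₁β₆]/([αₙβ₆][α]) and constant free [α],
  the product Kc[α] is estimated as the count ratio rₙ = Nₙ₊₁/Nₙ, fit to an
  exponential decay A·e^{−λn}, and compared with the independent-site
  statistical-factor prediction rₙ = ((6−n)/(n+1))·θ where θ is the
  per-site occupancy odds.
- **A synthetic particle generator** emulating symmetry-expanded
  focused-classification output (stationary per-site binding, optional
  per-copy label noise) plus a minimal STAR-dialect reader/writer and CLI.

## Worked example

```r
library(pccsort)

enumerate_orbits(point_group("D3"))
#> Isomer census under D3 symmetry: 16 oligomeric isomers, 7 oligomeric formulae
#> isomers per formula alpha_n beta_6:
#> 0 1 2 3 4 5 6
#> 1 1 4 4 4 1 1

# simulate 20,000 particles, 80% per-site occupancy, error-free labels
tr   <- sample_true_occupancy(binding_model(p = 0.8), 20000, seed = 1)
rec  <- apply_classification_error(tr, error_model(), seed = 2)
dist <- formula_distribution(count_missing_per_particle(rec))
equilibrium_analysis(dist)
#> Stepwise Kc[alpha] ratios (N_{n+1}/N_n):
#>  n     ratio defined
#>  0        NA   FALSE
#>  1 8.5588235    TRUE
#>  2 5.7147766    TRUE
#>  3 2.9031870    TRUE
#>  4 1.6445733    TRUE
#>  5 0.6604534    TRUE
#> Exponential decay fit: A = 18.51, lambda = 0.6369, R^2(log) = 0.9832
#> Independent-site occupancy odds: theta_hat = 4.017 (95% CI 3.96-4.074)
```

Reading the output: most particles are α₅β₆/α₆β₆, so r₀ is undefined
(N₀ = 0) and the defined ratios fall roughly e-fold per added α-subunit
(λ ≈ 0.64) — close to the pure statistical-factor decline for independent
sites at odds θ ≈ 4, which is exactly the generating model (p = 0.8,
θ = p/(1−p) = 4, inside the 95% CI).

## Command line

```sh
PCCSORT=$(Rscript -e 'cat(system.file("exec/pccsort", package = "pccsort"))')
Rscript $PCCSORT enumerate --group D3
Rscript $PCCSORT simulate --n-particles 20000 --binding-prob 0.8 --seed 1 \
    --out particles.star --truth-out truth.tsv
Rscript $PCCSORT sort --in particles.star --out dist.tsv
Rscript $PCCSORT equilibrium --in dist.tsv --out report.json --plot fig.pdf
```

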