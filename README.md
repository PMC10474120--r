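# ppekinetics

Reactivity ratios and chain microstructure of polyphosphoester (PPE)
copolymers from real-time ³¹P NMR kinetics.

## The problem

In the organocatalyzed ring-opening copolymerization (ROP) of cyclic
phosphoesters, two or three comonomers compete for the same living chain
ends. How fast each monomer is consumed relative to the others — the
reactivity ratios — decides whether the product is a random, gradient or
block-like copolymer, and with it the amphiphilicity, self-assembly and
MRI traceability of the material. Because every phosphoester species has a
resolved ³¹P resonance for both its monomer and its incorporated unit,
quantitative real-time ³¹P NMR gives per-species conversion trajectories
for free, and the whole microstructure question reduces to fitting a
kinetic model to integral time series.

`ppekinetics` implements that analysis as a tested pipeline for polymer
chemists: integral tables → conversions → reactivity ratios (three
nonterminal estimators) → gradient classification → Monte Carlo chain
microstructure → a polymer-level report (DPs, compositions, Mₙ). A
synthetic data generator with presets for ten published binary/ternary
PPE systems makes every stage testable without spectrometer data.

## The model

Living organocatalytic ROP is chain-end independent ("nonterminal"): each
monomer i is consumed first order in itself,
d[Mᵢ]/dt = −kᵢ·[Mᵢ]·[P*]. Writing aᵢ = [Mᵢ]/[Mᵢ]₀ for the surviving
fraction, all observables depend only on rate ratios:

- **Drift law:** a_B = a_A^(1/r), with r = k_A/k_B, so r₁·r₂ = 1 and
  r_xz = r_xy·r_yz hold exactly.
- **Jaacks:** r₁ is the through-origin slope of ln(1/(1−x_A)) on
  ln(1/(1−x_B)).
- **BSL (Beckingham–Sanoja–Lynd):** least squares of
  x_B vs 1 − (1−x_A)^(1/r) directly in conversion–conversion coordinates.
- **Ideal integrated:** least squares of the instantaneous unreacted-feed
  fraction f_A against the integrated composition curve f_A(X; r) in
  total-conversion coordinates.

The three estimators are reparametrizations of one curve and agree to
~1e−6 on noise-free data; their across-model mean ± sd is the reported
ratio. Gradient strength is Δr = r₁ − r₂ (ordered r₁ ≥ r₂), classified
soft (0, 1.5], medium (1.5, 7.5], hard (7.5, 25], block-like (25, ∞).
Fits use data up to 60 % total conversion. Chain microstructure comes
from a seeded Monte Carlo: chains grow round-robin (dispersity exactly 1)
from a shared depleting pool, drawing species i with probability
kᵢNᵢ/ΣkⱼNⱼ.

## Worked example

Synthetic rerun of the PhPPn/MePPn copolymerization (preset P1: feed
≈ 50/50, total conversion 93 %, Δr = 5):

```r
library(ppekinetics)

cfg <- preset("P1", noise_sigma = 0.02, seed = 101)
ds  <- generate_kinetics(cfg)              # 40 spectra, 2 species
tr  <- truncate_conversions(conversions(ds), x_max = 0.60)
fp  <- fit_pair(tr, cfg$rates$species)     # ideal + jaacks + bsl
fp$average
#> <reactivity_average> PhPPn/MePPn over {ideal, jaacks, bsl}:
#>     r1 = 5.25 +/- 0.0028, r2 = 0.191 +/- 0.00056
fp$gradient
#> <gradient_assessment> delta_r = 5.06 -> medium gradient
```

r₁ ≈ 5.2 and r₂ ≈ 0.19 say PhPPn enchains ~5× faster than MePPn while
their product stays ≈ 1 (ideal behavior); Δr ≈ 5 classifies the chain as
a medium gradient: PhPPn-rich early blocks fading into MePPn-rich ends.
The same numbers drive the microstructure and the report:

```r
ens <- simulate_chains(project_rate_set(
         matrix(c(NA, 0.191, 5.25, NA), 2, 2,
                dimnames = list(cfg$rates$species, cfg$rates$species))),
       cfg$f0, n_chains = 10, L = 100,
       final_conversion = cfg$final_conversion, seed = 1)
cat(chains_to_text(ens)[3], "\n")
#> AABAAABAAAABBAAAAAAAABAAAAAAAAAAABBAAAAAABABABAABAABBAABBAAABBBB...

rep <- build_report("P1", seed = 1)
rep$table[, c("id", "dp", "monomer_ratio", "mn_k", "delta_r",
              "gradient_class")]
#>  id    dp monomer_ratio  mn_k delta_r gradient_class
#>  P1 48/41         54/46 13.9k     4.9         medium
```

DP 48/41 and Mₙ = 13.9 kg/mol come out of the pipeline's own conversion
and end-group arithmetic (formula-derived molar masses, 2-methoxyethanol
end group) and match the published synthesis table for this polymer.

## The analysis workflow

The numbered drivers under `analysis/` run the full study on synthetic
data and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # ten preset datasets + QC
Rscript analysis/02_fit_binary.R      # P1-P8: per-model + averaged ratios
Rscript analysis/03_fit_ternary.R     # P9/P10: six ratios + projection
Rscript analysis/04_microstructure.R  # 10 chains x 100 units per polymer
Rscript analysis/05_report.R          # synthesis-table-style report
```

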