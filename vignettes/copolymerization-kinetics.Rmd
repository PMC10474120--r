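---
title: "Nonterminal copolymerization kinetics: models, synthetic data and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonterminal copolymerization kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppekinetics)
```

This vignette is the package's account of its science: the kinetic model
and its assumptions, the three reactivity-ratio estimators, what the
synthetic-data generator does and does not emulate, the Monte Carlo
microstructure algorithm, and the numerical and design choices made where
the problem left them open.

## The nonterminal model

In a living, organocatalyzed ring-opening copolymerization the propagating
chain end is the same alkoxide regardless of which unit was added last, so
the probability of adding monomer $i$ depends only on the incoming
monomer — the *nonterminal* (chain-end-independent) picture. Each monomer
is consumed first order in itself,

$$\frac{d[M_i]}{dt} = -k_i\,[M_i]\,[P^*],$$

and because the active-chain concentration $[P^*]$ is common to all
species, every observable composition quantity depends only on the rate
*ratios* $r_{xy} = k_x / k_y$. Dividing the rate laws for two monomers and
integrating gives the **drift law** between surviving fractions
$a_i = [M_i]/[M_i]_0$:

$$a_B = a_A^{1/r}, \qquad r = k_A/k_B,$$

which carries three exact structural consequences the package enforces and
tests: $r_{xy} \cdot r_{yx} = 1$, transitivity $r_{xz} = r_{xy} r_{yz}$,
and a one-parameter family of composition curves per pair. A `rate_set`
stores one relative $k_i$ per species (last fixed to 1), so these
identities hold by construction; gradient strength $\Delta r = r_1 - r_2$
(ordered $r_1 \ge r_2$) determines the pair uniquely under the ideal
assumption via `ratios_from_delta()`:
$r_1 = (\Delta r + \sqrt{\Delta r^2 + 4})/2$.

Composition as a function of total conversion follows by parametrizing
states with the survival of a reference species: with feed fractions
$f^0_i$,

$$X = 1 - \sum_i f^0_i a_i, \qquad
  f_i = \frac{f^0_i a_i}{\sum_j f^0_j a_j}, \qquad
  F_i = \frac{f^0_i (1 - a_i)}{X},$$

where $f_i$ is the instantaneous unreacted-feed fraction and $F_i$ the
cumulative incorporated fraction. Two conventions deserve note:

* **Reference-species parametrization instead of time.** Absolute rate
  constants are not identifiable from composition data (any time rescaling
  of $[P^*]$ cancels); time enters only in the synthetic generator. This
  removes an unidentifiable scale from the model layer.
* **$X = 0$ limit.** $F_i$ is $0/0$ at the curve start; it is defined by
  the continuous limit $F_i \to f^0_i$.
* **Final-conversion cap.** Curves stop at $X = 0.999$: at complete
  conversion the fast species' survival underflows
  ($a^{k_{\max}/k_{\min}}$ with ratios up to $\sim 185$ in the ternary
  presets).

Numerically the curve is inverted from $X$ to survival by bisection
**parametrized by the slowest species** — its powers $k_i/k_{\min} \ge 1$
keep every survival representable, whereas the fastest species' survival
underflows already at moderate conversions. The bisection bracket is
tightened to $10^{-12}$, which after power-law amplification (factor
$\le k_{\max}/k_{\min}$ near $a = 1$) keeps composition errors below the
$10^{-10}$ the tests demand. An independent check integrates the drift ODE
$da/db = r\,a/b$ with `deSolve` in the test suite; the analytic and
numeric curves agree to $10^{-6}$ over $r \in [0.1, 20]$.

## The three estimators

All three fits are reparametrizations of the same noiseless curve; they
differ in which coordinates the noise enters.

* **Jaacks** — the drift law in log coordinates,
  $\ln\frac{1}{1-x_A} = r_1 \ln\frac{1}{1-x_B}$, fitted by
  *through-origin* least squares. The model has no intercept, and fitting
  one would only absorb $t=0$ normalization error, so none is fitted.
  $r_2$ comes from the swapped regression; both directions are estimated
  independently (not forced to $r_2 = 1/r_1$) because the product
  $r_1 r_2 \approx 1$ then serves as a free diagnostic of ideal behavior.
* **BSL** — least squares of $x_B$ against $1 - (1-x_A)^{1/r}$ directly in
  monomer-vs-monomer conversion coordinates. This avoids using the noisy
  total conversion twice (both coordinate systems trace the identical
  noiseless curve).
* **Ideal integrated** — least squares of the observed instantaneous feed
  fraction $f_A$ against the model curve $f_A(X; r)$ at the observed total
  conversions, with the pair treated as a renormalized binary subsystem.
  Under the nonterminal model this is exact even inside a ternary
  mixture, which is what licenses the pairwise ternary analysis.

One-dimensional minimizations run on $\log r$ over
$[\ln 10^{-3}, \ln 10^{3}]$ with Brent's method (`optimize`, tol
$10^{-10}$), deterministic with no random starts; an optimum at the bound
is an error, not a result. Standard errors come from regression theory
(Jaacks) or the curvature of the objective at the optimum (BSL, ideal).
The *reported* uncertainty on a ratio, however, is the across-model
standard deviation from `average_models()` — the estimator spread is the
honest error scale for this kind of data, and per-fit standard errors are
kept separately on each estimate.

Fits use data truncated at 60 % total conversion
(`truncate_conversions()`): beyond that the minority feed is depleted,
leverage concentrates in a few late points, and slow side processes the
model excludes (e.g. transesterification) would accumulate. Conversions
are *not* forced monotone — no isotonic smoothing — so integration noise
stays visible to the fits exactly as in raw data.

For ternary systems (`fit_ternary()`) each of the three unordered pairs is
fitted per model, giving six directed ratios with across-model means and
sds. The six averages are generally *not* mutually consistent (they are
noisy views of only two free parameters), so for downstream simulation
`project_rate_set()` projects them onto the closest consistent rate set by
least squares on $\log k$ — equivalent to a geometric mean of the
$k$-estimates each ratio implies. Individual ratios can be excluded from
averaging via lambda flags (ordered pair + model + reason); no automatic
exclusion rule is applied, because none is well established — exclusions
are a documented analyst decision.

## Gradient classification

$\Delta r = r_1 - r_2$ with half-open class boundaries: soft $(0, 1.5]$,
medium $(1.5, 7.5]$, hard $(7.5, 25]$, block-like $(25, \infty)$. The
boundaries are applied exactly as stated (1.5 is soft, 7.5 is medium, 25
is hard). $\Delta r$ compresses two numbers into one and assumes
$r_1 r_2 \approx 1$; when the fitted product strays far from 1 the class
label should be read with caution — the report carries both.

## The synthetic-data generator

`generate_kinetics()` emulates what a quantitative real-time
$^{31}$P NMR experiment delivers, not the spectra themselves:

* **Kinetic law.** Living first-order decay per species,
  $[M_i](t) = [M_i]_0\, e^{-k_i \kappa t}$, with polymer signal
  $[M_i]_0 - [M_i](t)$ — total $^{31}$P per species is exactly conserved.
* **Time scale.** The overall scale $\kappa$ is solved (by `uniroot` on
  $\log \kappa$) so the run reaches its configured final conversion at the
  last spectrum. Real reaction times (19–125 h in the preset metadata) are
  cosmetic: absolute rates are not identifiable from composition data, and
  the generator makes no claim about them.
* **Acquisition grid.** Default 40 spectra: the first 10 at 5.7 min
  spacing, the next 10 at 11.3 min, then geometrically widening intervals
  (factor 1.25) as a reaction slows — the schedule of a typical real-time
  run.
* **Noise.** Multiplicative Gaussian noise on every integral,
  $(1+\varepsilon)$ with $\varepsilon \sim N(0, \sigma)$ i.i.d. per table
  cell, default $\sigma = 0.02$. Integration error scales with peak size,
  which makes the multiplicative model the natural default; an additive
  floor (constant absolute error, relevant for peaks near the noise floor)
  is a known omission.
* **Determinism.** One integer seed; the RNG state is restored afterwards,
  so identical configs give byte-identical CSVs and never perturb the
  caller's random stream.

What the generator does **not** emulate: lineshapes, phasing and baseline
error, peak overlap, temperature drift, catalyst deactivation, slow
initiation, or any monotone-breaking systematic. Passing tests therefore
demonstrate that the estimators are correct and stable *under the stated
noise model* — they do not certify robustness against spectral-processing
artifacts in real data, which is precisely why the ingest layer keeps a
conservation-based QC.

### Presets

The ten presets (`preset("P1")` … `preset("P10")`) encode the study
conditions of ten real copolymerizations: species, catalysts, initiator,
total conversion, and per-monomer degrees of polymerization from the
published synthesis table; total monomer concentration 4 mol/L and target
degree of polymerization ~100 as in the underlying protocol. Two
reconstructions are involved, both deliberate:

* **True ratios from $\Delta r$.** The per-model fitted ratios are not
  machine-readable from the source, so each preset's ground truth is
  reconstructed from its published gradient strength under the ideal
  assumption. These are reconstructions, not measured ground truth; the
  round-trip tests check that the pipeline recovers *them*.
* **Feed from DPs.** Incorporated amounts satisfy
  $\mathrm{DP}_i \propto f^0_i (1 - a_i)$ at the final conversion, with
  survivals tied together by the drift law; a 1-D root find on the slowest
  species' survival recovers the feed. For P1 this gives a feed of
  ≈ 50/50 and total monomer:initiator ≈ 96, consistent with the stated
  "ca. 100" target.
* **P10.** No gradient strengths are published for the TrisUrea-catalyzed
  terpolymer; only the inversion of the ETP/EPP incorporation order
  relative to P9 is described. P10 therefore reuses the P9 magnitudes
  ($\Delta r_{12} = 14$, $\Delta r_{23} = 13$) with the inverted species
  order — a documented stand-in, not a published value.

## Monte Carlo microstructure

`simulate_chains()` grows `n_chains` chains of exactly `L` units from one
shared pool. The pool holds $\mathrm{round}(n_\text{chains} L / X_f)$
units split by feed via largest-remainder rounding, so that completing all
chains consumes exactly the final experimental conversion $X_f$ — chain
ends then represent the composition actually reached (a polymer stopped at
72 % conversion never sees the late slow-monomer-rich regime). Growth is
round-robin: every round, each chain adds one unit drawn with probability
$k_i N_i / \sum_j k_j N_j$. This is the minimal scheme that is
simultaneously nonterminal, pool-depleting, and dispersity-1 (all chains
identical length, excluding chain-length effects from the visualization).
Monomer conservation is exact in integers, and the ensemble is
reproducible bit-for-bit from its seed. Defaults (10 chains × 100 units)
mirror the conventional microstructure plots; convergence to the analytic
composition curve is tested at $10^5$ drawn units against $3\sigma$
binomial bounds.

## Ingest and quality control

The CSV dialect is deliberately plain: optional `#` metadata lines
(species, feed, initiator, seed), then
`time_min, <sp>_monomer, <sp>_polymer, …`. Conversions default to the
*paired* normalization $x_i = P_i/(M_i + P_i)$, which is invariant to
per-spectrum gain — each species is its own internal standard. The
`monomer_only` mode ($x_i = 1 - M_i(t)/M_i(0)$) exists for spectra where
polymer resonances overlap, at the cost of gain sensitivity. Feed
fractions default to the first spectrum's monomer integrals (at low
temperature the first spectrum precedes measurable conversion) and can be
overridden by weighed-in values.

QC exploits the same conservation the generator builds in: per species,
the monomer+polymer sum should be constant. The reported *drift* is the
magnitude of the fitted linear trend across the run divided by the mean —
a statistic insensitive to zero-mean integration noise, so a 2 %-noise
dataset does not trip the 5 % warning, while a genuine 10 % systematic
loss does. The noise level itself is reported separately as a coefficient
of variation, and non-monotone per-species conversions are counted but
never corrected.

## Degenerate inputs and tie-breaks

* Fewer than 4 time points, non-monotone time, or missing columns are hard
  ingest errors; negative integrals are clipped to zero with a warning.
* All-zero conversions: "no consumption" error rather than a degenerate
  slope.
* Conversions $\ge 1$ (possible in `monomer_only` mode under noise) are
  dropped with a warning before fitting.
* In the ideal-integrated fit, observed conversions outside the model's
  invertible range are dropped with a warning; more than half dropped is
  an error.
* Largest-remainder rounding (compositions, pool splits) breaks ties by
  first occurrence, making rounded outputs deterministic.

## Problem sizes

The test suite and acceptance checks run at sizes chosen to make the
statistics decisive while staying quick on a laptop: 40–60 spectra per
synthetic run, 200 seeded replicates for the bias check at
$\sigma = 0.02$, $10^5$ drawn units for Monte Carlo convergence, and
500-chain ensembles for the symmetry checks. The full suite runs in about
twenty seconds.

## Known limitations

* The nonterminal model is assumed, not tested against alternatives: no
  penultimate/terminal-model estimators (Fineman–Ross, Kelen–Tüdős,
  Meyer–Lowry), no depropagation, no transesterification. For
  organocatalytic phosphoester ROP under the conditions encoded in the
  presets this is the appropriate model, but data from systems with
  chain-end selectivity will fit poorly in ways the $r_1 r_2$ diagnostic
  only partially reveals.
* Preset "truth" is reconstructed (see above); recovery tests validate the
  pipeline's internal consistency, not the original measurements.
* The generator's noise model is a single multiplicative term; correlated
  baseline error and peak overlap are not represented.
* Monte Carlo chains have dispersity exactly 1 by design; kinetic
  chain-length distributions are out of scope.
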