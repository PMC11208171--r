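---
title: "Electron-flow stoichiometry and chemiosmotic ATP accounting in acetoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electron-flow stoichiometry and chemiosmotic ATP accounting in acetoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetoflux)
```

## The model

acetoflux models acetogenesis in *Acetobacterium woodii* as a small
stoichiometric network over the carbon species (CO, CO₂, formate,
fructose, the THF-bound C1 pool, enzyme-bound [CO], acetyl-CoA, acetate),
the electron carriers (reduced ferredoxin Fd²⁻, NADH, H₂) and two
ledgers (Na⁺, ATP). Reactions are the enzymes of the Wood–Ljungdahl
pathway and its respiratory periphery:

* **CooS** — monofunctional CO dehydrogenase, CO + H₂O → CO₂ + Fd²⁻;
* **carbonyl entry** — either directly from CO into the CODH/ACS
  ([CO] from CO) or, without CO, by ferredoxin-driven CO₂ reduction;
* **HydABC** — electron-bifurcating hydrogenase; one flux unit is the
  bifurcation event 2 H₂ ⇌ Fd²⁻ + NADH (reversible);
* **HDCR** — hydrogen-dependent CO₂ reductase, H₂ + CO₂ ⇌ formate, or in
  its ferredoxin mode Fd²⁻ + CO₂ ⇌ formate (the capability the CO-adapted
  hydrogenase-free mutant acquires);
* **methyl branch** — formyl-THF synthetase (consumes one ATP), then two
  lumped NADH-consuming reductions (formyl→methylene including the
  cyclohydrolase, methylene→methyl). Finer THF chemistry is deliberately
  not resolved: the carrier ledgers the model reproduces do not resolve
  it either;
* **ACS condensation and Pta/Ack** — methyl-THF + [CO] → acetyl-CoA →
  acetate, returning one ATP;
* **Rnf** — Fd²⁻ + NAD⁺ → Fd + NADH, pumping 2 Na⁺ per Fd²⁻ (2 Na⁺/2 e⁻);
* **ATP synthase** — 3.3 Na⁺ per ATP (the c-ring stoichiometry of the
  Na⁺ F₁F₀ synthase);
* **fructose catabolism** — one lumped reaction
  fructose → 2 acetate + 2 CO₂ + 2 NADH + 2 Fd²⁻ + 4 ATP
  (glycolysis + pyruvate:ferredoxin oxidoreductase + Pta/Ack), since only
  its acetate stoichiometry and carrier output matter here.

Every non-exchange reaction is carbon- and electron-balanced by
construction, with degrees of reduction counted against fully oxidised
references (CO₂, NAD⁺, oxidised Fd, unloaded THF = 0; each two-electron
reduction adds 2; fructose = 24). `validate_model()` asserts both
balances and the Na⁺ ledger conventions exactly.

**Assumptions.** Steady state per unit product; no kinetics, no
thermodynamics, no CO inhibition constants — feasibility means
stoichiometric solvability, not viability (the wild-type-on-CO scheme is
solvable although the organism does not grow on CO). Hydrogen formed by
the pathway is fully recaptured by default (`h2_escape_fraction = 0`);
the true escape fraction during growth on formate is unknown, and a
nonzero value simply opens an H₂ export. ATP is a reported net, not a
balanced species; Na⁺ *is* balanced, through the synthase, which realises
the chemiosmotic yield Na⁺ pumped / (Na⁺ per ATP) as synthase flux.
Biomass is not modelled: the package reports ATP per acetate and makes no
claim about growth yields per ATP.

## Genotypes, conditions and network assembly

`build_model(genotype, condition, parameters)` assembles exactly the
permitted reactions: HydABC and the H₂-mode HDCR require their modules,
ferredoxin-mode HDCR must be enabled (it requires the FDH module; it is
off by default in the wild type, whose schemes route through H₂ — the
purified enzyme's small ferredoxin-mode activity is not part of the
wild-type ledgers), CooS requires CO, the formyl-THF synthetase requires
ATP coupling (bicarbonate uncoupling removes it), and Rnf plus the ATP
synthase require sodium. Removal is literal — disabled reactions are
absent, not zero-bounded — so an unbalanceable carrier is named in
diagnostics rather than hidden behind a bound.

Two assembly details were genuinely open and are decided here:

* **Carbonyl routing.** With CO present the carbonyl branch enters
  directly from CO; the CO₂ entry is assembled only without CO. Keeping
  both open would add a futile degree of freedom (CO → CO₂ → [CO]) that
  the ledgers never use.
* **Dead-branch pruning.** A species with no producer (or no consumer)
  among the assembled reactions forces every reaction touching it to zero
  flux; those reactions are removed to a fixed point, as is any reaction
  containing a species no other reaction touches. Under bicarbonate
  uncoupling this reduces the network to CooS + Fd-HDCR + exchanges,
  which is exactly the observed chemistry (CO → formate only).

## The solver

The balance matrix over all non-ATP species (exchange reactions included
as columns) is augmented with the normalisation row *product export =
flux* and solved by Gaussian elimination over exact rationals — a small
numerator/denominator class reduced by GCD after every operation, so all
residuals are identically zero and yields are exact fractions such as
50/33. The network has ~15 reactions; exactness costs nothing and removes
every tolerance question. Uniqueness is explicit: a remaining null-space
direction raises an error naming the free reactions, an inconsistent
system returns an `infeasibility_report` whose species set is found by
dropping one balance row at a time and re-solving (each row whose removal
restores consistency joins the irreducible conflict), plus a
producer/consumer scan for the mechanistic reading ("no route to
regenerate NADH"). Irreversibility is checked *post hoc* on the unique
solution — only HydABC, both HDCR modes and a substrate-side CO₂
exchange may run backwards — and a violation is reported as
infeasibility with the signed flux.

**The product split φ.** Resting cells on CO with moderate bicarbonate
form acetate and formate side by side. Stoichiometry alone cannot fix
that split; it is one genuine degree of freedom. The solver therefore
closes the non-target product's export unless the caller supplies `phi`,
the formate branch fraction, which pins acetate export at (1−φ)·flux and
formate export at φ·flux. Solutions are linear in φ (verified by test),
and the registry's mixed scenario defaults to φ = 1/2, matching the
near-equimolar measured endpoints; at that value CO:acetate:formate =
5:1:1. The package treats φ as a description of the observed split, not
a mechanism — why formate persists even without bicarbonate is an open
experimental question.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `na_per_atp` | 33/10 | Na⁺/ATP | synthase c-ring stoichiometry |
| `na_per_fd2_rnf` | 2 | Na⁺/Fd²⁻ | Rnf pumping per 2 e⁻ |
| `h2_escape_fraction` | 0 | — | pathway H₂ lost to the headspace |
| `phi` | 1/2 (mixed scenario) | — | formate branch fraction |

Both stoichiometries are exact rationals; changing them propagates
through the ledger exactly (e.g. a hypothetical 4 Na⁺/ATP synthase turns
the wild-type CO yield into 5/4).

## Reporting conventions

Raw values are always exact (rationals) and reported values are rounded
half-up at one decimal — `round_half_up()` does the rounding in integer
arithmetic for rationals, so 50/33 → 1.5, 10/33 → 0.3, 40/33 → 1.2
without any floating-point half-even surprises. Fold changes of 10 and
above are reported to the nearest integer (55.3/2.2 → 25), matching how
such activities are printed. Percent changes are computed on exact
rationals and rounded to whole percent: (40/33 − 10/33)/(10/33) → 300 %.
`endpoint_ratio()` takes an orientation flag because conversion ratios
are quoted in both directions (2.6 acetate *per fructose*, but 1.1 CO
*per formate*).

## Growth-rate estimation

`growth_rate()` fits ln(OD) against time by least squares over contiguous
windows of at least `window_min_points` (default 4) positive readings and
reports the slope of the selected window. Selection is the part that
matters. Simply maximising R² across windows of different lengths is
unstable under multiplicative noise: a four-point window can be almost
perfectly collinear by luck anywhere on the curve, including the lag and
stationary phases where the true slope is zero; in simulation sweeps this
mis-estimates μ by tens of percent. The estimator therefore selects the
**longest window that is log-linear to within the measurement noise**:

1. windows must span at least one OD doubling on the fitted slope
   (`min_span = log(2)`), which excludes flat lag/stationary stretches;
2. the noise variance of ln OD is estimated from the median squared
   second difference of the series (second differences are curvature-free
   wherever the curve is locally exponential, flat or saturated);
3. among windows whose residual variance is within `var_factor` (1.6) of
   that estimate, the longest wins; ties go to the smaller residual
   variance, then the earlier window.

On noiseless data the residual threshold collapses to zero and the rule
returns the maximal exactly log-linear window — the whole exponential
phase — recovering μ exactly, which the tests assert to 10⁻⁹. A series
with no usable variation (constant OD) is flagged as a degenerate fit
with μ = 0 and undefined R². The estimate is invariant to rescaling the
OD series, as a specific growth rate must be.

`specific_rate()` converts a concentration change over a window from
mM/h to nmol min⁻¹ mg⁻¹ as ×1000/60/protein, the natural basis for a
fixed-volume suspension where 1 mM ≡ 1000 nmol/mL and protein is in
mg/mL: 60 mM consumed in one hour at 1 mg/mL is 1000 nmol min⁻¹ mg⁻¹.

## SNP tables

Variant tables travel as TSV with one `freq_*` column per sampled
timepoint; blank cells mean *not detected* and are recorded as 0 % with a
parallel `detected` flag rather than silently imputed, since undetected
and absent are not the same claim. `snp_report()` filters by population
frequency at a timepoint and orders by descending frequency then genome
position — a total, deterministic order. The packaged
`inst/extdata/snp_table1.tsv` is a transcription of the adaptation
experiment's variant table; on it, the hycB2 R165P substitution is the
unique variant at 100 % after adaptation on CO, with the modC2 and fdhC
variants next at 81.2 % and 78.9 %.

## Synthetic data

`simulate_growth()` produces a three-phase batch curve — OD held at the
inoculum through the lag, then *exactly* exponential at μ, then capped at
the carrying capacity — with multiplicative lognormal noise of unit mean
and configurable CV (concentrations and ODs are positive, so noise is
multiplicative). The exact-exponential middle phase is a deliberate
idealisation: a logistic family was considered and rejected because its
log-slope is μ(1 − OD/od_max) *everywhere*, so at realistic inoculum
ratios (od0/od_max ≈ 1/20) no log-linear window estimator can recover μ
to within 10 % — the round-trip property the generator exists to support
would be unattainable by construction, not by estimator deficiency. The
sharp lag and saturation corners are the price; real curves are smoother
there. Defaults emulate the adapted cultures: μ = 0.05 h⁻¹, od0 = 0.05,
od_max = 1.0, 5 % noise, sampled every 3 h over 120 h.

`simulate_conversion()` takes a feasible flux solution and declines the
substrate linearly at a configured specific rate (nmol min⁻¹ mg⁻¹) until
exhaustion, with each dissolved product rising at the solution's
product:substrate ratio, so noiseless endpoint ratios equal the model's
ratios *exactly* and carbon is conserved along the whole trajectory
(asserted in tests). `simulate_snp_table()` emulates an
adaptive-evolution variant table: one locus sweeps monotonically to 100 %
by the final timepoint, the rest fluctuate below 90 %.

All generators consume an explicit seed, are bit-for-bit reproducible,
and restore the caller's global RNG state.

**What passing tests do and do not show.** The generators reproduce the
*shape* and *stoichiometry* of the experiments — not their biology. There
is no CO inhibition, no six-month adaptation lag, no replicate structure
(the experiments report mean ± SD of 2–3 cultures), no gas/liquid mass
transfer, and growth is decoupled from the flux model (no biomass-per-ATP
term). Recovery of μ on synthetic curves validates the estimator's
contract, not the claim that real OD series are piecewise exponential.

## Problem sizes

Everything is desk-scale by design: networks of ~15 reactions solved
exactly in milliseconds; growth-rate recovery exercised over 20 seeds per
rate at 40–50 points per curve (the selection rule was additionally
profiled over 100 seeds per condition during development); the full test
suite runs in well under a minute.

## Known limitations

* The split φ is descriptive; the package cannot predict it.
* Reported infeasibility names unbalanceable species but not every
  minimal conflict set when several overlap.
* The fructose reaction is a single lump; redox detail inside glycolysis
  is invisible.
* The growth-rate estimator assumes roughly uniform multiplicative noise;
  strongly heteroscedastic series would mislead its second-difference
  noise estimate.
* No statistical inference on replicates is provided anywhere — the
  quantities mirrored here are single reported means.
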