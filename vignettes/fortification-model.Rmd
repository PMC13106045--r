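---
title: "Modelling fortification scenarios: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fortification scenarios: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

fortisim models how large-scale food fortification (LSFF) of five staple
vehicles — wheat flour, maize flour, oil, rice and salt — shifts population
micronutrient intake distributions, how those shifts change the prevalence
of inadequate and excess intakes under six policy scenarios, and what each
scenario costs. This vignette explains the model, its assumptions, the
tunable parameters, and the choices made where the design was genuinely
open.

## The intake model

Usual (long-run average) daily intake of a micronutrient in one population
stratum — a country × age–sex group × nutrient cell — is represented by a
right-skewed parametric distribution, log-normal or gamma. Internally every
distribution is parameterised by its analytic mean and coefficient of
variation (CV); the family-native parameters are derived:

* log-normal: $\sigma^2 = \ln(1 + cv^2)$, $\mu = \ln(\bar{x}) - \sigma^2/2$;
* gamma: shape $= 1/cv^2$, scale $= \bar{x}\,cv^2$.

The mean/CV parameterisation is natural for the package's central
operation: fortification adds a deterministic daily contribution $\delta$
to intake, modelled by shifting the distribution to mean $\bar{x} + \delta$
while keeping its family and "the same amount of variability".

**Shift convention.** "Same variability" is ambiguous between constant SD
and constant CV. The default preserves CV, consistent with
re-parameterising skewed families by mean and CV (a distribution whose
relative spread is a population characteristic keeps that character as the
location moves); `shift_convention = "sd"` preserves the absolute SD for
sensitivity checks. Under either convention the mean shifts by exactly
$\delta$.

Distributions with CV at or below $10^{-6}$ are treated as point masses in
CDF/quantile computations; this keeps the degenerate limits (used by the
known-truth harness) numerically exact.

## The fortificant contribution

For nutrient $m$, country $c$ and age–sex group $(s,a)$, the daily intake
contribution from fortification is

$$I_{mcsa} = \sum_{FV} F_{csa} \times IP_{FVc} \times FC_{FVc} \times
D_{FVcm} / 1000,$$

summing over the five food vehicles: per-capita vehicle intake $F$ in
g/day (population-level figures scaled to age–sex groups by caloric-intake
ratios whose population-weighted mean is 1 within each country), the
fraction industrially processed $IP$, the fraction processed in compliance
with the standard $FC$, and the standard's nutrient level $D$ in mg/kg of
vehicle; the division by 1000 converts g×mg/kg to mg/day, and a per-nutrient
units registry converts to µg/day where that is the nutrient's reporting
unit (iodine, vitamin A, folate, B12, selenium). Programmes with status
`none`, and nutrients absent from a vehicle's standard, contribute zero.
The model deliberately has no storage-loss, bioavailability or overage
terms in the intake calculation.

Missing $IP$ and $FC$ indicators are imputed by the median of observed
values for the same vehicle within the country's region, falling back to
the global vehicle median; imputed values carry a provenance flag so the
compliance sensitivity analysis can perturb exactly the uncertain values.

## Prevalence of inadequate and excess intakes

Inadequacy uses the probability approach: with an independent requirement
distribution centred on the harmonised average requirement (AR),

$$\text{prev} = \int_0^\infty f_{\text{intake}}(x)\, P(\text{req} > x)\,dx,$$

computed by adaptive quadrature on the bounded support
$(0, Q_{\text{intake}}(1-10^{-9}))$ with absolute tolerance $10^{-8}$
(bounded support avoids infinite-interval fragility for the gamma family).
The requirement is normal with CV 0.10 by default — the conventional value
when requirement spread is not reported — overridable per nutrient and
stratum. Iron for menstruating women uses a right-skewed (log-normal)
requirement with CV 0.25, parameterised so its mean equals the AR: this is
precisely the case where the probability approach is needed and the EAR
cut-point shortcut fails. The normal requirement is used untruncated in the
analytic risk curve (mass below zero is $<10^{-15}$ for CV ≤ 0.25) and
truncated at zero in sampling oracles. As the requirement CV vanishes the
probability approach reduces to the cut-point method,
$\text{prev} \to F_{\text{intake}}(AR)$, which the tests verify to
$10^{-4}$.

Excess intake is the fraction above the tolerable upper level (UL),
$1 - F_{\text{intake}}(UL)$. Only the seven nutrients with harmonised ULs
are assessed; a nutrient without a UL returns "not assessed" (`NA`), never
0, because absence of a UL is not evidence of zero risk. UL availability is
data (rows of the UL table), not code.

## The six scenarios

1. **no_fortification** — all compliance zeroed; the baseline.
2. **current** — programmes as observed (identity).
3. **improved_compliance** — $FC \leftarrow \max(FC, 0.9)$ for every
   programme, mandatory and voluntary alike. The max rule (rather than
   forcing 0.9) never degrades countries already above 90%.
4. **aligned_standards** — standard levels aligned to international
   guidelines under the default `max_with_guideline` rule: a level is
   raised to the guideline where below it, kept where above, and guideline
   nutrients absent from the current standard are added. The rationale is
   that many existing standards already exceed guidelines and alignment is
   reported as a pure gain; `replace_with_guideline` is available where a
   strict-replacement reading is wanted.
5. **aligned_improved** — both of the above.
6. **aligned_improved_expanded** — both, plus new mandatory programmes
   (compliance 0.9, guideline standards) in country × vehicle cells with
   status `none` where the expansion rule holds.

**Expansion rule.** A cell is eligible when (a) the country's baseline
(no-fortification) population-weighted prevalence of inadequacy is ≥ 0.2
for at least one nutrient the vehicle's guideline delivers, (b) per-capita
vehicle intake is ≥ 50 g/day (5 g/day for salt, 10 g/day for oil —
condiments are eaten in grams), and (c) the industrially processed fraction
is ≥ 0.5. The published criteria are qualitative ("identified need and
appropriate food vehicle"); these thresholds are the package's
quantification of them and every one is configurable
(`expansion_params()`).

Voluntary programmes are treated identically to mandatory ones throughout,
including the 90% floor: their observed compliance already encodes lower
uptake.

## Aggregation

Stratum prevalences are multiplied by World-Bank-style population counts
and summed into person–nutrient totals (one person inadequate in $k$
nutrients counts $k$ times). Counts stay real-valued end to end — rounding
happens only in rendered reports — so no rounding error accumulates over
thousands of strata. Prevented counts are baseline minus scenario totals
over an identical stratum universe; strata missing population rows abort
the run rather than silently biasing the subtraction.

## Costs

Annual programme cost per country × vehicle is premix + industry +
government, in 2021 USD:

* **Premix**: for each standard nutrient, level (mg/kg ≡ g/tonne) ÷
  compound activity ÷ 1000 × compound price (USD/kg), summed, then marked
  up multiplicatively for shipping, taxes/duties and domestic logistics in
  supply-chain order (defaults 10%, 5%, 8%), times the fortified tonnage
  (vehicle supply × IP × FC).
* **Industry**: per facility, annualised fortification and QA–QC equipment
  plus recurrent QA–QC supplies, labour, training and
  management/overhead, times the facility count (an input, not an
  estimate).
* **Government**: once per programme, annualised monitoring equipment plus
  recurrent monitoring supplies and labour, social marketing, training and
  management/overhead; programmes created by expansion add annualised
  planning/launch costs.

Capital costs are annualised with the annuity formula
$C\,r/(1-(1+r)^{-L})$ at a default discount rate of 3%/yr and 10-year
lives (straight-line at $r=0$). The method is stated as "annualised"
without a printed formula upstream; the annuity at a conventional social
discount rate is the standard costing choice and both rate and lifespans
are configuration. Premix cost is exactly linear in compound prices, which
gives the ±50% price sensitivity a closed form: the relative total-cost
change equals (factor − 1) × premix share.

## The synthetic world

No real dietary, programme or population extracts are packaged; a seeded
generator builds a miniature world with the structure the analysis
assumes — it matches structure, not geography. Defaults (the study
conditions): 10 countries in 2 regions, 34 age–sex groups (17 five-year
bands × sex), 13 micronutrients, 5 vehicles. Intake means are drawn per
country × nutrient on a log scale around the stratum requirement
(SD 0.6 across countries, 0.15 across strata) so baseline inadequacy spans
(0, 1); CVs are uniform on [0.2, 0.8]; each nutrient is assigned one
family. Programme indicators are drawn in observed-plausible ranges (IP in
[0.2, 1], FC in [0.1, 0.95]); missingness per vehicle echoes the real
registries' pattern (worst for salt and oil), with at least one observed
value per vehicle guaranteed so median imputation is well defined. Current
standard levels scatter uniformly in [0.5, 1.5] × guideline so alignment
has binding and slack cases; calcium appears in wheat standards rarely
(15%), mirroring its seldom-practised status. Requirements, ULs, guideline
levels, compound activities and prices are synthetic but field-plausible
values declared in code (`base_requirements()`, `guideline_standards()`,
`default_compounds()`).

What the generator does **not** emulate: spike-at-zero (non-consumer)
strata, correlated intake across nutrients, within-person day-to-day
variance (inputs are already usual-intake distributions), or any specific
country's diet. Passing tests therefore demonstrate correctness of the
estimators and accounting on structurally realistic inputs, not
reproduction of real-world figures — those require the original data
extracts, which are not packaged.

A separate known-truth generator emits degenerate strata with closed-form
answers — point-mass intakes at, far below and far above the AR
(prevalence 0.5, 1, 0), a vanishing requirement CV (prevalence equals the
intake CDF at the AR) and a single-vehicle programme whose contribution is
a hand product — and the pipeline is required to reproduce the whole
answer sheet within $10^{-4}$.

## Problem sizes and determinism

The default world (10 × 34 × 13 = 4,420 strata, six scenarios) runs in
roughly ten seconds on one CPU; tests use a reduced 4 × 6 × 6 world where
the full structure is not needed. Everything downstream of the generator
is deterministic: two runs with the same inputs produce byte-identical
CSVs, and the run manifest records settings, seed, input checksums and
unrounded global totals for regression comparison.

## Known limitations

* Deterministic by design: no uncertainty propagation over imputation,
  intake estimation or cost inputs.
* Static premix prices; no price–scale economics.
* No bioavailability, storage-loss or overage terms in the intake
  contribution (an overage multiplier exists for cost sensitivity use
  only).
* Country totals cover modelled countries only; no out-of-sample
  population correction.
* The expansion and imputation rules are reasoned defaults exposed as
  configuration, not calibrated reproductions of the upstream procedures.
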