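---
title: "Tracer accounting for skin-mucus turnover: models, calibration and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracer accounting for skin-mucus turnover: models, calibration and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucotrace)
```

## The measurement model

An EA-IRMS run reports, per dried sample, the isotope ratios of carbon and
nitrogen on the δ scale (‰ deviation from VPDB and AIR) and the elemental
mass fractions %C and %N. `mucotrace` converts δ to the heavy-isotope atom
fraction through

$$R = R_{std}\,(1 + \delta/1000), \qquad
  \mathrm{at.\%} = 100\,\frac{R}{1+R},$$

with $R_{std}$ = 0.0111802 (VPDB, ¹³C/¹²C) and 0.0036765 (AIR, ¹⁵N/¹⁴N).
These reference ratios are conventional constants, overridable per run via
`iso_standards()`. Conversions are exact and invertible; the package
guarantees round trips to 1 part in 10¹².

Tracer uptake is expressed two ways, which the package keeps strictly
separate:

* **APE** (atom percent excess), `at.% sample − at.% blank`, used inside all
  mass computations;
* **‰ enrichment**, `δ sample − mean δ blank`, used for reporting and
  group comparison, matching how tracer time courses are conventionally
  plotted.

The blank baseline is always the mean of the *same compartment's* unlabelled
(blank) group, never a global pool: natural abundance differs systematically
between diet, liver, plasma, muscle and mucus. Negative APE values in
near-baseline samples are measurement noise; they are reported as-is with a
warning, never clipped, so that blank-group APE still averages to zero.

Excess tracer mass per gram of dry sample is

$$\left(\frac{\mathrm{APE}}{100}\right)\cdot
  \frac{f_{elem}}{M_{mean}}\cdot M_{heavy},$$

with $f_{elem}$ the elemental mass fraction of the dry sample and
$M_{mean}$ the conventional mean atomic mass (12.011, 14.007 g/mol) used to
count moles of element. Using the mean mass rather than a full isotopologue
expansion biases the gram conversion by well under 0.1 %, far below the
s.e.m. of any group in this design.

## Allocation as percent of ingested dose

The allocation of tracer to a compartment chains four measurable factors:

$$100\cdot
 \frac{(\mathrm{g\ isotope/g\ fraction})\cdot
       (\mathrm{g\ fraction/g\ tissue})\cdot
       (\mathrm{g\ tissue/g\ b.w.})}
      {\mathrm{g\ ingested\ isotope/g\ b.w.}}$$

Decisions embedded in the implementation:

* **Mucus mass factors are per fish.** Each fish's own collected mucus mass
  over its own body weight gives `tissue_per_bw`, and its own dry-mass
  measurements give `fraction_per_tissue`; ratios are averaged across fish
  afterwards. The alternative (ratios of group totals) gives visibly
  different numbers whenever weights vary, and the per-fish convention is
  the one consistent with reported per-100 g summaries.
* **Muscle and plasma mass fractions default to 0.45 and 0.035 g/g.** These
  are literature-style placeholders — the kind of values cited from
  comparative physiology rather than measured in a mucus study — and are
  deliberately exposed in `default_mass_model()` for overriding. The liver
  entry (hepatosomatic index) has **no** default: it must come from the
  study's own data or config, because HSI varies severalfold with feeding
  state.
* **The ingested dose is a required input.** A meal description such as
  "starch (3 % ¹³C), protein (1 % ¹⁵N)" is ambiguous between a mass share
  of the meal and an isotopic enrichment of an additive, so the grams of
  excess isotope per gram of meal are never guessed; the calibrated preset
  back-solves them instead (below).
* Raw-mucus allocation can be read directly from raw-mucus samples or
  assembled as the dry-mass-weighted sum of the fraction allocations; both
  paths exist (`timecourse_summary()` reports all three compartments) and
  they agree only as well as the input data are mass-balanced.

## The statistical ladder

Group comparisons follow the gated ladder used throughout this literature:
Levene's test (classic mean-centred form — exactly a one-way ANOVA on
absolute deviations from group means) decides at α whether variances are
homogeneous; if so, one-way ANOVA with Tukey HSD pairwise comparisons; if
not, Dunnett's T3. Student's pooled t handles the two-group contrasts
(renewal vs control; soluble vs insoluble at each time).

Dunnett's T3 is implemented from its definition: Welch statistics with
Welch–Satterthwaite degrees of freedom per pair, referred to the studentized
maximum modulus (SMM) distribution with $m = k(k-1)/2$ comparisons. The SMM
distribution function is evaluated by numerical integration of
$\int_0^\infty \left[2\Phi(q u)-1\right]^m f_{\chi_\nu/\sqrt{\nu}}(u)\,du$
(each pair at its own ν, as in the standard T3 procedure); the test suite
guards it against a 10⁶-draw Monte-Carlo oracle to within 0.005 in p.

Two properties worth knowing:

* Under homoscedastic nulls the whole gated procedure holds its familywise
  error at or below α (verified by simulation in the test suite), and T3
  alone stays at or below α under heteroscedastic nulls.
* Tukey and T3 make the same significance calls on balanced, homoscedastic
  data, but their *adjusted p values* only agree closely near the tails.
  Away from the tails T3's p can exceed Tukey's by 0.1 or more, because the
  SMM reference ignores the positive correlation among pairwise contrasts.
  Claims that the two "agree in p" should be read as agreement of
  decisions, not of mid-range p values.

Compact letter displays are built by the insertion algorithm over the
significant-pair matrix, with ties broken by input group order.

## The cohort simulator and its calibration

The simulator draws per-fish values around mean kinetic curves in
enrichment space and emits exactly the CSV schemas the analysis consumes.
Three mean-curve models exist: saturating $A(1-e^{-kt})$, a transit peak
$A\,(t/\tau)e^{1-t/\tau}$ (maximum $A$ at $\tau$, used for plasma ¹³C with
$\tau$ = 6 h), and interpolation through explicit (time, mean, sem)
anchors. Anchors exist because the published mucus time courses are not
monotone (soluble ¹³C: 240 ‰ at 6 h, 489 ‰ at 12 h, 437 ‰ at 24 h): no
two-parameter saturating curve passes through them, and the calibration's
first duty is to the printed group means.

Noise structure:

* enriched values: multiplicative lognormal around the mean curve
  (enrichments are positive and right-skewed), with per-anchor
  $cv = sem\sqrt{5}/mean$ taken from the published s.e.m. at n = 5;
* baseline: additive normal on δ (s.d. 0.9 ‰), so blanks scatter
  symmetrically around natural abundance and small negative APE values
  occur at realistic rates;
* morphometry: body weight lognormal (mean 186.1 g, cv 0.20), collected
  mucus as body weight × an independent per-fish ratio (mean
  510/186.1 mg/g, cv 0.07), extraction area allometric in weight^(2/3)
  around 70.8 cm²; mucus dry fraction 0.10 (cv 0.05); elemental fractions
  cv 0.03. The ratio/dry/elemental cvs were chosen once so that the
  *derived* quantities match the published dispersion structure: collected
  mass cv ≈ 0.21 and allocation cv ≈ 0.19, which is what the published
  s.e.m. values imply after removing the enrichment component. They are not
  tuning knobs.
* gravimetric partition: a processing loss (mean 2.3 %, lognormal) is drawn
  first and the recovered dry mass split soluble/insoluble around
  82.4/15.3 % (per-fish s.d. 4.7 points), so soluble + insoluble never
  exceeds the raw dry mass by construction.

`preset_paper()` back-solves the quantities the study does not print:

* the label doses, from the 24 h raw-mucus targets (294 ‰ → 0.25 % of
  ingested ¹³C; 124 ‰ → 0.11 % of ¹⁵N) through the inverse allocation
  equation — giving ≈ 0.022 g excess ¹³C and ≈ 0.0020 g excess ¹⁵N per gram
  of meal, plausible for an algal-starch/algal-protein label;
* tissue enrichment anchors, from allocation targets (liver ¹³C 45 % at
  12 h for the ">40 %" claim; liver ¹⁵N 15 %, muscle 3 %, plasma ≤1 %),
  with cv 0.15 where no s.e.m. is printed.

One deliberate infidelity: the published per-fraction values are not
mass-balanced (0.824·437 + 0.153·213 ≈ 393 ‰ against 294 ‰ for total mucus
at 24 h; the ¹⁵N fraction allocations 53 + 24 do not reach the total 110).
The preset therefore reproduces each printed compartment independently and
does **not** enforce isotope mass balance across fractions; the
mass-balance invariant is tested against a separate, balanced
configuration. Other declared simplifications: fish are drawn independently
across compartments (the real design sampled several tissues per fish, but
the between-compartment correlation is unreported), and one master seed
with a fixed generation order provides reproducibility rather than per-fish
random streams.

## What passing tests do and do not show

The test suite demonstrates: exact conversion algebra; the allocation
equation's linearity and dimensional invariance; unbiased recovery of the
configured truth by the full pipeline (200 small cohorts, and n = 4000
convergence within 3 Monte-Carlo s.e.); calibration of the testing ladder's
error rates; and recovery of every published group value by an n = 5 cohort
within twice the published s.e.m.

It cannot demonstrate anything about the individual animals of the original
study: per-fish raw data were never deposited, so the published per-fish
figure panels and the exact group s.e.m. realisations are **not
reproducible**. The calibrated preset covers them only at the level of
group means and dispersions, which is the strongest claim the available
data support. Problem sizes in the routine suite (n = 5 and n ≤ 40 cohorts,
1000–2000 simulation replicates, 10⁶-draw distribution oracles) were chosen
as the smallest that make each statistical assertion sharp.

## Numerical notes and degenerate inputs

* δ ≤ −1000 ‰, non-positive ratios, atom percent outside (0, 100) and
  elemental fractions outside [0, 1] are domain errors, reported with row
  numbers when reading CSV.
* Zero within-group variance: ANOVA/Levene report the degenerate case
  explicitly (F = 0, p = 1 when all values coincide); zero-variance pairs
  in T3 and Student's t collapse to exact equality tests.
* The SMM integral uses `integrate()` at rel.tol 10⁻¹⁰; its quantile
  function inverts by root finding and is exercised only for letters and
  reporting, never inside p-value computation.
* Single-observation groups are rejected for testing; a single labelled
  sample in a summary passes its mean through with an absent (NA) s.e.m.
* Groups in letters output follow input order; all tables are written with
  fixed column order, 6 significant digits, and units in a dedicated
  column.
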