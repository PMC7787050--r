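# mucotrace

Stable-isotope tracer accounting for fish skin-mucus turnover.

Fish skin mucus is continuously secreted, and its soluble (metabolites,
soluble proteins) and insoluble (mucin) fractions turn over at different
rates. A single meal labelled with ¹³C and ¹⁵N, followed by time-course
sampling of mucus, liver, white muscle and plasma, lets those rates be
quantified without repeated invasive sampling. `mucotrace` implements the
complete analysis chain for such pulse-chase experiments on EA-IRMS data, in
a tidyverse style (tibbles in, tibbles out):

* **δ ↔ atom-fraction conversion** against the international standards
  (VPDB for ¹³C/¹²C, AIR for ¹⁵N/¹⁴N):
  R = R<sub>std</sub>(1 + δ/1000), at.% = 100·R/(1+R).
* **Atom percent excess** against per-compartment natural-abundance blanks:
  APE = at.%<sub>sample</sub> − at.%<sub>blank</sub>, plus the ‰ enrichment
  δ<sub>sample</sub> − mean δ<sub>blank</sub> used for reporting.
* **Percent-of-ingested-dose allocation**:
  100 · (g isotope/g fraction) · (g fraction/g tissue) · (g tissue/g b.w.) /
  (g ingested isotope/g b.w.), with per-fish mucus mass factors and the
  conventional mean atomic masses for the mole count.
* **Exudation metrics**: collected mucus mass, mg/cm² of skin, mg/100 g of
  fish, computed per fish first and then averaged.
* **The statistical ladder**: Levene's homogeneity gate, one-way ANOVA,
  Tukey HSD or Dunnett's T3 post hoc (studentized maximum modulus by
  numerical integration), Student's t contrasts, compact letter displays.
* **A calibrated cohort simulator** for both trial designs (time course at
  0/6/12/24 h; mucus renewal at 24 h) so the whole pipeline is testable with
  no external data.

## Worked example

```r
library(mucotrace)

preset <- preset_paper()                  # calibrated study configuration
sim <- simulate_timecourse(preset, seed = 1)

summ <- timecourse_summary(sim$samples, sim$fish, preset$dose,
                           default_mass_model(c(liver = 0.013)))
dplyr::filter(summ, compartment == "total_mucus", element == "C")
#>   compartment element time_h n enrichment_mean enrichment_sem allocation_mean allocation_sem
#> 1 total_mucus       C      0 5           0.629          0.282        0.000523       0.000219
#> 2 total_mucus       C      6 5         152.247         19.587        0.131088       0.017927
#> 3 total_mucus       C     12 5         283.377         13.735        0.239458       0.008296
#> 4 total_mucus       C     24 5         284.489         35.198        0.239840       0.030231
```

Raw (total) mucus accumulates ¹³C over the first 12 h and plateaus near
0.24 % of the ingested ¹³C by 24 h — the tracer share of one meal that ends
up in the skin mucus layer. The time-course comparison with the gated post
hoc:

```r
d <- sample_allocations(sim$samples, sim$fish, preset$dose,
                        default_mass_model(c(liver = 0.013)))
d <- dplyr::filter(d, compartment == "soluble_mucus", element == "C",
                   treatment != "blank")
compare_groups(data.frame(value = d$enrichment_permil,
                          group = paste0(d$time_h, " h")), value, group)
#> Group comparison (alpha = 0.05 )
#>   Levene p = 0.00688 -> Dunnett T3 post hoc
#>   ANOVA F(3,16) =84.95, p =4.821e-10
#>   group     n    mean    sem letters
#> 1 0 h       5   0.317  0.357 a
#> 2 12 h      5 490.    12.5   c
#> 3 24 h      5 433.    15.1   c
#> 4 6 h       5 218.    44.3   b
```

Variances are heterogeneous across times (Levene p < 0.05), so the ladder
routes to Dunnett's T3; the letters say soluble-mucus ¹³C enrichment rises
from baseline (a) through 6 h (b) to a 12–24 h plateau (c). The renewal
trial contrast:

```r
rsim <- simulate_renewal(preset, seed = 1)
ren <- analyze_renewal(rsim$samples, rsim$fish, preset$dose,
                       default_mass_model(c(liver = 0.013)))
ren[ren$metric %in% c("collected_mucus_mg", "mg_per_cm2",
                      "total_mucus_C_enrichment_permil"), ]
#>                            metric control_mean control_sem renewal_mean renewal_sem  p_value significant
#> 1              collected_mucus_mg       551.77      31.849        281.5      24.256 2.52e-06        TRUE
#> 2                      mg_per_cm2         7.63       0.242          4.3       0.336 2.31e-07        TRUE
#> 3 total_mucus_C_enrichment_permil       278.38      14.682        642.8      14.991 1.23e-07        TRUE
```

Removing the mucus layer before the meal roughly halves the mucus collected
24 h later while more than doubling its ¹³C enrichment: the replacement
mucus is built largely from newly assimilated dietary carbon.

A thin command-line wrapper over the same functions ships at
`inst/cli/mucotrace.R` (subcommands `convert`, `simulate`,
`analyze-timecourse`, `analyze-renewal`, `stats`).

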