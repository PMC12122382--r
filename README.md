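# tsbdecay

Patient-specific exponential decay modelling of total serum bilirubin (TSB)
in very preterm infants (24–32 completed weeks of gestation).

After the first days of life, TSB in preterm infants declines towards a low
baseline as bilirubin metabolism matures. Characterising that decline per
infant matters twice over: the fitted parameters summarise how each infant's
clearance develops, and deviations of new measurements from the expected
decay can flag complications (sepsis, necrotising enterocolitis) that
co-occur with TSB rebounds and elevated C-reactive protein (CRP). This
package is aimed at neonatal researchers and biostatisticians working with
longitudinal TSB records — and, since such records are rarely shareable, it
ships a synthetic cohort generator with ground truth so every analysis step
is testable end to end.

## The model

For infant *i* with gestational age at birth *GA<sub>i</sub>* (days), TSB
(µmol/L) at postnatal age *p* (days) is modelled as

> y<sub>i</sub>(p) = A<sub>i</sub> · exp( −B<sub>i</sub> (p + GA<sub>i</sub> + Tc<sub>i</sub>) ) + C<sub>i</sub> + ε<sub>i</sub>

* **A** — amplitude (µmol/L), bounded to [0, 200] at fit time;
* **B** — decay rate (per day), bounded to [0, 1.5];
* **C** — baseline asymptote (µmol/L), non-negative;
* **Tc** — time-correction (days) which, together with GA, shifts the curve
  along the age axis; fitted values sit near −GA so the combined shift is
  small;
* ε — measurement/modelling error.

A and Tc enter the curve only through the composite amplitude
Ã = A·exp(−B·(GA+Tc)), which the package reports alongside the raw
parameters (only Ã, B and C are identifiable from data).

Each infant is fitted by bounded nonlinear least squares over a candidate
grid: {plain least squares, smooth-L1 robust loss at four MAD-adapted
scales} × a deterministic multi-start set, selecting the candidate with the
lowest plain sum of squared residuals. Around the per-infant model the
package provides the inclusion cascade (minimum 4 samples, no monitoring gap
over 10 days, removal of samples drawn during phototherapy or exchange
transfusion), population summaries with a median model and local
one-at-a-time sensitivity sweeps, and RMSE-based association with elevated
CRP (> 5 mg/L), including a deviation alert for newly drawn TSB levels.

## Worked example

```r
library(tsbdecay)

cfg <- load_config()                       # documented defaults
gen <- generate_cohort(generator_settings(cfg, n_patients = 72L, seed = 42L))
outcomes <- apply_inclusion_pipeline(gen$cohort, cfg)
#> inclusion pipeline: 69 of 72 patients included
sub  <- retained_cohort(gen$cohort, outcomes, cfg)
fits <- fit_cohort(sub, fit_settings(cfg))

fits[["P0016"]]
#> <tsb_fit> P0016: A=117 B=0.136 C=9.08 Tc=-176.8 (Atilde=142) rmse=11.2 [plain/start12]

as.data.frame(summarize_parameters(fits))
#>      parameter  n     mean     sd   median        q1       q3       min    max
#> A            A 69  116.940 64.464  120.778   76.1729  194.954    0.0000  200.0
#> B            B 69    0.312  0.454    0.139    0.0322    0.427    0.0000    1.5
#> C            C 69   28.093 44.497    3.142    0.0000   36.480    0.0000  225.8
#> Tc          Tc 69 -193.653 35.517 -193.452 -217.3944 -173.602 -304.0434 -102.0
#> rmse      rmse 69    9.456  9.944    5.751    2.5840   14.441    0.0315   41.3

build_median_model(as.data.frame(fits))
#> <decay_parameters> A=120.8 B=0.1387 C=3.142 Tc=-193.5 ga_days=198.6

tab <- rmse_crp_table(fits, sub)
attr(tab, "spearman")
#> [1] 0.503
```

Reading the output: patient P0016's TSB declines at 0.136/day from a
composite amplitude of 142 µmol/L towards a 9 µmol/L baseline, with a fit
RMSE of 11.2 µmol/L. Across the cohort the fitted decay rates cluster near
0.14/day and Tc centres near −194 days (≈ −GA). The positive Spearman rank
correlation between per-patient RMSE and the count of elevated CRP results
reflects the injected morbidity events: infants whose TSB rebounds are
fitted worse and show CRP elevations in the same window.

A newly drawn TSB far above the expected decay raises an alert:

```r
deviation_alert(fits[["P0016"]], list(pna_days = 20, tsb_umol_l = 185))
#> $predicted_tsb  18.5
#> $residual       166.5
#> $threshold_used 22.5     # max(2 * rmse, 10 umol/L)
#> $alert          TRUE
```

A command-line pipeline wrapping these functions is installed at
`inst/cli/tsb_pipeline.R` (`simulate` and `run` subcommands); all stage
outputs are plain CSV plus a JSON manifest.

## Vignette

`vignettes/tsb-decay-modelling.Rmd` documents the model and its
assumptions, the fitting strategy and its numerical choices, what the
synthetic generator does and does not emulate, and known limitations.
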