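# imgcea

Cost-effectiveness analysis of diagnostic imaging strategies for detecting
bone metastases in recurrent prostate cancer, built as a decision tree
feeding a five-state Markov cohort model.

## The problem

After definitive treatment for localized prostate cancer, a rising PSA
(biochemical recurrence, BCR) triggers imaging to find out whether the
disease has spread to bone — a turning point for both prognosis and
treatment. Three whole-body modalities compete for this job:
¹⁸F-sodium-fluoride PET/CT (NaF), ¹⁸F-fluorocholine PET/CT (FCH) and
diffusion-weighted MRI (DW-MRI). They differ in sensitivity/specificity
(and in how much those depend on who reads the images) and in per-scan
cost. `imgcea` answers the health-economic question: which strategy
maximises quality-adjusted life-years (QALYs) per euro for this
population?

## The model

A decision tree splits a cohort of 10,000 patients aged 70 by true
metastatic status (prevalence π = 7/55) and test result, sending true
negatives to the *m0-BCR* state, true positives to *m1-BCR*, false
negatives to a one-cycle tunnel state (diagnosis corrected after one
year) and false positives to a misdiagnosis state with m1-like hazards.
A Markov model with annual cycles then tracks *m0-BCR*, *m1-BCR*,
*m0-CRPC*, *m1-CRPC* (castration-resistant disease without/with bone
metastases) and *death* over a lifetime horizon. Death probabilities
combine state-specific excess mortality with age-dependent background
mortality qₓ on the rate scale:

    p* = 1 − ∏ᵢ (1 − pᵢ)        (probabilities combined via annual rates)

Each state-cycle accrues utilities (QALYs) and annual management costs,
counted by the half-cycle-corrected life-table method and discounted at
4%/year. Strategies are compared on the efficiency frontier (strict +
extended dominance) via the incremental cost-effectiveness ratio
ICER = ΔCost/ΔQALY, with one-way (tornado) and probabilistic (Monte
Carlo, with cost-effectiveness acceptability curves) sensitivity
analyses. A diagnostics module computes Se/Sp/PPV/NPV with exact
Clopper–Pearson intervals and the paired comparisons (Cochran Q, McNemar,
Cohen's κ), and a synthetic-data layer (trial generator, gamma cost logs,
Gompertz life table) lets the whole pipeline run with no external data.

## Worked example

```r
library(imgcea)
out <- run_base_case(NULL, "onsite")   # NULL = built-in defaults
print(out$table, digits = 4)
#>   strategy life_years life_years_disc qalys  cost
#> 1      NaF      8.286           6.756 5.821 32031
#> 2      FCH      8.665           7.034 6.075 33305
#> 3   DW-MRI      7.907           6.478 5.570 31111
print(out$frontier, digits = 4)
#>   strategy qalys  cost      status icer
#> 1   DW-MRI 5.570 31111 on_frontier   NA
#> 2      NaF 5.821 32031 on_frontier 3676
#> 3      FCH 6.075 33305 on_frontier 5007
```

Per patient and discounted, DW-MRI is cheapest (31,111 €, 5.57 QALYs);
FCH buys the most QALYs (6.07) at the highest cost; moving from DW-MRI to
FCH costs 4,347 €/QALY (`icer(out$results[["DW-MRI"]], out$results$FCH)`)
— cheap by any conventional willingness-to-pay threshold, so FCH is the
preferred strategy whenever a QALY is valued above a few thousand euros.
The internal-validity check runs the model without imaging:

```r
round(run_validation(NULL), 2)
#> overall m0_only m1_only
#>    6.72    9.33    4.12
```

i.e. a 70-year-old with non-metastatic BCR lives 9.3 more years on
average, 4.1 if bone metastases are already present. These numbers are on
the bundled synthetic Gompertz life table; supply a national period table
as a two-column `age,qx` CSV via `--lifetable` or the config to use real
background mortality.

The published analysis this package re-implements is reproduced in its
incremental structure (QALY differences, dominance ordering, validation
life expectancies); its absolute per-strategy levels are not derivable
from its published inputs — see `vignettes/imaging-cea-methods.Rmd`
("Known limitations") and `tests/testthat/test-acceptance.R`, where the
level assertions are deliberately left failing.

## Command line

```sh
Rscript inst/cli/imgcea base-case --reading onsite --out-dir results/
Rscript inst/cli/imgcea psa --iterations 1000 --seed 1 --out-dir results/
Rscript inst/cli/imgcea dsa | validate | simulate-trial ...
```

All commands take `--config <json>` (any default overridable), write TSV
tables plus a run manifest, and are byte-reproducible given a seed.

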