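---
title: "Methods: decision-tree + Markov cost-effectiveness modelling of bone-metastasis imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decision-tree + Markov cost-effectiveness modelling of bone-metastasis imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imgcea)
```

## The decision problem

Patients with a first biochemical recurrence (BCR) of prostate cancer — a
rising PSA after definitive local treatment — are imaged to decide whether
the recurrence has already spread to bone. Three whole-body modalities are
compared as strategies: ^18^F-sodium-fluoride PET/CT (NaF),
^18^F-fluorocholine PET/CT (FCH) and diffusion-weighted MRI (DW-MRI). Each
strategy is characterised by its per-patient sensitivity $Se$ and
specificity $Sp$ against a follow-up-based standard of truth, and by a
per-scan production cost. The question is which strategy buys the most
quality-adjusted life-years (QALYs) per euro.

## Model structure

A decision tree allocates a cohort (default 10,000 patients, age 70 at
entry) by true metastatic status (prevalence $\pi = 7/55 \approx 12.7\%$,
the observed trial value) and test outcome:

| branch | mass | entry state |
|---|---|---|
| true negative  | $(1-\pi)\,Sp$     | m0-BCR |
| false positive | $(1-\pi)(1-Sp)$   | FP misdiagnosis state |
| true positive  | $\pi\,Se$         | m1-BCR |
| false negative | $\pi(1-Se)$       | FN tunnel (one cycle) |

The Markov model then runs annual cycles over the five disease states
m0-BCR, m1-BCR, m0-CRPC, m1-CRPC and death (CRPC =
castration-resistant prostate cancer; m0/m1 = without/with bone
metastases), plus the two misdiagnosis entry states. Annual transition
probabilities (95% CI):

* m0-BCR → m1-BCR: 0.0288 (0.0279–0.0297)
* m0-BCR → m0-CRPC: 0.0279 (0.0249–0.0308)
* m0-BCR → m1-CRPC: rate-scale combination of the two probabilities above
* m0-CRPC → m1-CRPC: 0.1520 (0.1080–0.1940)
* m1-BCR → m1-CRPC: 0.2055 (0.1813–0.2251)
* excess death: 0.0413 (m0-CRPC), 0.1306 (m1-BCR), 0.2933 (m1-CRPC)

"Combination" of annual probabilities is additive on the rate scale,
$p^* = 1 - \prod_i (1 - p_i)$, the independent-competing-events
convention that matches probabilities derived from annual rates
(`combine_probs()`). Every state's death probability combines its excess
mortality with the age-specific background probability $q_x$ from a period
life table; the cohort ages one year per cycle, so cycle $t$ uses
$q_{70+t-1}$. The residual "stay" probability is one minus the outgoing
mass. If a parameter combination pushes a row's outflow above one (possible
at extreme sensitivity-analysis bounds or very high $q_x$), the engine
raises an error naming the row; an opt-in `renormalize` mode clamps and
rescales instead, because silent renormalisation hides bad parameter sets.
At the life-table closure age ($q_x = 1$, default 110) every living state
flows to death, which bounds the "lifetime" horizon with no extra stopping
rule.

## Rewards, counting and discounting

Each alive state accrues one life-year per cycle, a utility (m0-BCR 0.89,
m1-BCR 0.74, m0-CRPC 0.86, m1-CRPC 0.83, death 0) and an annual cost in
2016 euros (m0-BCR: 3,524 in the first cycle — which includes one-off
salvage radiotherapy — then 1,844; m1-BCR: 4,816 then 4,815; m0-CRPC:
5,717; m1-CRPC: 12,346). The per-scan imaging cost (NaF 302, FCH 881,
DW-MRI 112) is added once, undiscounted, at entry.

Cycle occupancy is counted by the **life-table method** by default — the
mean of the occupancies before and after each annual transition — which is
the half-cycle-corrected default of this model family; `"start"`
(post-transition) and `"end"` (pre-transition) counting are selectable.
Cycle-$t$ rewards are discounted by $(1+d)^{-(t-1)}$ with $d = 4\%$ per
annum, i.e. the first cycle is undiscounted. Under pure survival
(no disease, unit utilities) `"start"` counting reproduces the curtate
life-table expectancy exactly and `"life-table"` counting adds exactly the
half-cycle term; the test suite asserts both to $10^{-9}$.

## Misdiagnosis mechanics

False negatives enter a one-cycle **tunnel**: for that cycle they are
managed as non-metastatic (m0-BCR utility 0.89 and, by default, the m0-BCR
first-year cost, since clinicians believing the patient non-metastatic may
deliver salvage radiotherapy), but they progress per the m1-BCR row; after
the cycle the residual mass sits in m1-BCR — the diagnosis has been
corrected.

False positives are the genuinely open design point. The engine offers
four policies (`fp_transition_policy`):

* `"m1_dynamics"` (default): the FP state uses the m1-BCR transition row
  and non-progressors remain in it; rewards are m1-BCR's for the first
  cycle only, m0-BCR's subsequent-year cost and utility afterwards.
* `"m1_state"`: as above, but with m1-BCR costs and utility throughout —
  the patient is managed as metastatic for as long as they are
  misdiagnosed.
* `"m1_row_merge"`: one cycle of m1-BCR dynamics, then non-progressors
  merge back into m0-BCR.
* `"m0_row"`: one cycle of m0-BCR dynamics with m1-BCR rewards, then
  merge — the reading under which misdiagnosis affects rewards only.

The default was chosen because the published per-strategy life
expectancies differ by several tenths of a year between strategies whose
only material difference is their false-positive rate; that is only
possible if false positives carry m1-like transition hazards. Under
`"m0_row"` all strategies have identical survival. The first-cycle FP cost
is likewise configurable (`fp_cost_policy`): the default
`"m0bcr_subsequent"` reads the cost rules as "m0-BCR costs without the
first-year salvage radiotherapy"; `"m1bcr_first_year"` implements the
alternative "costs of the m1-BCR state for one cycle".

## Background mortality

`life_table()` objects hold integer ages and annual death probabilities
$q_x$, closed with $q_x = 1$ at a terminal age. Lookups use `floor(age)`
(annual cycles, no interpolation) and ages beyond closure return 1.
`life_expectancy()` computes $e(x) = \sum_{k\ge1} S(k) + \tfrac12$ with the
half-year continuity term togglable.

The bundled default is a **Gompertz fixture**, hazard
$\mu(x) = a e^{bx}$ with $a = 2.5\times10^{-5}$, $b = 0.095$, giving
$e(70) \approx 15.6$ years — the order of magnitude of a contemporary
low-mortality male national population. It is a synthetic stand-in, not a
national table: it has no infant/accident hump (irrelevant above age 70)
and its old-age tail is smoother than observed data. Any real period table
can be dropped in as a two-column `age,qx` text file via the config or
`--lifetable`. Consequently, green tests establish internal correctness of
the engine on a realistic mortality surface, not agreement with any
specific country-year table.

## Outputs and decision statistics

Per strategy the engine reports discounted and undiscounted life-years,
QALYs and costs per patient. `efficiency_frontier()` sorts by QALYs,
removes strictly dominated strategies (no cheaper, no more effective, one
strict), then sweeps out extended dominance until incremental
cost-effectiveness ratios (ICERs) strictly increase; ties on both cost and
QALYs are kept with an undefined ICER between them. `nmb()` and `ceac()`
provide net monetary benefit and acceptability curves; under a degenerate
(zero-variance) probabilistic analysis the acceptability curves are step
functions switching exactly at the frontier ICERs, which the tests assert.

## Sensitivity analyses

One-way DSA (`one_way_dsa()`) reruns the model at both bounds of each
parameter's plausible range — 95% CIs for probabilities and costs, mean
$\pm 1.96\,$SD clipped to $[0,1]$ for utilities — recording the ICER of a
fixed strategy pair (FCH vs DW-MRI by default; frontier recomputation per
bound was considered and rejected so that bars remain comparable). The
m0-BCR and m1-BCR cost groups move their first-year and subsequent-year
components jointly to their respective bounds.

The PSA (`run_psa()`) draws, per iteration: transition probabilities as
$k/n_{\mathrm{eff}}$ with $k \sim \mathrm{Bin}(n_{\mathrm{eff}}, p)$ and
$n_{\mathrm{eff}} = \mathrm{round}(p(1-p)/se^2)$, $se$ from the 95% CI
half-width (a binomial draw for a continuous utility is not implementable
without a denominator, so utilities instead use a moment-matched beta on
their stated mean/SD — they remain in $[0,1]$ by construction); costs from
gamma distributions moment-matched to the mean and
$\mathrm{SD} = (\mathrm{CI_{high}} - \mathrm{CI_{low}})/3.92$; and strategy
$Se$/$Sp$ binomially with the trial denominators (7 positives, 48
negatives). Parameters are sampled independently — no correlation
structure is claimed by the source estimates. The headline PSA ICER is the
ratio of mean incremental cost to mean incremental QALYs (the mean of
per-draw ratios is sign-unstable and is reported separately). Everything
is reproducible from a single seed.

## Synthetic trial generator

`generate_trial()` emulates the 55-patient diagnostic trial (7 metastatic)
with three modalities read on-site and centrally. In `exact_counts` mode
the per-modality 2×2 margins are reproduced deterministically by a greedy
fill in patient-index order; because only margins are published, the joint
assignment across modalities is underdetermined, so cross-modality
statistics (Cochran Q, kappa) on exact-count fixtures are
fixture-dependent and are never compared to published agreement values. In
`sampled` mode truth is Bernoulli(prevalence) and calls are conditionally
independent given truth — which also ignores the real-world correlation of
errors across modalities within a patient. Observed inter-reading kappas
(0.96/0.86/0.59) are therefore not regression targets.

## Validation convention

`validate_life_expectancy()` runs the model without imaging and reports
undiscounted life expectancy from an m0-BCR start, an m1-BCR start, and an
`overall` mix. The default `m1_weight = 0.5` reports the midpoint of the
two state expectancies, which is the convention under which the published
overall value (6.7 years at age 70) is recovered; a prevalence-weighted
cohort average (weight 7/55) is available via the argument and is about
two years higher, because 87% of the cohort starts in the long-lived
m0-BCR state.

## Known limitations

* With the published inputs the engine reproduces the published
  *incremental* structure (QALY differences between strategies, the
  qualitative strict dominance of NaF under central reading, the
  validation life expectancies) but **not the published absolute levels**
  of per-strategy life expectancy, QALYs and cost, which are 15–45% lower
  than any configuration of this engine family produces from those same
  inputs. The package's tests compute both and leave the level assertions
  failing rather than tuning parameters toward them; the discrepancy is
  analysed in the repository notes. Users comparing against the published
  table should rely on increments, ICER ordering and dominance structure.
* Statistical diagnostics are patient-level only; lesion/region-level
  analysis is out of scope.
* A false negative is reward-dominant over a true positive for its first
  cycle (utility 0.89 vs 0.74 with identical transitions), so QALYs
  decrease marginally in sensitivity; this follows directly from the
  published reward rules and is asserted as such in the tests.
* Lymph-node staging pathways, sub-annual cycles and correlated PSA
  sampling are out of scope.
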