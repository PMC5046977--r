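---
title: "Mitotic clocks from DNA methylation: model, construction and validation"
author: "epitoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mitotic clocks from DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitoc)
```

## The replication-error model

The package rests on a simple generative picture. A tissue's cancer
risk is taken to be monotone in the cumulative number of stem-cell
divisions per stem cell,

$$TNSC(s,t) = A(s)\,[IR(t) + E(s)\,ER(t)],$$

with $A$ the chronological age, $IR$ the tissue's intrinsic division
rate (divisions per stem cell per year), and $E\cdot ER$ an
exposure-driven extrinsic component that is zero in healthy,
unexposed tissue. A class of CpG sites accrues stochastic methylation
errors at cell division, so their cumulative methylation deviation is
linear in $TNSC$:

$$score(s,t) = \alpha(t) + \xi(t)\,TNSC(s,t) + \varepsilon.$$

In a healthy single-tissue cohort ($E\approx 0$, $IR$ constant) this
collapses to a linear age model $score = \alpha' + \gamma' A$ with
$\gamma' = \xi\,IR$, which is what `calibrateClock()` fits by ordinary
least squares. Given a literature estimate of $IR$, the calibration
inverts a score to a division estimate,
$TNSC = (score-\alpha')\,IR/\gamma'$ (`estimateTnsc()`); without $IR$,
the ratio $(score_1-\alpha')/(score_2-\alpha')$ still compares two
samples of the same tissue (`tnscRatio()`). The assumptions worth
keeping in mind: error accrual is linear in divisions (no saturation
within the observed range), $IR$ depends only on tissue (genetic
variation in division rate is ignored), and the calibration tissue
matches the scored tissue. Division estimates are only meaningful
within one tissue; the model deliberately makes no cross-tissue risk
comparison.

## Why the CpG filters look the way they do

Age correlation alone does not make a mitotic clock: many age-related
methylation changes reflect cell-composition drift or non-mitotic
programs. The construction pipeline therefore intersects several
constraints (`selectClockCpgs()`):

* **FDR-significant age association** (`runEwas()`, BH q < 0.05) in a
  single-tissue healthy cohort, adjusted for plate, sex and cell-type
  fractions. Fractions come from constrained least squares against a
  reference panel (`estimateCellFractions()`): weights are nonnegative
  and sum to one, the natural constraints for compositions, solved by
  a dual active-set quadratic program.
* **Unambiguous TSS200 promoter location** — probes within 200 bp of a
  single annotated transcription start site. Promoter CpGs of this
  kind share a common low ground state, which makes a mean-over-probes
  score comparable across its constituent sites.
* **Fetal ground state** — hypermethylation-clock CpGs must be below
  beta 0.2 in *every* fetal sample (strictly), so any adult signal is
  acquired; hypomethylation-clock CpGs must be at or above 0.3 in
  every fetal sample, so observed losses are genuine. The strict
  versus inclusive boundary semantics follow the construction rule as
  stated, and the per-sample (not per-tissue-mean) reading is the
  conservative interpretation.
* **PRC2/Polycomb marking** (hyper clock only) — Polycomb-target
  promoters are the sites known to gain methylation during normal
  ontogeny in proportion to turnover.

Filters are conjunctive, so membership is order-independent; the audit
table reports removals in cascade order for transparency. Two
interpretive choices are worth flagging. The construction regression
is fit with methylation as the response and age as the predictor
(the per-probe error model is then standard and the coefficient is
drift per year); the selection outcome only uses the coefficient sign
and its p-value, both of which are direction-symmetric for simple
regression. And "unambiguous" TSS200 mapping is read as
annotation-unambiguity (exactly one gene), not sequence-level
multi-mapping, which a probe annotation table cannot resolve.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `fdrThreshold` | 0.05 | BH q-value cut for age association |
| `fetalHyperBound` | 0.2 | strict upper bound on fetal beta (hyper) |
| `fetalHypoBound` | 0.3 | inclusive lower bound on fetal beta (hypo) |
| `minCoverage` | 0.95 | fraction of clock CpGs a sample must cover |
| `tolerance` (age matching) | 5 | years; maximum allowed pair gap |
| `ci` (ROC) | DeLong | deterministic CI; bootstrap (2000×) optional |

`minCoverage` defaults high because a mean-over-probes score shifts
when probe support differs between samples; below the threshold a
sample is flagged rather than scored. Negative division estimates
(scores below the intercept) are returned with a flag, never clipped —
silent truncation would hide calibration misfit.

The shipped calibration registry (`shippedCalibrations()`) carries the
published constants for whole blood (α′ = 0.052, γ′ = 0.000345 per
year), normal breast (0.053, 0.000165) and normal lung (0.021,
0.000588, IR = 0.07), and `tissueRates()` the literature division
rates used for normal-tissue validation. They are defaults, not
dogma: any cohort can be recalibrated with `calibrateClock()`.

## Statistical choices in the validation battery

* The "age-adjusted" rank test has no canonical definition; the
  package residualises both groups against age with a single pooled
  OLS and ranks the residuals, and always reports the unadjusted p
  alongside. This is transparent and reproducible, but it is an
  interpretation, and rank tests on residuals are only approximately
  distribution-free.
* A "paired rank-sum" comparison is carried out as the Wilcoxon
  signed-rank test — the rank-sum statistic has no paired form.
* Small samples without ties use exact enumeration; otherwise the
  normal approximation with tie and continuity correction applies
  (the `stats::wilcox.test` machinery in both regimes).
* AUC is the Mann–Whitney probability with ties counted one half;
  the default CI is DeLong because it is deterministic.
* Age matching is greedy nearest-neighbour without replacement,
  smallest gap first, identifiers breaking ties — simple, deterministic
  and auditable, though not globally optimal like full bipartite
  matching.

## What the simulator emulates — and what it does not

`simulateCohort()` generates cohorts directly from the model above:
ages uniform on 20–100; tissue-specific $IR$; optional log-normal
exposures per group; planted hyper/hypo clock CpGs with per-division
drift $\xi_c$ drawn uniformly from $2\times10^{-5}$–$6\times10^{-5}$;
a cell-mixture confounder (lineage-informative probes mixed by
proportions whose log-odds drift with age); mean-preserving
beta-family measurement noise; and a nine-gene expression panel
linear in the proliferation rate $IR + E\cdot ER$.

Default magnitudes were fixed once, on field-realism grounds: a blood
division rate of 13 per stem cell per year (hematopoietic order of
magnitude), which with the drift range above implies a blood slope
$\bar\xi\,IR \approx 5\times10^{-4}$ per year — the same order as the
published whole-blood $\gamma'$; noise precision 200, giving a
per-probe standard deviation near 0.02 at beta 0.1, typical of array
replicates; a composition trend of ±0.4 log-odds across the adult age
range (a few percentage points per decade). The beta-family noise was
chosen over a truncated Gaussian because it respects the [0,1] support
at extreme means without distorting them. Drift is linear with hard
clipping at [0,1]; clipped cells are counted and reported by warning
so analyses can avoid the saturated regime. $\xi$ is taken
tissue-independent, which is the model's own simplification; the
published per-tissue calibrations suggest real drift rates differ by
tissue, so cross-tissue simulations should be read qualitatively.

What passing simulation tests shows is that the pipeline recovers the
model's own structure — planted CpGs, the implied slope, direction of
group effects — under realistic noise and composition confounding. It
does not show robustness to array artifacts (probe-type bias, batch
effects), non-linear composition effects, or drift saturation, none
of which the generator produces.

## Numerical and degenerate-input conventions

* Deconvolution with a rank-deficient reference (duplicated cell
  types) adds a $10^{-10}$ ridge, warns, and returns the unique
  ridged solution, splitting ties evenly between equivalent columns.
  Samples missing more than half the shared probes are not fit.
* EWAS probes with constant methylation or too few complete
  observations are flagged and excluded from testing (and from the BH
  family); collinear designs are an error naming the offending
  columns.
* BH q-values go through `stats::p.adjust`; the test suite checks the
  step-up definition independently by brute force.
* Beta values are used as-is (no M-value transform), matching the
  score's definition as a mean beta; expression is averaged on the
  supplied scale with no internal log transform.
* Missing beta tokens accepted on input: `NA`, `NaN`, empty
  (case-insensitive). Values outside [0,1] are an error unless
  clipping is explicitly requested, in which case the count of
  clipped cells is reported.

## Problem sizes in the shipped tests

The test and acceptance runs use the scenario defaults: 500 × 2000
(samples × probes) for construction-recovery over 10 seeds, 288
samples across eight tissues for the multi-tissue analogue, 50 pairs
for the tumor analogue, 300 samples for the dose analogue, and 20
seeds of 200 × 100 null matrices for type-I calibration — sizes at
which every property is stable while a full run stays in the minutes
range on a single core.

## Known limitations

The hypomethylation clock is recovered with lower sensitivity than the
hyper clock at equal drift, a direct consequence of beta-value
heteroscedasticity (variance peaks at intermediate methylation, where
hypo-clock ground states live); this mirrors the weaker behaviour of
hypomethylation-based scores on real cohorts. Calibration transfers
only within tissue. The exposure term conflates dose and rate
($E\cdot ER$), so only their product is identifiable. And the
excess-divisions arithmetic follows the ratio form
$(TNSC_l/TNSC_n)\times f \times N$ as printed in the source
derivation, although a difference-based reading of "additional
divisions" would be arithmetically natural; the discrepancy is noted
in `?excessDivisions` rather than resolved.
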