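---
title: "Methods: dual-readout RNAi screen analytics and the 48-condition survival scan"
author: "screenSurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-readout RNAi screen analytics and the 48-condition survival scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenSurv)
```

# The problem

Genome-scale RNAi screens against cancer cells are commonly read out by a
fluorescence viability assay (resazurin reduction, proportional to the
metabolic activity of live cells). When surviving cells upregulate their
metabolism — as cells surviving a cytotoxic insult often do — the well-level
viability signal underestimates the kill, and image-derived cell counts
(stained nuclei per well) resolve effects the viability assay misses.
screenSurv analyzes screens that carry **both** readouts per well, in two
co-treatment arms (vehicle and a chemotherapy partner such as cisplatin),
and follows up candidate genes with a survival-biomarker scan over a
patient cohort with expression, mutation and follow-up data.

# Screen model and quality control

A screen is a set of 384-well plate instances — one physical plate per
(library plate, screening repeat, co-treatment arm) — each carrying
non-targeting negative-control wells (siNC), strong positive-control wells
(siPLK1, an essential kinase whose knockdown kills most cancer lines), one
well per library gene and trailing empty wells. Data are long-format
`WellRecord` rows inside a `ScreenExperiment` container; missing readouts
are `NA`, never zero.

Per plate instance and readout, assay quality is the z'-factor computed
from raw control wells:

$$z' = 1 - \frac{3\,(sd_{\mathrm{pos}} + sd_{\mathrm{neg}})}
                {\lvert \overline{x}_{\mathrm{pos}} -
                        \overline{x}_{\mathrm{neg}} \rvert}$$

with the sample (n−1) standard deviation, since control wells are a sample
of plate behavior. Values above 0.5 indicate an excellent screening window,
above 0 a borderline one, at or below 0 a failed plate; the thresholds are
strict inequalities and can be overridden. A second variant
(`variant = "as-printed"`) *subtracts* the SDs in the numerator. That form
appears in some write-ups, but it awards z' = 1 to a plate whose controls
are equally noisy, contradicting the definition of a screening window, so
we treat it as a transcription slip and default to the summed form while
keeping the subtracted form reproducible behind the flag.

QC is computed per (plate, batch, readout) within each co-treatment arm:
the arms are treated after transfection per plate set, so each arm's
controls characterize its own assay window. Whether QC should instead pool
plates per batch was genuinely open; per-plate is the finer-grained and
more conservative choice.

# Normalization and hit calling

Both readouts are converted per plate instance to
$\log_2(\mathrm{raw}/\mathrm{center}(siNC))$. Negative values mean fewer
cells (or less signal) than the negative controls. The siNC center is the
**median** by default — one transfection-failed control well otherwise
drags every well on the plate — with the mean behind a flag. Because each
plate instance is normalized against its own controls, plate- and
batch-level multiplicative shifts cancel, and the cisplatin arm's values
isolate the siRNA effect on top of the drug.

A gene's per-arm effect is the mean of its per-batch normalized values
(screens run in triplicate; each batch is an independently cultured
repeat). Significance is a two-sided independent two-sample Student t-test
(pooled variance; Welch behind a flag) of the gene's replicate values
against the normalized siNC well values of the gene's own plate across
batches. Comparing against the siNC wells rather than against zero uses
the controls' empirical spread as the null reference; the against-zero
one-sample form is available behind a flag. With fewer than two replicates
the effect is reported and the p-value is missing.

Hit rules, on the count readout: an arm is *significant* when p < 0.01 and
log2 fold change ≤ −1 (at least a twofold count decrease; inhibitory
effects only). `COMMON` hits are significant in both arms.
`CISPLATIN_SENSITIZED` hits are significant in the combined arm only, with
the combined-vs-single contrast (two-sample t-test on per-batch normalized
values) at p < 0.01 and the combined mean more inhibitory. No
multiple-testing correction is applied — the screen's published selection
rule is a fixed raw threshold — and this is stated prominently wherever
hit counts are reported.

# Derived statistics

*Viability per cell* is the raw quotient viability/count, a proxy for the
per-cell metabolic state of survivors; a zero count is signalled (NA with a
warning), never silently infinite. A normalized variant can be formed from
the anti-logs of the per-well log2-normalized values; the raw ratio is
primary because the exact normalized construction used in published
scatter plots is generally under-specified.

*Percent growth inhibition* for validation assays:

$$\%GI = \frac{N(\mathrm{treated},96h) - N(0h)}
              {N(\mathrm{control},96h) - N(0h)} \times 100,$$

scale-invariant in the three counts, 100 when treatment equals control, 0
at no net growth, negative for net kill below seeding.

*Self-renewal synergy*: after treatment, surviving cells are reseeded
across a density series (40–2000 cells per well) and regrowth is counted.
Counts are expressed as percent of the untreated control condition
**within each seeding density**, then the additive expectation for the
combination is the *sum* of the two single-treatment changes. The
combination is flagged synergistic when its observed change undershoots
the additive expectation by more than a tolerance. No published tolerance
exists; the default is the replicate standard error of the combined
condition, so a single noisy replicate cannot manufacture synergy. This is
deliberately not a Bliss/Loewe/HSA model — the synergy concept here is
strictly the additive-sum comparison.

*Serial-treatment contrast*: per-gene difference of mean percent-of-siNC
effects between cisplatin-pretreated and fresh cells, with a two-sample
Student t-test.

# Survival scan

Expression arrives as FPKM and is converted to $\log_2(TPM+1)$ with
$TPM_i = FPKM_i / \sum_j FPKM_j \times 10^6$; the per-sample TPM sum is
$10^6$ to floating tolerance (tested at $10^{-6}$ relative).

The Kaplan–Meier estimator and the two-group log-rank test are implemented
from first principles (the package's survival layer has no run-time
dependency on the survival package, which serves only as an independent
cross-check in the test suite). Ties put events before censorings:
subjects censored at *t* remain at risk for events at *t*. The log-rank
statistic accumulates observed-minus-expected events with the
hypergeometric variance at each distinct event time and is referred to
$\chi^2_1$; an exact permutation p-value over group-label reassignments is
available for small groups and is used to validate the asymptotic p at
n ≤ 10.

Endpoints are derived from registry-style clinical fields: OS time is days
to death for deceased samples, else days to last follow-up (censored);
the DFS event is the first of new tumor event or death. Expression splits:
`median` assigns HIGH strictly above the median (ties LOW); `quartile`
compares the top quarter (> 75th percentile) against the bottom quarter
(< 25th), excluding the middle half. Percentiles use linear interpolation.
Tie rule and percentile definition are documented because conventions vary
and published descriptions rarely pin them down.

The prognostic scan evaluates 48 = 2 endpoints × 2 splits × 3 gender
filters (female, male, both) × 4 stage filters. The grid is exactly the
published 3 × 4 × 2 × 2 reading; note it contains **no all-stage cell** —
every cell conditions on a single stage. Splits are computed within the
filtered subset so each cell's groups are non-degenerate whenever enough
samples remain. The best (smallest) p across cells with both groups
non-empty yields the prognosis call — UNFAVORABLE when the high-expression
group fares worse in the best cell, FAVORABLE for the reverse, NONE at
best p ≥ 0.05 — with reporting tiers at p < 0.05 and p < 0.01. Best-p ties
break by the fixed cell ordering (endpoint, split, gender, stage).

**Selection inflation.** Taking the minimum of 48 correlated, uncorrected
p-values inflates the false-positive rate of the call, and the package
measures rather than corrects this (the published rule is reproduced
as-is). The null calibration in the test suite and acceptance script
(planted hazard ratio 1.0, n = 300) finds best p < 0.05 in roughly 80% of
null cohorts. The driver is the grid's structure: the 12 gender × stage
subsets are disjoint, so the scan performs ~12 nearly independent looks
(each further multiplied by correlated endpoint/split variants), and
1 − 0.95^12 alone is ≈ 0.46. Consequently a NONE call on real data is
strong evidence of no signal, while a P05-tier call on its own is weak
evidence of one; only the P01 tier, or consistency across many cells,
should be read as a prognostic association. For the same reason, the
contrast "significant in mutation carriers but NONE in the full cohort" is
rarely observable even when the hazard effect is genuinely
carrier-confined: a carrier-only effect at 25% carrier prevalence still
lifts the full-cohort high-expression hazard (mixture hazard ratio ≈ 1.5),
which the always-significant-somewhere scan picks up. The corresponding
acceptance check is therefore expected to fail as specified, and the
stratified-vs-unstratified comparison should be interpreted through the
subset sizes and per-cell p-values it reports, not through the binary
call contrast.

Mutation stratification subsets the cohort to samples whose mutation set
intersects a user-supplied gene set (e.g. a GPCR-signaling mutation list)
and re-runs the scan on the subset, reporting the subset size. The
oncoprint module returns the binary sample × gene mutation matrix with
per-gene frequencies and pairwise co-occurrence counts; rendering is out
of scope.

# Synthetic data: what it emulates and what it does not

The generators define the package's study conditions; every distributional
default below was chosen once, on domain grounds.

**Screen** (`screenSimConfig`): 384-well plates with 16 siNC and 16 siPLK1
wells per plate, one well per gene, 3 batches, both arms. Counts are
lognormal around `baselineCount = 1600` (400 seeded cells over four days,
roughly two doublings) on the log2 scale —
`round(1600 * 2^(effect + armShift + plateShift + noise))` — because the
analysis model is log2-ratio based and the lognormal keeps the noiseless
oracle exactly invertible (a negative binomial alternative sits behind
`countModel = "nb"`). The siPLK1 effect is −3 log2 (a strong kill); the
cisplatin arm applies a global −1 log2 count shift (an
order-of-magnitude-plausible effect of 1 µM cisplatin on a lung
adenocarcinoma line; a free parameter, not a measured value). Noise
defaults: count CV 10%, viability CV 15% — imaging-based counting is the
tighter readout, which also reproduces the empirical ordering of count
vs viability z'-factors — and a per-plate-instance log2 shift of SD 0.1
emulating batch/handling effects. `resistanceGain = 0.5` makes the
per-cell viability of killed wells rise by half a log2 per log2 of count
lost, emulating the resistance phenotype of surviving cells; this term is
what makes the dual-readout comparison informative. The generator does
**not** emulate spatial (edge) effects, siRNA off-target structure, or
readout saturation; passing tests therefore certify the analysis logic,
not robustness to those artifacts.

**Cohort** (`cohortSimConfig`): gender 54/46 female/male and stage
probabilities (53, 25, 17, 5)% chosen to resemble a resected lung
adenocarcinoma registry cohort; exponential survival with baseline hazard
1/730 per day (two-year median) and independent exponential censoring at
1/1095 per day (roughly three-year follow-up, ~60% event fraction);
recurrence as an extra exponential process at half the death hazard so DFS
events precede or coincide with OS events; a latent high/low expression
mixture for the focal gene (shift 2 on log2(TPM+1), SD 1 — cleanly but not
perfectly separable by a median split); and a proportional-hazards effect
of the high component, optionally confined to carriers of a mutation gene
set (carrier fraction 0.25 by default). Times are rounded up to whole
days, producing realistic ties. Not emulated: stage- or gender-dependent
hazards, non-proportional hazards except the carrier mixture, competing
risks, or correlated expression across genes.

All randomness flows from the single config seed through an RNG scope that
restores the caller's stream, so generation is reproducible and leaves no
hidden global state.

# Numerical choices and degenerate inputs

* Sample SDs everywhere (n−1); control statistics need ≥ 2 wells per class.
* Zero/negative raws have no log2 image and raise an error; missing values
  propagate without becoming zeros; an all-missing plate readout yields
  all-missing output rather than an exception.
* z' with coincident control means is signalled as undefined, not NaN.
* Median split ties go LOW; quantiles interpolate linearly (type 7).
* Log-rank variance uses the standard tie-corrected hypergeometric form;
  cells with no events or an empty group report a missing p.
* Exact permutation p includes the identity assignment (so it is never 0),
  and sampled permutation p uses the add-one estimator.

# Problem sizes used in the checks

The test suite and acceptance script run the full pipeline at the scale
the analyses were designed for: 390-gene screens in triplicate and both
arms (≈ 4600 wells per screen) over 20–25 Monte-Carlo seeds for the
type-I and hit-recovery checks, cohorts of n = 120–400 over 50–200 seeds
for the survival checks, and exhaustive 252-permutation enumeration for
the exact log-rank oracle at n = 10. These sizes give Monte-Carlo standard
errors small enough for the stated bounds (e.g. ~0.0013 on the null 0.01
fraction) while completing in a couple of minutes on one CPU.

# Known limitations

* No spatial/plate-layout normalization (B-score, median polish); plates
  with systematic edge effects will leak those into gene effects.
* Raw-p hit selection and best-of-48 scanning are reproduced uncorrected,
  as published; both inflate discoveries, quantified above.
* No Cox regression or hazard-ratio estimation; the survival layer is
  KM + log-rank only, matching the published analysis.
* The additive-sum synergy concept does not distinguish potentiation from
  independence the way Bliss/Loewe models would.
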