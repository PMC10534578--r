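---
title: "Methods: the ASGO scoring model, its validation statistics, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ASGO scoring model, its validation statistics, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asgo)
```

## The instrument model

The ASGO describes a hospitalised patient on ten non-medical functions.
Each variable has an expert-assigned weight (the ten weights sum to 10) and
up to seven ordered modalities; the modality at level rank $\ell$ of a
variable with weight $w$ contributes the ranking value $w\ell$. An
assessment selects at least one modality per variable — exactly one except
for circulation, feeding, elimination and the sensory system, which allow
several — and is scored

$$\text{raw} = \sum_{\text{selected}} w_j\,\ell_{j}, \qquad
  \text{FD} = \text{raw}/10 .$$

Because first-level ranking values equal the weights themselves, the
all-minimum assessment scores exactly 10.0; with single selections the
ceiling over the shipped grid is 70.0. The FD index is banded into care
profiles. Three readings of the published material had to be reconciled
here, and the package commits to the one that makes the score range, the
bands and the dependence cut-off simultaneously coherent: the raw score is
the plain sum of ranking values (no further division), the $/10$ produces
the FD index, the profile bands apply to the FD index, and the dependence
cut-off (around 22.5) applies to the raw score.

Four further choices were genuinely open:

* **Multi-select combination.** Several selected modalities of one variable
  are *summed* (default), since the scale measures cumulative commitment to
  support needs and the sum preserves additivity and strict monotonicity;
  `combine = "max"` is available for sensitivity analysis.
* **Profile band gaps.** The printed bands (1.1–2.59, 2.6–3.69, 3.7–4.79,
  ≥4.8) leave gaps at one-decimal precision. We use left-closed, right-open
  intervals $[1.0, 2.6)$, $[2.6, 3.7)$, $[3.7, 4.8)$, $[4.8,\infty)$ —
  exhaustive, non-overlapping, with the minimum band extended down to the
  analytic floor FD = 1.0 and the printed 2.6/3.7/4.8 edges kept.
* **Movement/ambulation** ships the six printed modalities with level ranks
  $\{1,2,3,4,5,7\}$ (ranking values 1.3…6.5, 9.1); no level-6 modality is
  invented.
* **Barthel item maxima** follow the original Mahoney–Barthel allocation
  (15 points for transfer and walking, 5 for bathing and grooming, 10
  elsewhere), the only allocation consistent with the 0/5/10/15 scoring
  combinations the instrument description lists. Totals ≥ 60 classify as
  independent; ASGO ties *at* the cut-off classify as dependent.

## The validation statistics

All statistics behind `run_validation()` are implemented in the package
(established implementations are used only as cross-check oracles in the
test suite).

**Spearman's rho** is the Pearson correlation of midranks. The two-sided
p-value uses $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df. For $n \le 8$
the exact permutation distribution (40,320 permutations at $n=8$) is
enumerated instead; we chose 8 rather than 10 as the exactness boundary
because $10!$ ≈ 3.6 million permutations buys no practical accuracy for the
cost, and the t approximation is already adequate at $n=9$.

**Cronbach's alpha** uses sample (n−1) variances:
$\alpha = \frac{k}{k-1}\bigl(1 - \sum_i s_i^2 / s_T^2\bigr)$; it equals the
covariance form $\frac{k}{k-1}(1 - \mathrm{tr}\,C / \mathbf{1}^\top C
\mathbf{1})$, which the tests verify on random matrices.

**ROC analysis.** Higher ASGO scores mean more dependence, and a subject is
classified dependent when score ≥ threshold. Candidate thresholds sit at
the unique observed scores plus a $+\infty$ sentinel, so the curve runs
from (0,0) to (1,1); `placement = "midpoint"` instead places candidates
between adjacent unique scores — exposed because a published cut-off of
22.25 alongside a tabulated 22.5 suggests midpoint placement may have been
used upstream, but `"unique"` is the default. The AUC is the trapezoid
area, which equals the Mann–Whitney pairwise probability with ties counted
half (an exact identity the tests assert to $10^{-12}$). The **Youden**
cut-off maximizes $J = \text{sens} + \text{spec} - 1$; when several
thresholds tie, the smallest (most sensitive) finite threshold is returned,
a deliberate tie-break since no rule is published.

**Factor analysis.** KMO is built from squared correlations vs squared
anti-image partial correlations of $R^{-1}$ (inputs with reciprocal
condition number below $10^{-8}$ are rejected as near-singular; an identity
matrix makes the statistic 0/0 and is an error). Bartlett's statistic is
$-(n-1-\tfrac{2p+5}{6})\ln\det R$ on $p(p-1)/2$ df. The EFA is a principal
component decomposition of the correlation matrix — loadings are
eigenvectors scaled by $\sqrt{\lambda}$, retention follows the strict
Kaiser rule $\lambda > 1$ — followed by **varimax** rotation: iterated
pairwise planar rotations with Kaiser row-normalization on, convergence
when a full sweep improves the criterion by less than $10^{-8}$, a cap of
1000 sweeps (exceeding it is an error that reports the criterion trace),
column signs fixed so each factor's largest loading is positive, and
columns ordered by explained variance. Rotation preserves row
communalities to $10^{-10}$ and the rotation matrix is orthonormal to the
same tolerance.

The item matrix feeding alpha and the EFA uses each variable's *summed
ranking values* (weighted) by default — `item_values = "levels"` switches
to raw levels — and the EFA runs on admission assessments by default
(`efa_timepoint` accepts discharge or pooled); both choices are logged in
the report header because the published analysis does not state them.
P-values are reported raw, without multiplicity correction, matching the
upstream analysis plan.

## The synthetic cohort

There is no deposited dataset, and the validation design is retrospective,
so the generator is this package's own construction. It was chosen to
reproduce, with one mechanism, the three observable structures the
validation rests on:

1. an inverse ASGO–Barthel association that is *tighter at discharge* than
   at admission,
2. a two-factor item structure (physical functionality vs sensory
   behaviour), and
3. realistic marginal score distributions.

Per patient, a standard-normal **physical dependence trait** $D$ doubles as
the physical factor; the sensory factor is $F_2 = 0.4\,D +
\sqrt{1-0.4^2}\,u$. Each ASGO variable's standardized item latent loads
0.75 on its own block and 0.2 on the other (blocks: physical = mental
status, movement, elimination, feeding, sleep/wake, self-care; sensory =
circulation, breathing, sensory system, mood), and is cut at equally
spaced thresholds (spacing 0.55 latent SD) into the variable's level
ranks. Multi-select variables add a second, uniformly drawn modality with
probability 0.1. Barthel items derive from a latent $B = c\,D +
\sqrt{1-c^2}\,\eta$ plus per-item noise (SD 0.6), thresholded onto each
item's point lattice — so totals are multiples of 5 in [0, 100] by
construction.

Two scalars are *solved*, not hand-tuned:

* the ASGO and Barthel threshold origins are found by `uniroot` on the
  closed-form expected scores (through the normal CDF) so the admission
  means match the configured 27.1 and 39.2;
* the per-timepoint latent correlation $c$ is **calibrated** by a
  deterministic pilot simulation (fixed internal seed, 4000 patients, a
  9-point grid inverted with a monotone spline) so the observed Spearman
  correlations hit the configured targets, −0.5916 at admission and
  −0.7988 at discharge. Targets beyond the model's reach raise an error
  stating the feasible bound.

Discharge traits are $D - 0.35 + 0.3\,\varepsilon$: the 0.35 improvement
shift lowers mean dependence (raising the mean Barthel total and lowering
the mean ASGO score), and the innovation gives discharge its own variation.
The tighter discharge coupling comes from the calibrated larger $c$ at
discharge. Demographics (age 76.4 ± 12.3, 55% male, stay 20.1 ± 13.4 days,
eight admission-reason categories) are decorative marginals: no statistic
consumes them. An optional `pairing_loss_rate` drops a random fraction of
discharge records to emulate incomplete pairing; its default is 0 because
no loss mechanism is documented.

Randomness uses one seeded base-R stream per cohort: a given configuration,
seed and cohort size reproduce bit-identical records. (Record-level
reproducibility independent of cohort size — a counter-based stream — was
considered and dropped as non-idiomatic in base R; nothing downstream needs
it.)

**What passing tests do and do not show.** The generator emulates the
*correlational* skeleton of a real cohort; it does not model ward
clustering, floor/ceiling pile-ups of real Barthel distributions, rater
effects, informative discharge timing, or item-specific response styles.
Tests passing on this cohort demonstrate the pipeline's statistical
machinery is correct and that the design's directional claims
(discharge > admission discrimination, two recoverable factors) follow
from the stated structure — not that the instrument is valid on real
patients.

## Numerical and reporting choices

* Youden tie-break: smallest finite threshold; degenerate single-class
  truth vectors are errors for ROC construction, and the pipeline marks
  those blocks "unavailable" while computing everything else (likewise the
  factor block when $n \le p$ or the correlation matrix is singular).
* Rendered JSON fixes numerics at 6 significant digits so identical inputs
  give byte-identical reports; the $+\infty$ sentinel threshold is
  rendered as JSON `null` (JSON has no Inf). Markdown tables round to the
  conventional two decimals for coefficients and one for means/SDs; CSV
  exports keep the 6-digit values.
* Paired statistics use listwise exclusion: only patients with both valid
  timepoints enter the per-timepoint comparisons; descriptives are
  additionally reported for all assessed rows, labelled separately,
  because the published descriptives do not state which basis they used.

## Problem sizes in the test suite

Unit and property tests run at small n (tens to hundreds). The simulation
checks use the study-scale cohort of 842 patients: 50 seeds for the
correlation-calibration and discrimination-ordering checks (sharing the
same generated cohorts) and 20 seeds for planted-structure recovery —
sizes chosen to keep Monte-Carlo error well below the asserted margins
while the whole suite stays under half a minute on one core.

## Known limitations

* The exact Spearman permutation p is limited to $n \le 8$.
* No confidence intervals for AUC or rho, no principal-axis or
  maximum-likelihood factoring, no oblique rotations — outside the
  validation design this package mirrors.
* The calibration pilot fixes its own internal seed; recalibrating with a
  different pilot size can move the latent correlations by a few
  thousandths, which is far below the ±0.05 tolerance the cohort checks
  use.
* Care-profile boundaries between printed band edges follow this package's
  interval convention (above); scores exactly on a printed edge are
  assigned to the higher band.
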