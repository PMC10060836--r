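---
title: "Anatomically weighted functional connectivity: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomically weighted functional connectivity: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(awfc)
```

## The problem

Functional connectivity (temporal correlation of resting-state BOLD
signals between regions) and structural connectivity (white-matter
streamlines recovered by diffusion tractography) measure different, partly
coupled properties of the same network. Strong structural linkage predicts
strong functional coupling, but the converse is unreliable, so group
differences can be visible in a fused metric that neither modality shows
cleanly on its own. `awfc` implements such a fusion for ROI-level inputs,
with the group comparison that typically follows, and a synthetic cohort
generator that stands in for the MRI-derived inputs.

## Structural probabilities

The unit of structural evidence is the voxel-level streamline count: for
an ordered pair (i, j), a vector with one entry per voxel of the target
ROI j. The pair's probability is

$$p_{i \to j} = \frac{Q_{90}(\text{voxel counts for } i \to j)}{\text{streamlines leaving } i},$$

clipped to [0, 1]. Two conventions are deliberately explicit:

* **Quantile type.** "90th percentile" is computed with linear
  interpolation between order statistics (`stats::quantile` type 7), the
  most common default; the `type` argument exposes the choice because no
  convention is canonical for count vectors. On the fixture `0:9` the
  type-7 value is 8.1, giving `0.081` over a denominator of 100.
* **Direction.** The rule is asymmetric (the denominator is the *source*
  ROI's outflow) while the analysis is of unordered pairs, so the two
  directions are averaged (`symmetrize_sc(..., "mean")`); a max option
  exists for users who prefer "best evidence either way". The diagonal is
  fixed at 1 and never tested.

A source ROI with zero outflow yields probability 0 with a warning rather
than an error: it is a legitimate (if suspicious) tractography outcome.

## Distance de-biasing with a zero-inflated Poisson model

Streamline counts decay with inter-ROI distance for reasons that are
algorithmic as much as biological. Pair totals are modelled as

$$P(S=0) = \omega + (1-\omega)e^{-\mu}, \qquad
  P(S=k>0) = (1-\omega)\frac{e^{-\mu}\mu^k}{k!}, \qquad
  \log\mu = \alpha_0 + \alpha_1 g,$$

with g the pair distance in mm. The likelihood is maximized by bounded
quasi-Newton (L-BFGS-B) on $(\alpha_0, \alpha_1, \operatorname{logit}\omega)$
from method-of-moments starts (log-linear fit on positive counts; ω from
the excess-zero fraction). Two numerical choices matter:

* $\operatorname{logit}\omega$ is boxed to $[\operatorname{logit}(10^{-4}),
  \operatorname{logit}(1-10^{-4})]$. When the true MLE sits at ω = 0 (no
  excess zeros) an unbounded optimizer walks the logit toward −∞ forever;
  the box makes that boundary case terminate cleanly, at a likelihood cost
  below $10^{-3}$ log-units at the scales involved.
* The optimizer is restarted from its own solution until the likelihood
  improves by less than $10^{-8}$; `converged` reports that flatness. A
  non-converged fit is returned (best iterate) rather than raised;
  `distance_adjust` then refuses to use it unless `force = TRUE`.

The fit is per subject by default (the pipeline makes no pooling
assumption); `zip_pooled = TRUE` fits once across all kept subjects'
pairs, which roughly quadruples the effective n under the default world
and is what the cohort-level recovery test exercises.

**How the fit enters.** The adjustment

$$\pi_{\text{adj}} = \min\!\left(1,\; \pi \cdot e^{-\hat\alpha_1 (g - g_{\text{med}})}\right)$$

divides out the fitted exponential trend while anchoring the scale at the
cohort-median distance, so a fit with $\hat\alpha_1 = 0$ is exactly the
identity and, for the usual $\hat\alpha_1 < 0$, longer pairs are boosted
and shorter pairs shrunk. Anchoring at the median rather than at g = 0
keeps the rescale factors near 1 and the clipped-at-1 set small. This
functional form is this package's construction: the source method states
*that* a ZIP regression adjusts the distance bias but not *how* the fitted
mean enters.

## Second-order connections

Indirect structural routes through one intermediate region are admitted
by a single max-product pass,

$$\pi_{ij} \leftarrow \max\left[\pi_{ij},\; \max_{m \notin \{i,j\}} \pi_{im}\pi_{mj}\right],$$

computed entirely from the input matrix: the pass is deliberately **not**
iterated, so three-hop chains do not compose (applying the operator twice
would extend reach further — it is monotone but not idempotent — and the
pipeline applies it exactly once, after distance adjustment, matching the
stated stage order probabilities → regression → second order). The
implementation zeroes the diagonal before the pass, which excludes
$m \in \{i, j\}$ without branching, and is verified bitwise against a
literal triple loop.

## Fusion

$$\text{awFd} = (1 - \pi)(1 - \text{FC}) \in [0, 2], \qquad
  \text{awFC} = 1 - |\text{awFd}| \in [-1, 1].$$

Useful identities, all tested exactly: π = 1 forces awFC = 1 regardless of
FC; π = 0 with FC ≥ 0 returns FC unchanged (the metric degrades gracefully
to plain FC when structure offers no evidence); awFC is strictly
increasing in each argument on the relevant ranges. Negative FC passes
through verbatim — awFd can then exceed 1 and awFC go negative — because
the defining equations place no restriction; `truncate_fc = TRUE` floors
FC at 0 first for users who consider anticorrelations artefactual. No
Fisher-z transform is applied before testing: the group test is rank-based,
so any monotone transform leaves its p-values unchanged.

## Group statistics

Per pair and per metric the two groups are compared with a two-sided
Wilcoxon rank-sum test: exact by enumeration when both groups have ≤ 25
observations and the pooled sample is tie-free, otherwise the normal
approximation with tie and continuity corrections (ties force the
approximate path, mirroring standard package behaviour). With 9 vs 8
subjects the smallest attainable two-sided p is $2/\binom{17}{8} \approx
8.2\times10^{-5}$ — worth remembering when reading adjusted values. If
every observation in both samples is one shared constant the statistic has
zero variance and sits exactly at its mean; the p-value is defined as 1.

FDR adjustment is Benjamini–Hochberg, applied per metric across all tested
pairs (28 under the default atlas). Pooling across networks is the
conservative reading of "corrected for multiple comparisons" when one
table mixes networks; `fdr_scope = "per-network"` is available. Only
within-network pairs are tested by default because the method segments
ROIs by network; cross-network testing is off by default.

Cohen's d uses the pooled SD without small-sample correction, computed on
awFC, with sign = control − adversity (so a deficit in the adversity group
is positive d, and an adversity *increase* is negative). Size labels on
|d|: < 0.2 negligible, < 0.5 small, < 0.8 medium (synonym of "moderate"),
≥ 0.8 large.

## The synthetic world

The generator's defaults are the stated study conditions, fixed once and
not tuned:

| parameter | default | rationale |
|---|---|---|
| atlas | 19 ROIs / 5 networks | the published ROI table, coordinates and voxel volumes as printed |
| group sizes | 9 control, 8 adversity | the study's final sample |
| `t_volumes` | 105 | 108 acquired minus 3 discarded dummy volumes |
| `rho_within` / `rho_between` | 0.6 / 0.1 | strong within-network, weak between-network coupling typical of RSN block structure |
| ZIP (α₀, α₁, ω) | 2.0, −0.02 /mm, 0.25 | counts of a few to ~10 streamlines at 20–170 mm with a quarter of pairs dropped — small-cohort paediatric tractography scale |
| `lost_rate` | 20 | streamlines leaving an ROI that reach no target, so outflow exceeds the row sum as in real tracking |
| displacement | U(0.05, 0.50) mm | below the 0.55 mm exclusion threshold unless a QC failure is planted via `qc_fail_ids` |

FC is simulated as ROI time series (multivariate normal with the block
correlation structure, group effects added to the generating covariance
before an eigenvalue-floor PSD repair) and then *sampled* as a Pearson
matrix over `t_volumes` frames — so FC noise scales with scan length, the
feature that makes 17-subject inference hard. Streamline counts come from
the same ZIP form the fitter assumes, spread over target-ROI voxels by a
uniform multinomial; distances are Euclidean between MNI peaks, a proxy
for tract length that exercises the distance-bias machinery without
claiming anatomical realism. Questionnaire scores are drawn consistent
with each subject's group so the composite adversity rule reproduces the
labels from the manifest alone.

What a green test does **not** establish: realism of head-motion,
physiological noise, ICA decomposition quality, voxel-level count
clustering (real counts are not uniform-multinomial), or tract-length vs
Euclidean-distance discrepancies. The generator validates the pipeline's
statistics, not the upstream imaging.

## Degenerate inputs and tie-breaks

* All-zero pair totals: `fit_zip` errors (no information); all-zero voxel
  counts for one pair: probability 0, no error.
* Zero pooled variance in Cohen's d: error ("degenerate samples"); inside
  `build_results_table` this is caught and reported as d = 0 (it occurs
  only when both groups are constant and identical, where 0 is the honest
  value).
* QC threshold is a strict inequality: exactly 0.55 mm is kept.
* Missing questionnaire scores are sub-threshold, not errors
  (`strict = TRUE` reverses this): real manifests are partial, and a
  missing score cannot demonstrate adversity.
* Labels are matched case-sensitively; any FC/tractography label mismatch
  is an error, never a silent reindex.

## Known limitations

* Only one distance-adjustment form (median-distance rescale) is
  implemented besides `none`; residual-based alternatives would need their
  own validation.
* Second-order incorporation stops at one intermediate; no multi-hop
  closure.
* No covariate adjustment (age, sex, site) in the group comparison.
* The CLI reads flags only; there is no YAML/JSON config-file layer.
* The exact Wilcoxon path requires tie-free data; heavily discretized
  metrics silently use the approximate path (as mainstream tools do).
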