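---
title: "Models and methods behind memsem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind memsem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

memsem analyzes delayed-recognition memory experiments in which each studied
picture is probed at test together with a semantically related, a
perceptually related and an unrelated lure, after either a short (1 day) or
long (28 days) retention interval. This vignette documents the models the
package implements, the choices that were genuinely open, and what the
synthetic-data generator does and does not establish.

## 1. Behavioral scoring

An item counts as endorsed 'old' when the response is 'rather old' or
'definitely old'; the primary hit/false-alarm analyses are binary, with
confidence entering only through the separate ×1/×2 weighting analysis.
Rates are percentages of valid (non-missing) trials per cell. Whether the
original analyses divided by the per-cell valid count or by the fixed set
count is not determinable from the published description; the per-cell
valid-count convention is used, which is the conservative choice when
missingness is rare (the emulated rate is under 1%).

Memory specificity is classified per stimulus set from the responses to its
old item and two related lures:

| old | semantic lure | perceptual lure | label |
|-----|---------------|-----------------|-------|
| old | new | new | detailed |
| any | old | new | semantically_transformed |
| any | new | old | perceptually_transformed |
| new | new | new | forgotten |
| —  | old | old | uncategorized |

Sets with any missing response are labelled `missing`. The four named
categories do not cover the both-lures-endorsed combination; it is reported
as `uncategorized` rather than silently dropped so that counts always sum to
the number of sets. The six labels are mutually exclusive and exhaustive —
this partition is enforced by an enumeration test over all response
combinations.

For trial-wise mixed models, relatedness ratings are centered *within
subject* (group-mean centering). Cross-level interaction estimates (e.g.
delay × relatedness) are biased when level-1 covariates carry between-
subject variance, which group-mean centering removes. The dichotomized
perceptual-relatedness factor splits at ≤ 5 vs. > 5 on the 0–10 scale.

## 2. Model-based RSA

Per subject and emotion category, all test-phase activation patterns are
correlated pairwise (Pearson's *r*), giving a 120 × 120 RSM at study scale,
ordered by item type then stimulus set; the diagonal is excluded throughout.

**Run-proximity bias.** Trials scanned close together in time correlate
spuriously. For each unordered run combination (three within-run, three
between-run at study scale) the mean similarity over that combination's
off-diagonal cells is subtracted from each of its cells. After correction
every combination's mean is exactly zero, and the operation is idempotent.
Note what this correction does *not* do: it equalizes means, not scale. If
some trial categories have systematically larger pattern variance, a shared
run-level component contributes equal covariance but smaller *correlation*
for the high-variance categories, and mean subtraction then leaves those
categories slightly below zero. This residual structure is real and is
documented because it matters for interpreting model fits (see §5).

**Conceptual models.** Three binary hypotheses: (1) old items form a
distinct cluster; (2) old + semantic lures form a cluster; (3) old +
perceptual lures form a cluster. The published description specifies which
*categories* are similar but not the lure–lure cells within a cluster; the
standard categorical convention — the full block, including lure–lure
cells — is adopted and is configurable (`lure_lure = FALSE` restricts
similarity to old–lure cells). Model fit is Spearman's rank correlation over
the lower-triangle cells (average ranks for ties), Fisher z-transformed.
Whether the original analysis used one triangle or all off-diagonal cells is
not stated; for symmetric matrices the two differ only through tie
structure, and the triangle avoids double counting.

## 3. Encoding–retrieval similarity

ERS for an old item is `atanh(r)` between its test pattern and its encoding
pattern. "The" encoding pattern is ambiguous when every item was encoded
three times; the default averages the three run patterns voxel-wise
(`mean_encoding`), with per-run variants available — the original report
found no difference among these variants, and the package treats the choice
as a parameter rather than a commitment. Gist reinstatement correlates a
*lure's* test pattern with the corresponding old item's encoding pattern.
r = ±1 yields non-finite z; such records are flagged invalid and excluded
with a warning — in practice this occurs only in noise-free synthetic data.

## 4. Inference

**Split-plot ANOVA.** Implemented via orthonormal contrast transforms of
the subject × cell matrix: for each within-subject effect, the data are
projected onto the effect's contrast space; hypothesis and error sums of
squares come from the transformed variables, which reproduces the classical
univariate repeated-measures F exactly (cross-checked against
`stats::aov` error strata to 1e-6). Greenhouse–Geisser epsilon and
Mauchly's test use the covariance of the transformed variables pooled
*within* groups — the car/SPSS convention for split-plot designs (some
implementations pool across groups; on purely within-subject designs the
conventions coincide, and the package matches an independent reference
implementation to six decimals there). The reported `p` column follows the
usual convention: GG-corrected when Mauchly's test rejects at .05.

Partial η² = SS_effect / (SS_effect + SS_error), with a confidence interval
from inverting the noncentral-F CDF (the published report does not name its
CI procedure; noncentral-F inversion is the standard choice and the interval
is clamped at a lower bound of 0 when the observed F is consistent with a
zero effect).

**Contrasts.** Šidák adjustment `1 − (1 − p)^m` over the declared family.
Interaction contrasts are contrasts between contrasts: the between-group
difference of a within-subject cell difference, tested with a pooled-
variance two-sample t on per-subject differences. Cohen's d is the paired
mean over the paired SD, or the group difference over the pooled SD.

**Mixed models.** Gaussian LMMs are fitted with REML (lme4's default
nloptwrap optimizer), binomial-logit GLMMs with ML and bobyqa, matching the
original fitting conventions up to optimizer naming. Binomial fixed effects
are tested with Wald z, as in the original analyses. For gaussian LMMs the
original post-hoc machinery used Satterthwaite degrees of freedom; no
Satterthwaite implementation is available in this dependency set, so t
statistics are reported against a residual-df approximation (n − p). With
the cluster counts these designs produce (thousands of trials, ≥ 50
clusters) the t is effectively a z and the approximation is inconsequential
for the package's uses; it is still an approximation and is labelled as
such. Boundary (singular) fits — legitimate when a variance component is
truly zero — are flagged `singular` but not treated as convergence
failures; genuine non-convergence is always flagged, never silent.

**Outliers.** The ±3 SD rule: a value is excluded when it lies more than
3 SDs from the mean of its condition, mean and SD computed on all values of
that condition. The rule is deliberately literal — with n = 5 values
{0, 0, 0, 0, 100}, the 100 is *not* excluded (it sits at 1.79 SD), which a
test documents.

## 5. The synthetic world

Every generated pattern is a weighted sum of independent unit-variance voxel
vectors:

- `w_item · u_item` — item-specific signal (every picture its own vector);
- `w_semantic · u_sem(set)` — shared between an old item and *its* semantic
  lure (the semantic gist is set-level: different sets have different
  gists);
- `w_perceptual · u_perc(set)` — likewise for the perceptual lure;
- `w_old_common · u_old` — shared by all old items at test (a recognition
  signal);
- `run_offset_sd · o(run)` — an additive common vector per run, exactly the
  artifact the bias correction targets;
- i.i.d. Gaussian noise, `sd_noise` per voxel.

The encoding pattern of an item carries its item + gist components scaled by
`w_reinstate`, which is what ERS detects. Responses are drawn independently
per trial from delay × emotion × item-type endorsement probabilities;
ratings are truncated-normal integers on the 0–10 scale.

**Defaults are the stated world.** Design: 26 subjects/group, 30 sets per
emotion, 3 + 3 runs. Endorsement defaults reproduce the published
group-level pattern — hits ~92% at 1d; 70% (neutral) / 81% (negative) at
28d; false-alarm probabilities chosen so the 28d false-alarm mix is ~56/24/20
percent semantic/perceptual/unrelated, close to the published 53/23/24 —
and missingness 0.95%. Rating means are the published group means per lure
type × dimension (9.20/2.30/1.72 on the semantic dimension, 5.50/6.09/1.74
on the perceptual). The confidence split (0.5) is illustrative: the
confidence-level composition of responses is not recoverable from the
published summaries. Pattern weights default to 1 (item), 0.5 (gist,
old-common, reinstatement, run offsets) against unit noise — moderate
signal-to-noise chosen once as representative of single-trial estimates.

**The model-recovery experiment** (acceptance test) asks whether elevated
semantic-gist coupling in the 28d group is recovered as model-2 dominance.
Two mechanical facts, derived before fixing the experiment's parameters,
shape its stated world. First, Spearman fitting is rank-based: the 30
same-set old–semantic cells are extreme but *saturate* — a cell 5 SDs above
baseline contributes no more rank mass than one at 2 SDs — so a dilute
block of 1770 cells with 30 extreme members cannot outrank a model-1 block
that is uniformly (even weakly) elevated. Any appreciable `w_old_common`
therefore hands model 1 the win regardless of `w_semantic`. Second, the
variance-scaling residual of the run-bias correction (§2) depresses
precisely the old + semantic block when run offsets are present. The
semantization world of that experiment is accordingly: distinct-old signal
decayed (`w_old_common = 0` — the account the delayed group's data support),
no run-common component in the post-GLM patterns (`run_offset_sd = 0`; the
correction is exercised separately with planted offsets),
`w_semantic` 1.0 (28d) vs. 0.25 (1d), `w_perceptual = 0.25` in both groups.
The converse world (only `w_old_common > 0`) must and does yield model-1
dominance.

**What a green test does not establish.** The generator draws responses
independently per trial (no sequential dependencies, no drift), uses
homogeneous voxel noise (no spatial autocorrelation, no physiological
artifacts), set-level gist vectors (no semantic similarity *between* sets),
and Gaussian signals. Passing tests establish that the estimators recover
the structure they target under this world — not that the world is a
faithful model of BOLD data. Properties that depend on realistic noise
spectra (e.g. the size of the run-proximity bias in real data) are outside
what the suite can show.

## 6. Numerical and degenerate-input policy

- Zero-variance pattern vectors make their correlations undefined: flagged
  and excluded, never silently imputed.
- A run combination with no off-diagonal pairs is skipped with a warning.
- Constant model or neural RSM values abort the Spearman fit with an error
  (a fit of a constant is meaningless, not zero).
- Constant dv in the ANOVA yields F = NaN with a warning (zero error
  variance), not an error.
- `atanh` is applied to correlations strictly inside (−1, 1); ±1 produces
  non-finite z and the record is flagged.
- All generators are deterministic given their seed; the pipeline stamps
  every run with seed and config hash, and a same-seed rerun is
  byte-identical on all numeric outputs.

## 7. Known limitations

- One between-subjects factor in `mixed_anova` (the designs in scope need no
  more); balanced designs only — unbalanced data error out rather than
  silently switching SS types.
- Satterthwaite df are unavailable (see §4); gaussian-LMM p-values use a
  residual-df approximation.
- The NIfTI reader/writer is deliberately minimal: single-file NIfTI-1,
  five datatypes, sform affine, no reorientation or extensions. It exists to
  extract masked voxel vectors, not to replace a neuroimaging I/O library.
- The hippocampal long-axis analyses take ROI masks as supplied inputs; no
  atlas is bundled.
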