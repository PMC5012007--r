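---
title: "Finding signaling alterations shared between drug-adaptation states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding signaling alterations shared between drug-adaptation states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptomics)
```

## The analysis problem

Kinase-inhibitor-treated cancer cells adapt in stages. Short-term BRAF
inhibition of BRAF-mutant melanoma leaves behind a slow-cycling
*persistent* subpopulation; chronic exposure selects proliferative
*resistant* cells. Label-free mass-spectrometry profiles of the parental,
persistent and resistant states of several cell lines — together with
matched gene-expression profiles — pose an integration question: which
signaling alterations are *shared* between the early and the late
adaptation state, and are they specific to a resistance mechanism
(RTK-upregulation-driven, mesenchymal-shifted lines) as opposed to a
control mechanism (NRAS-mutant, MAPK-reactivating lines)?

`adaptomics` implements that integration as a chain of small, testable
statistics. This vignette documents the model behind each stage, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical decisions taken where the design was open.

## Differential statistics and the signed log-t score

Quantification tables hold log2 intensities with an explicit missing-value
mask; values are never imputed at I/O time — each operation states its own
policy. The only normalization applied is per-sample median centering
(`normalize_median_center()`), which is idempotent and leaves the mask
untouched. Columns with fewer than two present values cannot be centered
meaningfully and are an error.

Per-feature two-group testing (`feature_ttest()`) uses the pooled-variance
Student's *t* by default, matching the named test of the assay design;
Welch is available by flag. The fold change is reported as
`log2fc = mean(group_b) - mean(group_a)` (e.g. resistant minus parental)
while the `stat` column keeps the `t.test(a, b)` sign convention, so
`sign(stat) = -sign(log2fc)`. Features with fewer than two present
replicates in a group are flagged, never dropped: silent row loss is the
classic integration bug in sparse label-free data. Zero pooled variance
with unequal means — which genuinely occurs with saturated or censored
intensities — receives the machine-minimum p sentinel `1e-300` and a
`zero_variance` flag rather than `p = 0`, keeping downstream log-scores
finite.

The *signed log-t score* is

$$s = \mathrm{sign}(\Delta)\,(-\log_{10} p),$$

with $\Delta$ the log2 fold change. Whether the "log" in a signed log-t
statistic should log the p-value or the t statistic is a genuinely open
convention; the p-value variant is the default because it is
monotone-equivalent within a contrast but additive across contrasts with
different degrees of freedom, and the $\mathrm{sign}(\Delta)\log_{10}|t|$
variant stays available via `score_variant = "log_t"`. Scores are capped at
±300 (the sentinel's log) so sums stay finite.

One-way ANOVA (`feature_anova()`) reports the F statistic with raw p and
all pairwise group-mean differences; the filter presets mirror how the two
assays are thresholded: `"proteome_anova"` (raw p < 0.05 with a 3-fold
average change), `"phospho_ttest"` (BH q < 0.2 with a 2-fold change) and
`"ecm_ttest"` (q < 0.1). The ANOVA preset deliberately filters on raw p and
the t-test presets on BH q — the two assays were filtered differently and
both rules are kept verbatim as named presets. "3-fold" is implemented as
the linear fold of group means (the per-replicate-average alternative is a
documented open choice; group means are the variance-minimizing reading).

## The combined perturbation score

The headline statistic ranks shared alterations. Per phospho-site,

$$S = \sum_{c \in \text{contrasts}} s_c,$$

summing over the persistent/parental and resistant/parental pairs of the
case lines, then collapsing to one site per protein by largest $|S|$
(sign preserved). Ties prefer the positive score, then the
lexicographically smallest site label, and are recorded — determinism is a
hard requirement for a ranking that names follow-up candidates.

Sites absent from some runs are the rule, not the exception, in
label-free data (the motivating study's top shared candidate was at first
detected only in the resistant runs). The default `allow_missing` policy
sums over present contrasts, flags the site, and breaks score ties in
favor of better coverage, so a partially observed site can never outrank a
fully observed site with the same per-contrast scores. `require_all`
restricts to the intersection. Shared-up and shared-down candidates are
reported as two rank columns rather than one absolute-value list because
candidate targets are directional.

## Concordance, enrichment, RRHO, signature similarity

**Direction concordance.** Two contrasts are compared by cross-tabulating
the sign of the fold change among sites significant in *either* contrast
(policy and threshold configurable; the default threshold is the phospho
profiles' own FDR, q < 0.2) and applying Fisher's exact test with the
minimum-likelihood two-sided convention. Zero-fold sites carry no
direction and are excluded with a count.

**Permutation KS test.** Signature enrichment at the top of a ranked list
uses the one-sided statistic
$D = \max_i \left( \hat F_{\text{sig}}(i) - i/N \right)$ and gene-label
permutation: `B` draws of member positions without replacement, with the
add-one estimator $p = (\#\{D^* \ge D\} + 1)/(B+1)$, which can never
return zero and is conservative at the resolution $1/(B+1)$. One-sided and
unweighted is the default (the named rank test of the study's methods does
not specify a variant); the weighted two-sided running sum is the separate
`gsea_es_nes()`.

**GSEA ES/NES.** The running sum increments by $|r_j|^w / N_R$ on hits and
decrements by $1/(N-m)$ on misses; ES is the extremum. `weight = 0`
reduces to the classic KS walk (the maximal positive excursion equals
$D \cdot N/(N-m)$, a relation the test suite checks against the KS
implementation, and the weighted statistic is cross-checked against an
independent implementation). NES normalizes by the mean |ES*| of same-sign
permutations — the standard convention; p-values are same-sign add-one
estimates and q is BH across sets. Sets smaller than `min_size = 3` are
skipped with a record. Permuting gene labels rather than sample labels is
a deliberate choice: the comparison use case ranks a *fixed* signature
ordering where replicate-level resampling is not available.

**Directional calls.** Kinase-substrate enrichment
(`kinase_enrichment()`) ranks phospho-features by mean fold change and
calls a kinase significant at q < 0.2 *with positive NES* by default. The
one-sided call matters: when strong planted (or real) programs occupy the
top of a ranking, gene-label permutation produces spurious *depletion*
(negative-NES) calls for unrelated sets, because a random null set is
"depleted" relative to a top that is packed with signal. An analysis
looking for upregulated kinase activities should not report those;
`direction = "both"` restores the two-sided behavior.

**Specificity filter.** A program counts as mechanism-specific when
enriched in *every* case line (q < 0.1) and not in the control line
(q > 0.2); survivors are ordered by summed case NES. Sets missing from any
collection are excluded with a record.

**RRHO.** For rank thresholds $(i, j)$ the overlap of the two top lists is
scored by the hypergeometric tail $P(X \ge k)$, $X \sim \mathrm{Hyp}(N, i,
j)$, computed in log space (`stats::phyper(log.p = TRUE)`) so that deep
corners of the map do not underflow; the map reports $-\log_{10} p$.
Defaults follow the method's common practice where the study left them
unstated: one-sided over-enrichment (a signed variant marks depletion
cells negative via the lower tail), step size $\max(1, \lfloor N/100
\rfloor)$, universe = intersection of the two lists with discarded
identifiers logged (the compared platforms rarely share their full
universe), optional BH/BY correction across cells.

**Signature similarity.** Pairwise Pearson correlation over
pairwise-complete identifiers (platforms differ; the per-pair n is
recorded, with a configurable minimum overlap — 3 for tests, of order 100
for genome-scale use). Clustering is agglomerative on distance $1 - r$,
*not* $1 - |r|$: negative-control signatures are expected to
anti-correlate, and that information must separate, not attract, them.
Average linkage is the default; a constant signature yields an undefined
correlation which is flagged `NA`, never coerced to zero.

## The synthetic-data generator

`simulate_experiment()` draws the study design the analysis assumes: cell
lines labelled with a resistance mechanism (two RTK-like case lines, one
NRAS-like control line), each in parental/persistent/resistant states with
n = 3 replicates (replicate counts of the motivating experiments are not
on record; 3 is the field's standard minimum for per-feature t-tests).
Log2 intensities are baseline N(20, 2) per feature plus the planted effect
plus N(0, 0.5) replicate noise — i.e. log-normal raw intensities, the
standard label-free noise model. Planted programs (disjoint, protein
level, defaults in log2 units):

| program | size | effect | applied to |
|---|---|---|---|
| `shared_up` | 20 | +2 | persistent *and* resistant, RTK-like lines |
| `persistent_down` | 30 | −2 | persistent state, all lines |
| `resistant_up` (mesenchymal-like) | 30 | +2 | resistant state, RTK-like lines |
| `control_up` (MAPK-reactivation-like) | 20 | +2 | resistant state, NRAS-like line |

Mechanism gating encodes the biology being emulated: the shared and
mesenchymal programs are specific to the RTK-mechanism lines (shared-target
upregulation is BRAF-mutant-line behavior), growth-arrest downregulation
accompanies persistence everywhere, and the control line gets its own
program so the specificity filter has something to reject. Missingness is
intensity-dependent left censoring: an entry of true log2 intensity $x$ is
detected with probability $\mathrm{logit}^{-1}(\text{slope}\,(x -
\text{midpoint}))$ (defaults slope 1, midpoint 14 — mild at the default
baseline, so tests of detection behavior move the midpoint). This
reproduces the limited overlap of detected features between runs that
motivates the coverage policies. The generator also emits the planted
programs as gene sets plus size-matched decoy sets drawn from unplanted
proteins, and `make_expression_twin()` produces the one-row-per-protein
expression counterpart with inherited effects, independent noise
(sd 0.3) and no missingness (array/RNA-seq-like completeness).

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: batch and run-order effects, correlated
noise between sites of one protein beyond the shared planted effect,
peptide-level summarization artifacts, non-Gaussian heavy tails, and any
identifier-mapping noise between platforms (identifier matching in the
package is exact and case-sensitive; normalization is an explicit separate
step). Effect sizes are homogeneous within a program, which makes planted
recovery cleaner than real biology.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at sizes chosen to
exercise the statistics honestly on one CPU: exhaustive Fisher enumeration
for all 2×2 tables with margins ≤ 12; RRHO against a naive
intersection-plus-tail-sum oracle at N ≤ 50 (log-space agreement to
1e-12); BH against a literal step-up oracle on 1000 random vectors; KS
type-I calibration from 1000 null simulations at B = 199; null-uniformity
checks at 5000 features; planted-recovery benchmarks with 20 shared
4-fold sites among 1000 at sd 0.5 over ten seeds; B = 10,000 for single
headline enrichment runs and B = 499 inside 100-fold repeated suites
(resolution 0.002 against a 0.2 threshold). The default pipeline runs the
full 1000-protein design.

Other fixed conventions: all randomness flows through explicit integer
seeds (simulation seed, enrichment seed) and a config hash is stamped into
the pipeline summary; ranked lists break score ties lexicographically by
identifier; permutation draws are positions without replacement;
`p = 1e-300` is the only p sentinel; RRHO cells are floored at the double
minimum before logging.

## Limitations

The package deliberately stops short of: raw spectra processing (inputs
are quantification tables), empirical-Bayes moderated tests (the in-scope
statistics are plain t/ANOVA; moderation would change the signed score's
meaning), meta-analytic p-value combination (the shared-target statistic
is a score sum, kept faithful), permutation significance for the RRHO map
maximum, and bootstrap confidence for the signature clustering. The
gene-label permutation scheme shares the known limitation discussed above
for depletion calls; sample-label permutation would require replicate-level
expression for every comparison input, which the comparison use case does
not have.
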