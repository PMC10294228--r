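---
title: "Resistance signatures and signature-reversal drug repositioning: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resistance signatures and signature-reversal drug repositioning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revsig)
```

# The problem

In neoadjuvant breast-cancer trials, pre-treatment tumor expression profiles
can be stratified by how the tumor eventually responded: residual cancer
burden (RCB) class 0 or I marks a drug-sensitive tumor, RCB III a resistant
one (RCB II, the ambiguous middle, is excluded; so are samples with no RCB
record). Within each (treatment, receptor-subtype) arm, the genes that
differ between resistant and sensitive tumors form a *resistance
signature*. If a compound in a drug-perturbation compendium (a
Connectivity-Map-style collection of genes-by-drugs differential-expression
rankings) *down*-regulates the signature's up-genes and *up*-regulates its
down-genes, that compound is a candidate chemosensitizer. `revsig`
implements this chain — normalization, stratification, moderated
differential expression, MCC-optimized signature thresholding, preranked
gene-set enrichment, and KS-based reversal scoring — and ships a synthetic
cohort/compendium generator so every stage can be validated against planted
ground truth without any external data.

# Normalization and stratification

Arrays are normalized per sample by centering the log2 intensities at the
sample's 75th percentile and adding a fixed 9.5 to keep values positive;
afterwards every sample's 75th percentile is exactly 9.5, and the operation
is idempotent. The percentile uses linear interpolation between order
statistics (`stats::quantile` type 7) — a stated convention so the defining
property is testable.

Arms are keyed by (treatment, HR/HER2 subtype). An arm is analyzed only if
both response groups have at least 3 samples; smaller arms are dropped with
a logged reason.

# Moderated differential expression

Per gene, with $n_s$ sensitive and $n_r$ resistant samples,
$\mathrm{log_2FC} = \bar x_r - \bar x_s$ and the pooled residual variance
$s^2$ has $d = n_s + n_r - 2$ degrees of freedom. Gene variances are
shrunk toward a common prior by empirical Bayes: assuming
$s^2 \sim s_0^2 \, F(d, d_0)$, the moments of $\log s^2$ give closed-form
estimates of $(d_0, s_0^2)$ via digamma/trigamma matching (the trigamma
inverse is a short Newton iteration). The posterior variance is
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ — in the limit
$d_0 = \infty$, simply $s_0^2$ — and the moderated statistic
$\tilde t = \mathrm{log_2FC} / (\tilde s \sqrt{1/n_s + 1/n_r})$ is
referenced to a t distribution on $d_0 + d$ degrees of freedom. A gene
that is constant everywhere gets $\tilde t = 0$, $p = 1$. An ordinary
pooled t is available (`method = "pooled"`) for cross-checks; the test
suite verifies the moderated statistics against an independent
implementation of the same model (limma) to near machine precision on a
heteroskedastic fixture.

# MCC-optimized signature thresholding

Candidate members must pass $p < 0.01$. The log2FC cutoff is then chosen
by iterating $c = 1.0, 0.9, \dots, 0.0$ (11 values): at each $c$, the
genes with $|\mathrm{log_2FC}| \ge c$ define a feature space (each gene
standardized to zero mean, unit variance across the arm's samples; genes
with zero variance are left at zero rather than divided by it); k-means
with $k = 2$, Euclidean distance and 25 seeded restarts clusters the
samples; the two clusters are mapped to sensitive/resistant by whichever
assignment gives the larger Matthews correlation coefficient

$$\mathrm{MCC} = \frac{tp\,tn - fp\,fn}
{\sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}},$$

with any zero factor in the denominator defining MCC = 0. The cutoff with
the highest MCC wins; ties resolve to the larger cutoff (the smaller,
stronger signature), which falls out naturally from iterating the grid
downward with a strict comparison. Cutoffs leaving fewer than 2 genes are
recorded as undefined and skipped. Signature members with log2FC exactly 0
are excluded — a signature gene needs a direction — and a signature is
retained for downstream scoring only if it has *more than* 50 members (a
51-gene signature is the smallest retained; the threshold is read
strictly).

Two open choices here were fixed as follows: the cutoff grid is applied to
$|\mathrm{log_2FC}|$, not signed values (both directions matter to a
reversal score), and k-means runs on standardized expression so
high-variance genes cannot dominate the Euclidean metric.

**A caution on interpreting the MCC.** The clustering is performed on
genes *selected for* separating the two labeled groups ($p < 0.01$), so
the achieved MCC is optimistically biased — under a global null with no
true signal, the handful of genes that pass the p-filter by chance still
separate the labels, and the selected-cutoff MCC is typically near 1. The
MCC should be read as a descriptive measure of how cleanly the chosen
gene set separates the samples, and as a relative criterion between
cutoffs, never as evidence that a signature generalizes. This is a
property of the published procedure that the package reproduces
deliberately; the test suite measures and documents it.

# Preranked gene-set enrichment

Each arm's full gene list, ranked by log2FC (descending, ties broken by
gene id), is scored against a gene-set collection with the classic
weighted Kolmogorov–Smirnov running sum: at member positions the sum rises
by $|r_j|^p / N_R$ (with $N_R$ the sum of $|r_j|^p$ over present members,
$p = 1$), elsewhere it falls by $1/(N - t)$; the enrichment score (ES) is
the extreme deviation from zero. If every gene is a member the sum never
falls and the score is taken at the first position. The null is built by
drawing `n_perm` random gene sets of the same size from the ranked
universe (only a preranked list exists at this stage, so sample-label
permutation is not available); NES = ES divided by the magnitude of the
mean same-sign null ES, and the permutation p-value is sign-stratified
with a $1/(1 + n_\text{perm})$ floor. FDR across sets is Benjamini–
Hochberg on these p-values — simpler and better defined than the original
GSEA FDR-curve procedure, and stated openly as a deviation. A fast
positions-only scorer (algebraically identical to the running sum; the
suite checks equality) makes the permutation loop linear in set size, and
null draws are shared across sets of equal size.

# Reversal scoring (RGES)

For one drug's complete ranking of $n$ genes (rank 1 = most up-regulated
by the drug; ties in the underlying statistic are broken by gene id so
rankings are reproducible), the signed KS tag-enrichment of a gene set at
ascending ranks $V_1 < \dots < V_t$ is

$$a = \max_j\left(\tfrac{j}{t} - \tfrac{V_j}{n}\right),\qquad
  b = \max_j\left(\tfrac{V_j}{n} - \tfrac{j-1}{t}\right),\qquad
  \mathrm{es} = \begin{cases} a & a > b\\ -b & \text{otherwise.}\end{cases}$$

The reverse gene expression score combines the up- and down-set scores:
$\mathrm{RGES} = \mathrm{ks}_{up} - \mathrm{ks}_{down}$ when the two have
opposite signs (or either is zero), and 0 otherwise — a coherent reversal
(or mimicry) requires the two sets displaced in opposite directions.
RGES $\in [-2, 2]$; strongly negative means reversal.

Significance is a one-sided (left-tail) permutation test: the null draws
`n_perm` random disjoint up/down sets of the signature's sizes against a
fixed reference ranking (equivalent in distribution to fixing the sets
and randomizing the ranking), shared across all drugs scored against the
same signature — so one 100,000-draw null serves the whole compendium.
$p = (1 + \#\{\mathrm{null} \le \mathrm{obs}\})/(1 + n_\text{perm})$,
never zero. BH correction runs across drugs, and a *hit* is a drug with
$q < 0.05$ and RGES $< 0$. Signature genes absent from the profile
universe are dropped with a reported count.

**A caution on the permutation p-values.** Because the same-sign rule
maps roughly half of random-drug scores to exactly 0, the null RGES
distribution has a large atom at zero and the one-sided p-values are
discrete there (about half of random drugs share one p-value near 0.7).
They are valid — conservative — for the left tail that the hit rule uses,
and the suite verifies false-positive control (no hits among random drugs
at the nominal 5% FDR), but they are *not* uniform on [0, 1] and should
not be treated as continuous test statistics.

# The synthetic study

`sim_config()` defaults define the validation conditions: 5,000 genes;
one arm of 10 sensitive + 10 resistant samples; background expression
$\mathcal N(9.5, 0.5^2)$ on the log2 scale; 100 planted signature genes
per arm, half shifted $+3$ and half $-3$ log2 units in resistant samples
only (additive on the log scale, matching the pipeline's log2FC
arithmetic); optional RCB II samples carry half the shift, emulating
their intermediate phenotype; 200 random drugs with i.i.d. standard-
normal stats, plus one reverser that pushes a `reverser_fidelity`
fraction of the planted up-genes far into its negative tail (and
down-genes positive) and one mimicker doing the opposite. Each generator
role draws from its own seeded stream, so adding drugs never changes the
cohort draw and everything is a pure function of the master seed.
`n_shared_signature_genes` lets multi-arm designs share part of the
planted signature, making cross-arm recurrence observable.

What the generator deliberately does *not* emulate: probe-level effects,
batch/platform structure, gene–gene correlation, heavy-tailed or
intensity-dependent noise, and realistic compendium curation. Passing
tests therefore demonstrate that the machinery recovers the signal it is
specified to recover under clean Gaussian conditions — they do not
certify performance on real cohort data, where correlated genes and
subtler effects will lower recall and MCC.

# Problem sizes and runtime choices

The test suite and the acceptance script run the full planted benchmark
at 5,000 genes, 202 drugs and 10,000 RGES permutations (seconds on one
core); GSEA uses 2,000 permutations; replicate-based calibration checks
use 20–50 replicates at 2,000–5,000 genes. `run_pipeline()` defaults to
100,000 RGES permutations — the compendium-scale setting — which the
shared null keeps affordable; end-to-end determinism is verified byte for
byte on the written outputs (no timestamps appear in any output).

# Known limitations

* The MCC cutoff criterion is circular (see above): its absolute value is
  not a validation statistic.
* The permutation p-values for RGES are discrete with an atom induced by
  the same-sign-zero rule; only their left tail is decision-relevant.
* The NES normalization uses the mean of same-sign null scores; with very
  few same-sign draws (tiny `n_perm`) it is unstable, hence the
  `n_perm >= 100` floor.
* The pipeline assumes a gene-level expression matrix; probe collapsing,
  batch correction and compendium quality filtering are upstream concerns
  out of scope here.
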