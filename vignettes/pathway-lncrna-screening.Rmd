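---
title: "Screening pathway-associated lncRNAs: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening pathway-associated lncRNAs: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncTES)
```

## The problem

Bulk tumour expression cohorts mix malignant and non-malignant cells. Because
tumour purity shifts the measured expression of thousands of genes at once,
raw lncRNA–mRNA correlations are systematically inflated, and a naive
co-expression screen attributes purity structure to biology. `lncTES`
implements a purity-aware screen for lncRNAs associated with the activity of
a chosen gene set (for instance an MSigDB hallmark pathway in a liver-cancer
cohort), then carries the candidates forward into molecular subtyping and a
survival risk score.

## The screening statistic

For lncRNA $i$, mRNA $j$, and per-sample purity $p$, with pairwise Pearson
correlations $R_{lm}$, $R_{lp}$, $R_{mp}$, the first-order partial
correlation is

$$\mathrm{PCC}_{ij} = \frac{R_{lm} - R_{lp} R_{mp}}
  {\sqrt{1 - R_{lp}^2}\,\sqrt{1 - R_{mp}^2}},$$

which equals, as an algebraic identity, the correlation of the residuals of
each vector after regression on purity; the test suite verifies that
identity to $10^{-10}$ on random inputs. Its two-sided normal-approximation
p-value is

$$P_{ij} = 2\,\Phi\!\left(-\left|\mathrm{PCC}_{ij}
  \sqrt{\tfrac{n-3}{1-\mathrm{PCC}_{ij}^2}}\right|\right),$$

and each mRNA receives the signed rank index

$$\mathrm{RI}_{ij} = -\ln(P_{ij})\cdot\operatorname{sign}(\mathrm{PCC}_{ij}).$$

A note on this form: composing the logarithm directly with the signed
p-value is undefined for negative associations, so the package applies the
sign outside the logarithm — the only reading under which "descending RI"
places strong positive associations first and strong negative ones last.
When $P$ underflows to zero, $|\mathrm{RI}|$ is capped (default 745, about
$-\ln$ of the smallest representable double).

mRNAs are sorted by descending RI and the target set is tested with a
weighted Kolmogorov–Smirnov running sum (`preranked_es()`): hits increment
by $|\mathrm{RI}|^{w}$ (default $w = 1$, the preranked-GSEA convention),
misses decrement uniformly, and the enrichment score ES is the most extreme
running-sum deviation, always in $[-1, 1]$. Significance comes from a
gene-label permutation null of equal-size random sets:

$$p = \frac{1 + \#\{|ES_{\text{null}}| \ge |ES_{\text{obs}}|\}}{n_{\text{perm}} + 1},$$

never zero and floored at $1/(n_{\text{perm}}+1)$. The comparison is on the
magnitude only; direction is carried by $\operatorname{sign}(ES)$. A
sign-conditioned count was considered and rejected because it is not
uniformly distributed under the null (its mean is about 1/4), which would
distort the FDR step that follows. Gene-label permutation is used because a
ranked-list screen has no per-lncRNA phenotype to permute; its known caveat
is discussed under the generator below.

Raw permutation p-values are Benjamini–Hochberg adjusted across all lncRNAs
of one screen invocation (one family per cohort), giving $P_i$, and the
total enrichment score combines direction and adjusted significance:

$$\mathrm{TES}_i = (1 - 2P_i)\cdot\operatorname{sign}(ES_i) \in [-1, 1].$$

Candidates satisfy $|\mathrm{TES}| > 0.95$ and $P_i < 0.05$ (both
configurable; note the TES gate is the binding one, equivalent to
$P_i < 0.025$). Multi-cohort use intersects candidate identifiers across
per-cohort screens.

## Companion stages

**ssGSEA.** Per-sample pathway activity uses the weighted-ECDF difference
statistic: within a sample, genes are ranked (average ranks on ties, highest
expression largest rank), and the score sums the difference between the
in-set cumulative distribution weighted by $\mathrm{rank}^\tau$ and the
unweighted out-of-set cumulative distribution. $\tau = 0.25$ by default;
$\tau$ and optional cohort-level min–max normalization are exposed because
neither affects rank-based downstream use but both change the score scale.
Scores depend only on within-sample ranks.

**Pathway survival screen.** Each pathway score row is fitted in a
univariate Cox model (Breslow tie handling), reported as
$\log_2 \mathrm{HR}$ — positive values mark risk factors, negative values
protective factors — with a Wald p-value against `cox_alpha` (default 0.05;
the threshold is a package default, exposed because reasonable cohorts may
prefer stricter control).

**Consensus subtyping.** Candidate-lncRNA expression (standardized by
default) is repeatedly subsampled at 80% without replacement — subsampling,
not bootstrap resampling, so no sample is duplicated within a draw — and
clustered by k-means (Hartigan–Wong, `nstart = 10` random restarts per
resample; restarts guard against bad local optima at a per-resample cost
that stays within the budget of thousands of resamples). Co-clustering
counts are normalized by co-selection counts into a per-k consensus matrix.
The empirical CDF of consensus entries is summarized by its area $A_k$, and
the selected $k$ is the largest one whose relative gain
$(A_k - A_{k-1})/A_{k-1}$ exceeds `elbow_threshold`. The default threshold
is 0.15: splitting one *stable* cluster containing a fraction $f$ of the
samples converts about half of its pairs from consensus 1 to 0, a relative
gain of roughly $f^2/(2A)$ — up to about 0.14 for realistic cluster sizes —
so genuine additional structure must exceed what a contentless split can
produce. Final labels cut an average-linkage tree on $1 - $ consensus.
A `pam_chebyshev` backend (partitioning around medoids under the maximum
metric) is available behind the `method` flag for users who want a
non-Euclidean reading of the procedure; k-means is the default because a
"maximum-distance k-means" is not a defined algorithm.

**Risk model.** Cox coefficients for the candidate panel are fitted jointly
by default (`mode = "multivariate"`); per-lncRNA univariate fits are also
provided because the two conventions coexist in practice and give different
coefficients under correlated panels. The per-sample risk score is
$\sum_i \beta_i \mathrm{EXP}_i$; the cohort splits at the median score, with
scores exactly at the median assigned to the low-risk group (a deterministic
tie rule), and the high/low survival difference is tested by the log-rank
test — the standard companion of Kaplan–Meier estimation, and the reading
this package adopts for "the" survival-difference test. Applying a saved
model to a new cohort re-splits at that cohort's own median.

## The synthetic cohort generator

`generate_cohort()` draws, per sample: tumour purity from Beta(5, 2)
(high-purity tumour cohorts; configurable), a standard-normal latent
pathway activity $A$, and a subtype label. Genes have unit marginal
variance on a continuous log-like scale:

* pathway-set mRNAs: loading `pathway_coherence` on $A$ plus loading
  `purity_confounding` on standardized purity, Gaussian noise;
* background mRNAs: heterogeneous purity loadings drawn uniformly from
  $[-b, b]$ with $b$ = `purity_confounding`, plus noise;
* every lncRNA: the coherent purity loading $b$; *active* lncRNAs add a
  loading on $A$ chosen so their marginal correlation with $A$ is exactly
  `effect_r`.

Two of these choices deserve their rationale spelled out. First, the
heterogeneous background: if every gene loaded purity identically, purity
would inflate all correlations equally and an unadjusted screen would show
no *preferential* enrichment of the pathway set — the configuration would
not reproduce the failure mode purity adjustment exists to fix. A coherent
module loading against a heterogeneous background does. Second,
`pathway_coherence` defaults to 0.2 (mean intra-set correlation 0.04, the
loose end of real modules) rather than something larger: the mean rank-shift
a *null* lncRNA imposes on the whole set through its sampling correlation
with $A$ scales with the loading but not with $n$, while the resolution of
a gene-label permutation test is about $3/\sqrt{|S|}$ on the mean shift.
At loading 0.2 the coherent shift stays below that resolution and the
screen's false-candidate rate is controlled; at loading 0.5 and above the
permutation test is strongly anti-conservative. This is the well-known
inter-gene-correlation caveat of preranked GSEA, reproduced here by design
and documented so that users of the screen on real cohorts (where hallmark
sets can be tighter) treat borderline TES values with caution.

Subtype centroids in active-lncRNA space form a randomly oriented regular
simplex — all subtype pairs equally separated, so no pair is accidentally
coincident — scaled so the mean per-coordinate centroid difference equals
`subtype_shift` (default 0: labels are drawn but unseparated until a
shift is requested; the generator's calibration guarantee that active
lncRNAs correlate with $A$ at exactly `effect_r` would otherwise be diluted
by between-subtype variance).

Survival times follow an exponential proportional-hazards law with baseline
rate 0.1 per time unit and log-hazard `hazard_beta` $\times\, A$ — the
simplest law satisfying the Cox model the downstream screen assumes.
Censoring is uniform on $[0, c_{\max}]$ with $c_{\max}$ solved numerically
(conditional on the drawn activities) so the expected censored fraction
equals `censor_rate`.

What the generator does *not* emulate: RNA-seq count noise, library-size or
batch effects, gene-length bias, correlated lncRNA–lncRNA structure beyond
purity, and non-proportional hazards. Passing tests therefore demonstrate
the statistical machinery under its stated assumptions, not robustness to
real-data artefacts.

## Numerical and reproducibility choices

* Ties in ssGSEA ranking: average ranks; ties in RI orderings keep input
  order (stable sort), making ranked lists deterministic.
* All-pairs associations are computed as standardized matrix products
  (cost linear in samples × lncRNAs × mRNAs), not per-pair loops.
* Every stochastic function takes a `seed` and restores the caller's RNG
  state; `run_pipeline()` derives one stream per stage from a single master
  seed (`derive_seed()`, a fixed affine map modulo $2^{31}-1$), so reruns
  are byte-identical and individual stages are independently reproducible.
* Degenerate inputs fail loudly and early: constant vectors, purity
  collinear with expression, gene sets covering all genes, rank-deficient
  risk panels (collinear features are named), and p-value underflows are
  either errors or capped-and-warned, as documented per function.

## Problem sizes used for verification

The test suite and the acceptance script verify the pipeline on cohorts of
300 samples, 400 mRNAs (30 in the target set), and 60 lncRNAs (5 active) —
large enough for the asymptotics the screen relies on, small enough that
the full suite reruns in minutes; consensus clustering is verified with 500
resamples at 80% over $k = 2\ldots10$, and the calibration checks use
20–50 replicates per property. These sizes are the package's desk-scale
verification conditions; headline counts from full-size public cohorts
(hundreds of candidate lncRNAs from ~15,000 mRNAs) are not reproducible at
this scale and are not asserted.

## Known limitations

* The screen outputs association candidates, not regulatory targets; no
  causal claim is made or tested.
* Gene-label permutation is anti-conservative under strong intra-set
  correlation (see above); a competitive null is inherent to the
  ranked-list setting.
* Tumour purity is consumed as an input column; the package does not
  estimate purity from expression.
* The normal approximation for the partial-correlation p-value is the
  screen's defined transform; it is slightly anti-conservative at very
  small $n$ compared to the exact t reference, which only shifts RI scale,
  not ranking order.
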