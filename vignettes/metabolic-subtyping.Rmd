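---
title: "Metabolic pathway-based subtyping: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic pathway-based subtyping: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpsuite)
```

## The problem

Tumors of the same histology can run their metabolism very differently, and
those differences carry prognostic information. `mpsuite` implements a
transcriptome-based route to metabolic phenotyping: score each sample's
enrichment of a collection of metabolic pathway gene sets, cluster samples on
those scores into metabolic pathway-based subtypes (MPS), transfer the
subtype definitions to new cohorts with a supervised classifier, and relate
both the discrete subtypes and continuous pathway scores to survival
endpoints. Every stage is a plain function over flat files, so any stage can
be run, inspected, or replaced in isolation.

## Single-sample enrichment scoring

The scoring engine is a full reimplementation of the kernel-CDF random-walk
statistic (the GSVA family), not a wrapper around an external package.

**Kernel CDF.** For gene $i$ with expression $x_{i1},\dots,x_{in}$ across
samples, the empirical CDF is smoothed with a kernel and evaluated at each
sample's own value:

* Gaussian kernel (continuous, log-scale data):
  $\hat F_{ij} = \frac1n \sum_k \Phi\!\big((x_{ij}-x_{ik})/h_i\big)$ with
  bandwidth $h_i = s_i/4$, $s_i$ the per-gene sample SD.
* Poisson kernel (non-negative normalized counts):
  $\hat F_{ij} = \frac1n \sum_k F_{\mathrm{Pois}}\!\big(\lfloor x_{ij}\rfloor;\,
  \lambda = x_{ik} + 0.5\big)$. The floor makes the discrete CDF well-defined
  on non-integer normalized counts; the $0.5$ offset keeps the kernel proper
  at zero counts.

Two numerical conventions matter. A constant gene ($s_i = 0$) gets
$\hat F_{ij} = 0.5$ everywhere, which keeps it mid-ranked and uninformative
instead of producing a division by zero. And within each sample, genes are
ranked by decreasing $\hat F$ with ties broken by ascending gene index —
deterministic, with no hidden RNG state.

**Rank statistic and walk.** With ranks $1..p$ (rank 1 = most enriched), the
weight is $r_{ij} = |p/2 - \mathrm{rank}_{ij}|$, largest at both extremes of
the ranking. For gene set $\gamma$ of effective size $m$, the walk over a
sample's ranking increments by $r^\tau / \sum_{\gamma} r^\tau$ at in-set
genes and decrements by $1/(p-m)$ otherwise ($\tau = 1$ by default). The
enrichment score is read off the walk in one of two modes:

* `diff_extremes` (default, mirroring the reference implementation's
  default): maximum positive deviation plus minimum negative deviation;
* `max_deviation`: the walk value at its largest absolute deviation.

Both are bounded in $[-1, 1]$. A set whose total rank weight is zero (only
possible in degenerate tiny cases) scores 0 with a warning; a set covering
all measured genes is an error because the out-of-set decrement is undefined.

**Size filtering.** Sets are intersected with the measured genes first, then
kept only if the effective size lies in $[9, 300]$ — the bounds used for the
KEGG metabolic collection. `score_signature()` is the same machinery on a
one-set collection with bounds $(2, p-1)$.

The test suite pins the whole chain against an independent naive-loop oracle
at $10^{-12}$, so the vectorized implementation and the defining formulas
cannot drift apart.

## Subtype discovery and the consensus vote

Samples are clustered on the pathway-by-sample score matrix (transposed)
with `stats::kmeans`, 100 random starts and up to 100 iterations, seeded.
Scores are already commensurate in $[-1,1]$, so no additional
standardization is applied before clustering.

When `k` is not forced, each of ten cluster-validity indices votes for its
preferred $k$ over a grid (default $2..10$), and the modal $k$ wins, with
ties resolved toward the smallest tied $k$:

| index | rule |
|---|---|
| silhouette | maximize |
| Calinski–Harabasz | maximize |
| Davies–Bouldin | minimize |
| Dunn | maximize |
| Hartigan | smallest $k$ with $H(k) \le 10$, else argmin |
| Krzanowski–Lai | maximize |
| gap statistic | smallest $k$ with $\mathrm{Gap}(k) \ge \mathrm{Gap}(k+1) - s_{k+1}$ |
| point-biserial | maximize |
| McClain–Rao | minimize |
| SD index | minimize |

This is a curated core of the larger published index zoo: these ten have
unambiguous textbook formulations, and the majority-vote contract does not
depend on carrying every published index. The gap statistic uses 20 seeded
uniform reference draws over the per-feature ranges. Indices whose
definition needs a neighbouring partition (Hartigan, Krzanowski–Lai) abstain
at grid boundaries; an index undefined across the whole grid abstains from
the vote. The Hartigan rule above is the classic threshold-10 heuristic; any
fixed deterministic rule would preserve the voting contract, and this one is
stated so results are reproducible.

**Deterministic subtype names.** k-means labels are arbitrary, so cluster
identities are mapped to stable names: the cluster with the highest centroid
of the *anchor* pathway (by convention the chondroitin/dermatan-sulfate
glycan pathway, the hallmark of the high-risk subtype) becomes MPS1, and
remaining clusters are ordered by decreasing overall centroid mean. Without
an anchor, all clusters are ordered by overall centroid mean. This
convention is this package's resolution of the label-permutation problem;
the underlying partition does not depend on it.

## Cross-cohort transfer

`nsc_train()`/`nsc_cv()`/`nsc_predict()` implement nearest shrunken
centroids from its defining formulas: standardized centroid deviations
$d_{ik} = (\bar x_{ik} - \bar x_i)/(m_k (s_i + s_0))$ with
$m_k = \sqrt{1/n_k - 1/n}$ and fudge $s_0 = \mathrm{median}(s_i)$,
soft-thresholded at $\Delta$, with the operating $\Delta$ chosen by
stratified 10-fold cross-validation as the *largest* threshold attaining the
minimum error (the most parsimonious among ties). Priors default to training
class proportions, matching imbalanced cohorts. Agreement between a
transferred classification and a cohort's own unsupervised labels is
summarized by `consistency_rate()` (exact agreement under fixed label
names — the anchor convention above is what makes names comparable across
cohorts) and by `centroid_congruence()` (Pearson correlation of subtype
centroids over shared pathways).

## Differential statistics

`differential_enrichment()` reports, per pathway, the difference of group
mean scores in a column conventionally labeled "LFC" in this field.
Enrichment scores can be negative, so a literal log-ratio is undefined; the
mean difference is exactly the "logFC" a linear-model pipeline reports when
fed a score matrix, and it is documented as such rather than silently
renamed. Significance comes from the two-sided Wilcoxon rank-sum test —
exact enumeration when $n_1+n_2 \le 12$ with no ties, otherwise the normal
approximation with tie and continuity corrections — with Benjamini–Hochberg
adjustment across pathways. Cohen's d (pooled-SD standardized difference)
serves the same role for abundance-scale data, and `activity_group_test()`
is the two-group linear-model t-test on standardized precomputed pathway
activities (activity matrices are accepted as input; no activity-inference
weight matrix is shipped).

## Survival suite

Kaplan–Meier estimation, the log-rank test, Cox proportional-hazards fits,
and the Schoenfeld-residual proportionality check are delegated to the
`survival` package behind this package's interfaces; these are standard,
well-audited steps, not this package's contribution. Fixed choices:

* Efron tie correction (the reference default; note that under Efron,
  duplicating every record shifts $\beta$ slightly — exact duplication
  invariance holds only for Breslow — so the suite checks it at a small
  relative tolerance);
* Newton–Raphson tolerance $10^{-9}$, at most 50 iterations; divergence
  (monotone likelihood / perfect separation) raises an error instead of
  returning a runaway coefficient;
* Wald confidence intervals, level configurable;
* concordance index: Harrell's C over censoring-comparable pairs, risk ties
  counting $1/2$, with Noether-type normal CIs at both 95% and 85% — the 85%
  interval approximates a 5% error rate when two C-indices are compared by
  interval overlap.

`risk_group_model()` compares the Cox model on one dichotomous clinical
factor against the model on the four factor-by-subtype combinations (three
indicators against a designated high-risk reference combination) by a
likelihood-ratio chi-square with 2 degrees of freedom.

`multivariable_workflow()` is the full protocol: event-stratified random 7:3
train-test split ("balanced" is interpreted as balance on the event
indicator, which prevents event-free test sets at modest $n$; the balancing
variable was an open design point), univariable screen at $p < 0.2$,
backward elimination minimizing AIC with penalty 2 per parameter
(implemented as an explicit deterministic loop equivalent to stepwise AIC),
final fit on the training set, and on the test set a univariable Cox fit of
the centered-and-scaled linear predictor plus the concordance index with
dual CIs. A screen that removes every candidate returns a documented null
result rather than an exception.

`sliding_threshold_scan()` generalizes a fixed top-vs-bottom sextile
comparison to a grid of fractions $f \in \{0.05, \dots, 0.50\}$: at each
$f$, the $\lfloor f n\rfloor$ largest and smallest marker values form the
two groups (marker ties broken by stable sample order, stated because
percentage-valued markers tie often), the middle is excluded, and a
univariable Cox model is fitted. Fractions above $0.5$ would overlap the
groups and are refused.

## The synthetic world

`simulate_cohort()` generates the cohort the tests and the acceptance
script run on. Its defaults are a stated world, chosen once: 200 samples in
two equal subtypes; ~95 disjoint pathways of 10–40 genes cycling through the
12 metabolic category labels, plus 300 background genes; a glycan-category
anchor pathway elevated only in the MPS1 analog and a broad amino-acid/lipid
elevation in the MPS2 analog, with effect size $\delta = 1$ per-gene SD;
negative-binomial counts with dispersion 0.3 around log-normal baseline
means (median 200), the subtype shift applied on the log scale as
$\delta \cdot \sqrt{\log(1+\phi)}$, the log-scale SD the NB's gamma mixing
implies; exponential survival with hazard ratio 1.75 for the MPS1 analog
against a two-year-median baseline, and independent exponential censoring
calibrated numerically so the expected censoring fraction is 0.3. All
randomness flows from the single config seed, and regeneration is
bit-identical.

What the generator does **not** emulate: overlapping pathway membership
(real KEGG maps share genes; planted effects stay interpretable only with
disjoint sets), library-size and batch effects, gene-gene correlation beyond
the pathway shifts, single-cell sparsity, and non-proportional hazards. A
green recovery test therefore establishes that the pipeline recovers planted
structure of the stated kind and size — not that any real cohort contains
such structure.

`inst/extdata/kegg_metabolic_synthetic.gmt` is a deterministic synthetic
stand-in for the curated KEGG metabolic collection with the same accounting
(95 sets, 1659 unique genes, 12 categories, overlapping membership); its
gene symbols are placeholders, as the filename says.

## Known limitations

* The consensus registry carries 10 of the published validity indices;
  extending it changes votes only if the added indices disagree with the
  core in the aggregate.
* NSC assumes roughly class-conditional independence with shared per-feature
  scale; strongly correlated pathway scores can make its CV error curve
  flat, in which case the largest-$\Delta$ tie rule picks the sparsest
  model.
* The C-index CIs are normal approximations; at very few usable pairs they
  are crude.
* Clinical numbers reported for real cohorts (hazard ratios, consistency
  rates on public data) require those cohorts; the package mirrors them
  only as property-style checks on synthetic data.
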