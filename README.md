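# mpsuite

Metabolic pathway-based subtyping of tumor transcriptomes.

Tumors with the same histology can organize their metabolism very
differently, and that organization predicts how they respond to treatment.
`mpsuite` is for computational biologists who have a normalized expression
matrix (bulk RNA-seq counts or continuous log-scale values), a collection of
metabolic pathway gene sets, and optionally clinical follow-up — and who want
to (1) score each sample's pathway enrichment, (2) partition the cohort into
metabolic pathway-based subtypes (MPS), (3) transfer those subtypes to other
cohorts, and (4) quantify their association with survival.

## What it computes

* **Single-sample enrichment** — a from-scratch implementation of the
  kernel-CDF random-walk score: per-gene CDFs are kernel-estimated across
  samples (Poisson kernel, `λ = x + 0.5`, for counts; Gaussian with
  bandwidth `s_i/4` for continuous values), genes are ranked per sample by
  `F̂`, and a weighted Kolmogorov–Smirnov-like walk over each gene set yields
  a score `ES ∈ [−1, 1]` per pathway and sample. Set sizes are bounded to
  `[9, 300]` after intersection with the measured genes.
* **Subtype discovery** — seeded k-means (100 starts, 100 iterations) on the
  score matrix; when `k` is not forced, ten cluster-validity indices
  (silhouette, Calinski–Harabasz, Davies–Bouldin, Dunn, Hartigan,
  Krzanowski–Lai, gap, point-biserial, McClain–Rao, SD) each vote for their
  preferred `k ∈ [2, 10]` and the mode wins. Cluster identities are named
  deterministically (MPS1 = highest anchor-pathway centroid, by convention
  the chondroitin/dermatan-sulfate glycan pathway).
* **Cross-cohort transfer** — nearest shrunken centroids
  (`d_ik = (x̄_ik − x̄_i)/(m_k(s_i + s0))`, soft-thresholded at a
  cross-validated Δ), plus agreement metrics: exact classification
  consistency and Pearson congruence of subtype centroids.
* **Differential enrichment** — per-pathway group-mean score differences
  (the "LFC" column), Wilcoxon rank-sum p-values (exact for small tie-free
  samples), Benjamini–Hochberg adjustment, Cohen's d, a two-group
  linear-model test for precomputed activities, and pre-ranked GSEA with
  seeded permutation p-values.
* **Survival** — Kaplan–Meier, log-rank, Cox PH with Efron ties (via the
  `survival` package), Schoenfeld-residual proportionality checks, Harrell's
  concordance with 95%/85% CIs, nested two-group vs four-group risk models
  compared by likelihood ratio, an event-stratified 7:3 train/test
  multivariable workflow (p < 0.2 screen, backward AIC, standardized
  test-set risk score), and a sliding-threshold top-vs-bottom marker scan.
* **Synthetic cohorts** — a seeded generator planting subtype shifts in
  pathway gene expression with coupled exponential survival, so the whole
  pipeline is testable offline.

## Worked example

```r
library(mpsuite)

cfg <- simulation_config(n_samples = 300, n_pathways = 60,
                         pathway_size_range = c(10, 20), n_background = 100,
                         seed = 7)
cohort <- simulate_cohort(cfg)

scores <- gsva_scores(cohort$expr, cohort$collection, kernel_spec("poisson"))
model  <- discover_subtypes(scores, anchor = "glycan_cs_ds", seed = 7)
model
#> MPS subtype model: k = 2 over 60 pathways, 300 samples
#>
#> MPS1 MPS2
#>  150  150
#> Consensus votes:
#>        silhouette calinski_harabasz    davies_bouldin              dunn
#>                 2                 2                 2                 2
#>          hartigan    krzanowski_lai               gap    point_biserial
#>                 2                 2                 2                 2
#>       mcclain_rao          sd_index
#>                 2                 2

adjusted_rand_index(model$labels, cohort$truth[names(model$labels)])
#> [1] 1
```

All ten indices vote for `k = 2`, matching the two planted subtypes, and the
recovered labels agree perfectly with the generator's truth (ARI = 1). The
subtype is then associated with the simulated survival endpoint:

```r
is1 <- as.numeric(model$labels[cohort$clinical$sample_id] == "MPS1")
coxph_fit(data.frame(MPS1 = is1),
          cohort$clinical$OS_time, cohort$clinical$OS_event)
#> Cox proportional-hazards fit (Efron ties): n = 300 , events = 206
#>        beta     HR  lower  upper     p
#> MPS1 0.4825 1.6202 1.2258 2.1413 7e-04
```

The estimated hazard ratio 1.62 (95% CI 1.23–2.14) recovers the planted
MPS1 hazard ratio of 1.75 at this sample size. The pathways driving the
split are the planted ones, led by the glycan anchor:

```r
tab <- differential_enrichment(scores$scores, model$labels)
head(tab[order(tab$p_adj), c("feature", "delta", "p_adj")], 3)
#>         feature      delta        p_adj
#> 1   pathway_001 -0.6360007 8.478596e-49
#> 5  glycan_cs_ds  0.7322754 8.478596e-49
#> 25  pathway_025 -0.6134224 8.478596e-49
```

Here `delta` is the MPS1-minus-MPS2 mean score difference: positive for the
glycan anchor (elevated in MPS1), negative for the broadly-elevated MPS2
pathways.

A command-line wrapper with per-stage subcommands (`simulate`, `score`,
`subtype`, `diff`, `survive`, `scan`, `pipeline`) is installed at
`system.file("cli", "mpsuite", package = "mpsuite")`.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch:
it simulates a seeded synthetic cohort, writes its expression/GMT/clinical
files, executes the full pipeline (scoring, subtype discovery, differential
enrichment, survival association), and writes the JSON report of numeric
targets to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

* `R/` — implementation (gene-set I/O, enrichment engine, subtyping, NSC,
  statistics, survival, synthetic generator, pipeline).
* `inst/extdata/kegg_metabolic_synthetic.gmt` — deterministic synthetic
  stand-in for the curated KEGG metabolic pathway collection (95 sets, 1659
  unique placeholder genes, 12 categories).
* `vignettes/metabolic-subtyping.Rmd` — the methods vignette: models,
  parameters, numerical conventions, what the synthetic world does and does
  not establish.
* `tests/testthat/` — unit, property, and acceptance tests, with independent
  naive-loop oracles in `helper-oracles.R`.
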