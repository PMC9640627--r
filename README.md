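# lncTES

Screening for **pathway-associated long noncoding RNAs (lncRNAs)** in bulk
tumour expression cohorts, with downstream molecular subtyping and survival
risk modelling. Written for computational biologists who have a gene-level
expression matrix split into mRNAs and lncRNAs, per-sample tumour purity
estimates, a survival table, and a target gene set (e.g. an MSigDB hallmark
pathway), and who want to know which lncRNAs track that pathway's activity
once the purity confounding that pervades bulk co-expression is removed.

## The statistic

For lncRNA *i* and mRNA *j* with purity vector *p*, the screen computes the
first-order partial correlation

```
PCC_ij = (R_lm − R_lp · R_mp) / (√(1 − R_lp²) · √(1 − R_mp²))
```

its normal-approximation p-value
`P_ij = 2·Φ(−|PCC_ij·√((n−3)/(1−PCC_ij²))|)`, and the signed rank index
`RI_ij = −ln(P_ij)·sign(PCC_ij)`. mRNAs are sorted by descending RI and the
target set is tested with a weighted Kolmogorov–Smirnov enrichment score
(ES ∈ [−1, 1]) against a gene-label permutation null. After
Benjamini–Hochberg adjustment across lncRNAs (giving `P_i`), direction and
significance combine into the **total enrichment score**

```
TES_i = (1 − 2·P_i) · sign(ES_i)   ∈ [−1, 1]
```

with candidates gated at `|TES| > 0.95` and `P_i < 0.05`. Candidates feed
consensus clustering (subsampled k-means, CDF-based selection of the cluster
number) and a Cox proportional-hazards risk score with median split and
log-rank testing. A seeded synthetic-cohort generator with planted pathway
activity, purity confounding, subtypes, and survival makes every claim
testable at desk scale.

## Worked example

```r
library(lncTES)

co <- generate_cohort(synthetic_config(seed = 11))   # 300 samples, planted signal
scr <- screen_lncrnas(co$expression, co$purity, co$truth$pathway_genes,
                      n_perm = 1000, seed = 5)
head(as.data.frame(scr), 7)
#>        lnc_id         es       p_raw      p_adj       tes is_candidate
#> 1 lncRNA_0057 -0.1656813 0.997002997 0.99700300 0.9940060        FALSE
#> 2 lncRNA_0001  0.9506814 0.000999001 0.01198801 0.9760240         TRUE
#> 3 lncRNA_0002  0.9421624 0.000999001 0.01198801 0.9760240         TRUE
#> 4 lncRNA_0003  0.9549210 0.000999001 0.01198801 0.9760240         TRUE
#> 5 lncRNA_0004  0.9515628 0.000999001 0.01198801 0.9760240         TRUE
#> 6 lncRNA_0005  0.9242344 0.000999001 0.01198801 0.9760240         TRUE
#> 7 lncRNA_0026 -0.2144701 0.966033966 0.98240742 0.9648148        FALSE
sum(scr$is_candidate)
#> [1] 5
```

The five planted lncRNAs (`lncRNA_0001`–`0005`) sit at the permutation
floor (`p_raw = 1/1001`), get `TES ≈ 0.976` after BH adjustment across the
60 screened lncRNAs, and pass both gates; no inert lncRNA is called in this
seed. The top row shows why the candidate definition needs *both* gates:
`TES = (1 − 2P)·sign(ES)` is symmetric about `P = 0.5`, so an
*anti-extreme* permutation p-value near 1 also produces `|TES|` near 1 (with
flipped sign) — the `P < 0.05` condition screens those out.

The full chain — ssGSEA pathway scoring, univariate Cox pathway screen,
lncRNA screen, consensus subtyping, risk model — runs as one call and
writes TSV/JSON stage outputs plus a manifest:

```r
cfg <- pipeline_config(synthetic = list(subtype_shift = 3), seed = 17)
run_pipeline(cfg, "out/")
```

A thin command-line front end with the same stages lives at
`inst/scripts/lnc-pipeline.R`
(`Rscript lnc-pipeline.R run-all --config cfg.yaml --seed 17 --outdir out`).

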