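# agmniche

Transcriptomic mapping of the embryonic hematopoietic stem cell (HSC) niche
and prioritisation of secreted niche factors.

The first definitive HSCs mature in the aorta-gonad-mesonephros (AGM) region
of the mid-gestation mouse embryo, driven by signals concentrated in the
ventral domain of the dorsal aorta (AoV) between embryonic days 9.5 and
10.5. `agmniche` is a tested, reusable implementation of the computational
workflow for mapping that niche from bulk RNA-seq of dissected AGM
subdomains (AoV, AoD, UGR at E9.5/E10.5 in triplicate) and for screening
secreted candidate factors against a supportive stromal cell line (OP9,
profiled flat versus reaggregated). It is aimed at developmental
hematologists and computational biologists who want the pipeline's
statistical machinery without the original deposited data: every stage runs
on synthetic inputs with planted ground truth.

## What it implements

- **Quantification** — fractional assignment of multi-mapping reads
  (a read hitting genes g1..gk adds U(gi)/ΣU(gj) to each, U = unique-read
  evidence; equal split when no evidence, so mass is conserved exactly),
  reads-per-million scaling, and the 0.5 RPM expression floor.
- **Exploration** — PCA of expressed genes (zero-centered, unit variance)
  with one-way ANOVA linking components to embryonic stage and
  dorso-ventral polarity.
- **Consensus clustering** — the top-3000 CV genes, median-centered, 50
  subsampled average-linkage clusterings on 1 − Pearson r per K in 2..10;
  consensus CDF areas select K at the smallest relative gain below 0.025.
- **Differential expression** — median-of-ratios size factors,
  method-of-moments NB dispersions with an a0 + a1/μ trend (max sharing),
  a conditional exact test on group sums, Benjamini-Hochberg adjustment,
  calls at |FC| ≥ 2 and FDR ≤ 0.05.
- **Gene-set testing** — TMM factors and voom-style observation weights
  (both numerically matching the established implementations), then a
  rotation set test with empirical-Bayes variance moderation:
  p = (b+1)/(n_rot+1), directional and mixed statistics, BH across
  pathways at 0.2, contributing genes at uncorrected p < 0.2.
- **GO enrichment** — true-path DAG propagation, classic hypergeometric and
  elim-decorrelated p-values; secreted = annotated (directly or via
  ancestry) to GO:0005576 / GO:0005615.
- **Candidate funnel** — stage-up-regulated ∩ secreted genes, mean-rank
  combination of the stage and polarity fold-change ranks, OP9 category
  (absent / expressed / up-regulated on reaggregation at > 0.5 RPM), and
  hypergeometric cluster/OP9 overlaps.
- **Validation statistics** — exact/approximate Wilcoxon rank-sum for
  donor chimerism, BH screening at 10% FDR, colonies per embryo
  equivalent, and ΔΔCt qPCR expression with pooled-variance t tests.
- **Synthetic data** — NB generators (Var = μ + αμ²) for the niche design,
  the OP9 experiment, alignments, annotations/DAG/pathways and
  repopulation percentages, all with planted truth and explicit seeds.

## Worked example

```r
library(agmniche)

sim  <- simulate_niche_counts(n_genes = 1500, seed = 42)   # 5 tissues x 3 reps
expr <- filter_expressed(rpm_normalize(sim$counts))

pca <- niche_pca(expr)
print(pca)
#> PCA of 1500 genes x 15 samples
#> variance explained (%): 28.1, 22.7, 11, 10.4, 3.3 ...

genes <- select_variable_genes(expr, 520)
cc <- consensus_cluster(median_center(expr[genes, ]), 2:8, 50, 0.8, seed = 43)
select_k(cc)
#> [1] 5
cluster_signature_anova(cc$runs$K5$assignment, median_center(expr[genes, ]),
                        sim$metadata)
#>   cluster n_genes peak_tissue         F            p
#> 1       1     103   E10.5_AoV  5058.338 1.764250e-16
#> 2       2      96   E10.5_AoD  5070.121 1.743856e-16
#> 3       3     116    E9.5_AoV 26216.421 4.728710e-20
#> 4       4      95   E10.5_UGR  7303.892 2.813278e-17
#> 5       5     110    E9.5_AoD 11749.859 2.613058e-18
```

The first two components separate the samples by stage and polarity, and
consensus clustering recovers the five planted tissue programs (K = 5, each
cluster's mean signature peaking in its planted tissue at p < 1e-15).
Running the two differential contrasts (E10.5 AoV vs E9.5 AoV; AoV vs AoD),
simulated annotations and an OP9 experiment through the funnel:

```r
fun <- run_funnel(de_stage, de_pol, ann$annotation,
                  rpm_normalize(op9$counts), op9_de,
                  clusters = cc$runs$K5$assignment)
print(fun)
#> Candidate funnel: 160 up-regulated -> 26 secreted
#>   OP9 categories: absent 2 / expressed 21 / up on reaggregation 3
#>           gene_id log2fc_stage log2fc_polarity final_rank  op9_category
#> 1  gene_candidate     3.976764        3.759075          1  upregulated_on_reaggregation
#> ...
```

Of 160 stage-up-regulated genes, 26 are secreted; the planted candidate — a
gene simulated to rise 16-fold ventrally between stages, be secreted, and be
induced in OP9 cells on reaggregation — is recovered at rank 1 with the
correct OP9 category.

## Package layout

`R/` one file per stage (io, simulate, quantify, pca, consensus, diffexp,
gsa, enrich, screen, validation); `tests/testthat/` unit, property and
acceptance suites with independent brute-force oracles in
`helper-oracles.R`; `vignettes/niche-pipeline-methods.Rmd` documents the
models, parameter choices and limitations.
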