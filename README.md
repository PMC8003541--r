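# mir29triage

Integrative prioritization of miR-29 target genes in melanoma
transcriptomes.

The miR-29 family (miR-29a/b/c, from the miR-29b1~a and miR-29b2~c
clusters) is a melanoma tumor suppressor whose pri-miR-29b2~c cluster is
silenced as nevi progress to melanoma, de-repressing its targets. Any
single targeting criterion — a fold change after mimic transfection, a
seed match, clinical co-expression — is individually weak, so this
package nominates candidate targets by intersecting four orthogonal
evidence streams, and supplies the downstream statistics used to
characterize them. It is written for computational biologists who want
the whole chain as tested, composable functions rather than a one-off
analysis.

A gene is a candidate iff it passes all four stages:

| Stage | Evidence | Criterion |
|---|---|---|
| 1 | mimic-vs-control RNA-seq | log2FC < −0.5 **and** FDR < 0.05 (strict) |
| 2 | melanoma-vs-nevus cohort | log2FC ≥ 0.3 **and** FDR ≤ 0.05 |
| 3 | conserved seed sites | ≥ 8 of 12 prediction algorithms **and** conserved |
| 4 | pri-miR-29b2~c co-expression | Pearson r ≤ −0.3 on log2(normalized + 1) |

Both differential contrasts use a self-contained negative-binomial Wald
test: median-of-ratios size factors, method-of-moments dispersion
(Var = μ + φμ²) with trend shrinkage, delta-method standard errors and
Benjamini–Hochberg step-up FDR. Seed sites (8mer > 7mer-m8 > 7mer-A1 >
6mer, classified from the 6-nt seed core and its flanking context) are
detected by an internal scanner over 3'UTR FASTA and exported as BED6.
Survival of score-stratified patients is compared with the
Gehan–Breslow–Wilcoxon weighted log-rank test (weight = number at risk,
exact small-sample p by enumeration), qPCR data with the 2^−ΔΔCt
convention, and dual-luciferase reporters with a seed-mutant rescue
index. A negative-binomial simulator generates every input with planted
ground truth — repressed targets, planted seed sites and algorithm
votes, a latent pri-miR-29b2~c factor inducing anti-correlation, and
hazards coupled to a target score — so the entire cascade is validated
end to end.

## Worked example

```r
library(mir29triage)

demo <- runDemo(simParams(seed = 7))
demo$cascade
#> CascadeResult: 8 candidate(s) from 2000 genes
#>   stage 1 (mimic down):  log2FC < -0.5 & FDR < 0.05  [8 genes]
#>   stage 2 (cohort up):   log2FC >= 0.3 & FDR <= 0.05 [9 genes]
#>   stage 3 (sites):       >= 8 algorithms & conserved [9 genes]
#>   stage 4 (anticorr):    r <= -0.3            [14 genes]
#>   candidates: g0005, g0006, g0002, g0001, g0007, g0008, g0004, g0009

head(candidates(demo$cascade)[, c("gene_id", "mimic_lfc", "mimic_fdr",
                                  "cohort_lfc", "n_algorithms", "r")], 4)
#>   gene_id  mimic_lfc    mimic_fdr cohort_lfc n_algorithms          r
#> 1   g0005 -0.9883285 2.699736e-12  0.5135888           11 -0.8440480
#> 2   g0006 -1.2862499 3.145738e-10  0.5035611           11 -0.8398330
#> 3   g0002 -1.3065137 1.221353e-13  0.5688373            9 -0.8393217
#> 4   g0001 -0.6095395 5.280106e-03  0.5821337            8 -0.8328218

demo$report$recall     # 0.889: 8 of the 9 planted targets recovered
demo$report$precision  # 1.000: no non-planted gene survived the cascade
```

The nine planted targets are `g0001`–`g0009`; at this seed the cascade
recovers eight (the ninth drew too few algorithm votes — the designed
binomial lottery of stage 3) with zero false positives among 1991
background genes. Each candidate row shows the evidence it passed on:
a ~2-fold mimic repression at genome-wide significance, cohort
upregulation around +0.5 log2, a conserved consensus site, and strong
anti-correlation with the emitted pri-miR-29b2~c vector.
`stageLedger(demo$cascade)` returns every gene with its four stage
booleans, and `runDemo(..., outDir = "out")` writes all intermediate
tables (counts/metadata TSV, UTR FASTA, BED sites, candidate and ledger
TSV, survival tables, KM curves, JSON report).

Individual stages are plain functions: `findSeedSites()`,
`summarizeGeneSites()`, `computeSizeFactors()`, `nbWaldTest()`,
`bhAdjust()`, `corLog2()`, `runCascade()`, `kmEstimate()`, `gbwTest()`,
`stratifyByScore()`, `ddctQuantify()`, `luciferaseNormalize()`,
`groupCompare()`, and the `simulate*()` generators.

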