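# coregQTL

Multi-layer molecular QTL co-regulation analysis in R.

## What problem this solves

A causal regulatory variant leaves correlated footprints at every layer of
gene regulation: chromatin openness (caQTL from ATAC-seq, hQTL from
histone-mark ChIP-seq), transcript abundance (eQTL), and ultimately the
protein phenotype (pQTL). `coregQTL` is for geneticists who want to make —
and stress-test — that multi-layer argument at a locus:

* build the molecular phenotypes: repeated-measures protein aggregates
  from an animal model (AI-REML with relationship-matrix random effects),
  input-residual chromatin phenotypes from ChIP/ATAC count matrices, and
  size-factor-normalised expression;
* map each layer with a mixed linear model (MLMA): GRM construction with
  LOCO/LOSO region exclusion, eigen-rotated REML variance components,
  per-variant GLS effects, conditional scans on candidate variants;
* quantify cross-layer agreement: Pearson/Spearman correlations of allele
  effects and of −log10(p), and the PCA pseudo-R² — for three layers, the
  fraction of variance of the aligned effect vectors captured by their
  first principal component;
* extract the **core haplotype**: the variants simultaneously in the top
  5% by |β| of every layer;
* score candidate variants for transcription-factor binding-site
  disruption: PWM scanning with relative-score thresholds and exact
  score-distribution (TFM) p-values computed by dynamic programming, for
  both alleles.

The key quantities, in standard notation: the per-variant model is
`y = Xβ + g·b + u + e` with `u ~ N(0, σ²_g G)` and `G = ZZ'/m` the
standardised-dosage GRM; a log-scale allele effect `b` converts to a fold
change `exp(b)` per allele; the pseudo-R² of layers 1–3 is
`λ₁ / (λ₁ + λ₂ + λ₃)` of their correlation matrix; a TFBS hit's relScore is
`(s − s_min)/(s_max − s_min)` and its TFM p-value is
`P(score ≥ s)` under the background base distribution.

A fully seeded synthetic-data generator (`sim_config()`,
`simulate_genotypes()`, `simulate_molecular_cascade()`) emulates the causal
cascade in an F2 cross — a high-frequency (MAF 0.45) core haplotype of 20
perfectly linked variants with a 0.56 natural-log per-allele protein
effect, negative-binomial chromatin counts with paired input, and three
lactation periods at heritability 0.4 — so every stage is testable offline.

## Worked example

```r
library(coregQTL)
report <- run_demo(seed = 1)
report
#> Co-regulation demo (seed 1)
#>   aggregate-protein h2: 0.203 (SE 0.038)
#>   Bonferroni threshold: 2.5e-05
#>   pqtl   causal variant beta=+0.618  p=6.93e-59 (significant)
#>   eqtl   causal variant beta=+0.659  p=3.16e-76 (significant)
#>   hqtl   causal variant beta=+0.246  p=9.53e-49 (significant)
#>   caqtl  causal variant beta=+0.240  p=1.2e-44 (significant)
#>   pQTL~eQTL Pearson beta r = 0.991
#>   pseudo-R2 (beta, triplet): 0.989
#>   core haplotype: 20 variants, recall 1.00, precision 1.00
#>   after conditioning on causal: 19 perfect-LD copies collinear, min focal-window p = 0.0227
#>   TFBS sites disrupted at planted variant: 1
```

Reading the output: the planted causal variant is genome-wide significant
(Bonferroni 0.05/2000 tests) in all four molecular layers, with a protein
effect of 0.618 natural-log units per allele — `effect_to_fold(0.618)`
≈ 1.86× protein per allele — against a simulated truth of 0.56. The four
top-5% sets intersect in exactly the 20 planted core variants (recall and
precision 1.0). Conditioning the protein scan on the causal variant
absorbs the entire locus signal: its 19 perfect-LD copies become
statistically collinear and no remaining variant in the focal window stays
below p = 1e-3. One planted binding site is disrupted by the candidate
variant (alt-allele score lower than ref).

The same stages are available as a file-based workflow with YAML
configuration and provenance sidecars:

```r
cfg <- read_pipeline_config("config.yaml")   # or read_pipeline_config(NULL)
run_pipeline(cfg, "out/")                    # simulate → pheno → chrompheno
                                             # → assoc → coreg → tfbs
```

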