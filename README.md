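# infoRatio

Where does the information about a clinical phenotype live in a gene
expression matrix — in the handful of leading principal components that
carry the study's dominant co-expression, or in the high-dimensional
residual behind them? The answer predicts whether the phenotype will yield
reproducible biomarkers. `infoRatio` implements the **Information Ratio
(IR)**, a weighted p-value-ratio statistic that quantifies this partition,
together with the machinery to relate it to gene-list stability across
studies and to classifier-accuracy transfer.

The package is aimed at transcriptomics analysts who select gene
signatures from case-control expression studies (bulk arrays or RNA-seq
count matrices after log transformation) and need to know, *before*
trusting a signature, whether the contrast at hand can support one.

## The statistic

For a study with log2 expression x and a binary contrast:

1. The gene–gene Pearson correlation matrix is decomposed (via SVD of the
   row-standardized matrix) and the top *n* eigenvectors (default n = 4)
   define metagene profiles across samples, spanning the subspace S_n.
2. Every gene's centered profile is split by least squares into a
   projected and a residual component, x = x_p + x_r, with the centered
   residual orthogonal to S_n.
3. Welch's t-test per gene in original, projected and residual space gives
   log10 p-values lp, lp_p, lp_r.
4. Genome-wide |lp| is near-exponential; its decay rate λ, fitted by
   log-linear regression on a 50-bin histogram, defines weights
   w_i = exp(λ|lp_i|) under which every sensitivity stratum of genes
   contributes equally.
5. The Information Ratio is

       IR = Σ_i w_i |lp_r,i| / (|lp_r,i| + |lp_p,i|)  /  Σ_i w_i  ∈ [0, 1]

   IR ≤ 0.25 classifies the contrast as "type 1" (information inside S_n:
   stable gene lists, transferable classifiers); higher IR means the
   information sits partly (type 2) or mostly (type 3) in the residual,
   where gene rankings are noise-driven and signatures do not replicate.

Stability between two studies is measured as the percentage of overlapping
genes (POG) in their top-5% Welch-ranked lists; achievable accuracy by an
RBF-SVM under nested 10×10 cross-validation with in-fold gene selection;
transferability by the accuracy loss when a source-ranked list is reused
in another study. A latent-factor simulator generates studies with known
intrinsic dimensionality and controlled signal placement, so every claim
is testable without external downloads.

## Worked example

```r
library(infoRatio)

# a synthetic study whose phenotype is tied to the leading factors
cfg <- simConfig(signalMode = "subspace", seed = 7)
sim <- simulateStudy(cfg)
sim$study
#> ExpressionStudy 'sim_subspace_d4_s7': 2000 genes x 100 samples
#> phenotype variables (1): group

irForContrast(sim$study, sim$contrast, n = 4)
#> IRResult 'group_c1_vs_c2': IR = 0.0977 (n = 4, lambda = 0.21, 2000 genes) [type1_low]

# the same machinery on a residual-placed signal
simR <- simulateStudy(simConfig(signalMode = "residual", seed = 7))
irForContrast(simR$study, simR$contrast, n = 4)
#> IRResult 'group_c1_vs_c2': IR = 0.7075 (n = 4, lambda = 0.762, 2000 genes) [type2_3_high]
```

The subspace-placed signal is type 1 (IR 0.10, far below the 0.25
threshold); the residual-placed signal of identical per-gene size lands at
IR 0.71. The practical consequence — gene-list stability — shows up when
two cohorts of the same biology are compared:

```r
pr <- simulateStudyPair(cfg, sharedSignal = TRUE)   # two cohorts
deOf <- function(s) {
  m <- fitSubspace(s$study, 4)
  differentialAllSpaces(s$study, splitExpression(s$study, m), s$contrast)
}
pog(topGeneList(deOf(pr$a), 0.05), topGeneList(deOf(pr$b), 0.05))
#> [1] 69
```

69% of the top-5% genes replicate across the low-IR pair (residual-signal
pairs stay near the ~5% chance level). The subspace dimension itself can
be scanned; on intrinsically four-dimensional data the IR falls and then
flattens at n = 4, which is why 4 is the default:

```r
irDimensionScan(sim$study, sim$contrast, nRange = 1:6)[, c("n", "ir")]
#>  n         ir
#>  1 0.49420873
#>  2 0.55159131
#>  3 0.26905086
#>  4 0.09765415
#>  5 0.09820354
#>  6 0.09349528
```

Real data enter through TSV files (`loadExpression()`,
`loadPhenotypes()`), with the usual hygiene steps available as functions:
probe-set collapse to symbols by largest mean expression
(`collapseProbesets()`), cross-study sample deduplication at R² ≥ 0.99
(`deduplicateSamples()`), 5σ mean-expression outlier removal
(`removeOutlierSamples()`), gene-set intersection (`intersectGenes()`),
and a registry of clinical binarization rules (`builtinContrasts()`:
grade 1&2 vs 3, tumor size >25 mm vs <20 mm, ER status, five-year
relapse, and so on).

A command-line wrapper is installed under `exec/ir`:

```sh
ir simulate --seed 1 --out-expr sim.tsv --out-pheno pheno.tsv
ir compute --expr sim.tsv --pheno pheno.tsv --contrast group_c1_vs_c2 \
   --n 4 --out ir.json
ir scan-n --expr sim.tsv --pheno pheno.tsv --contrast group_c1_vs_c2 \
   --n-min 1 --n-max 10 --out scan.tsv
```

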