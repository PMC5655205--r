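# dbncs

Inference of multiple time-delayed gene regulatory networks (GRNs) from
time-series expression data, for systems biologists who want not just *who
regulates whom* but also *with what transcriptional lag*.

## The method

Given a genes x time expression matrix X, `dbncs` reconstructs a dynamic
Bayesian network — a directed prior network paired with an integer delay
(transition) matrix — in five stages:

1. **Skeleton learning.** Path-consistency filtering of the complete graph
   with conditional mutual inclusive information. For Gaussian data,
   MI(X,Y) = −½ ln(1 − r²), CMI is a determinant ratio of covariance
   blocks, and CMI2 augments CMI with two Kullback–Leibler terms comparing
   the observed distribution with the interventional distributions in which
   the direct edge X→Y (resp. Y→X) is deleted:
   CMI2(X;Y|Z) = ½ D(P‖P_{X→Y}) + ½ D(P‖P_{Y→X}).
   Edges whose order-L conditional strength falls below a threshold θ are
   removed, L increasing until no conditioning set exists.
2. **Redundancy pruning.** Per target gene, regulation intensities β solve
   the LAD-lasso problem min Σᵢ|yᵢ − βᵀxᵢ| + λ‖β‖₁, reformulated exactly as
   a linear program; coefficients below θ₀ are zeroed and the survivors
   refitted until stable.
3. **Delay estimation.** For each surviving pair and direction, the
   transcriptional delay m\* maximises the MI of the shift-aligned series
   (x[1..T−m], y[m+1..T]) over m = 1..k.
4. **Orientation.** Each co-expressed pair is oriented by the comprehensive
   score CS = σ·(ω|β^RO| + (1−ω)β^MI)² + (1−σ)·TRS², combining
   background-standardized linear, non-linear and dynamic evidence; the
   higher-scoring direction wins, exact ties breaking deterministically.
5. **Assembly.** Oriented edges, delays and scores become a
   `TimeDelayedGRN` (S4) with accessors, TSV/SIF writers and evaluation
   helpers (confusion counts, TPR/FPR/PPV/ACC/MCC, rank-based AUROC).

A delayed linear-Gaussian simulator with known ground truth
(`simSpec()`/`simulateGRNData()`) makes every stage testable without any
external download. See the methods vignette
(`vignettes/grn-inference-methods.Rmd`) for assumptions, parameter guidance
and limitations.

## Worked example

```r
library(dbncs)

spec <- simSpec(nGenes = 10, nEdges = 10, seed = 7)   # planted 10-edge DAG
sim  <- simulateGRNData(spec)                         # 10 x 50 time course
grn  <- inferGRN(sim$expression, theta = 0.03, kMax = 5,
                 omega = 0.09, sigma = 1)
grn
#> TimeDelayedGRN: 10 genes, 12 directed edges, kMax = 5
#>   regulator target delay       score
#> 1        G4     G1     1 0.170311472
#> 2        G3     G2     1 0.833238501
#> 3        G2     G5     1 0.172715819
#> 4        G2     G6     1 0.072902437
#> 5        G2     G9     1 0.020187180
#> 6        G6     G4     4 0.000620423

classificationMetrics(confusionCounts(grn, sim$network))
#> TPR=0.700 FPR=0.062 PPV=0.583 ACC=0.911 MCC=0.589 AUC=NA

rocAUC(candidateScores(grn), priorNetwork(sim$network))
#> [1] 0.8160494
```

Seven of the ten planted regulations are recovered with the correct
direction (TPR 0.70) at five false positives over the 90 ordered gene
pairs (FPR 0.062); each reported edge carries its estimated
transcriptional delay in sampling intervals, and the comprehensive scores
rank all candidate pairs with AUROC 0.82 against the planted gold
standard.

## Command line

```sh
dbncs simulate --genes 10 --edges 10 --timepoints 50 --seed 1 --out sim
dbncs infer    --expr sim_expression.tsv --theta 0.03 --max-delay 5 --out net
dbncs evaluate --pred net.tsv --gold sim_gold.tsv --out metrics.tsv
```

(`exec/dbncs` ships with the package; options may also come from a YAML
file via `--config`, with explicit flags taking precedence.)

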