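# POSelect

Overlap-based gene selection for two-class expression data.

Given a genes × samples expression matrix and a binary phenotype per sample
(tumour/normal, responder/non-responder, …), POSelect ranks genes by how
little their per-class expression intervals overlap and returns a compact,
class-balanced panel of discriminative genes. It is a filter method: fast,
classifier-agnostic, and robust to expression outliers by construction. It
is aimed at transcriptomics analysts who need small marker panels out of
microarray or preprocessed RNA-seq / single-cell matrices.

## The method in brief

For every gene *i* and class *c* the package builds a robust **core
interval** from the empirical quartiles,

    I(i,c) = [ max(Q1 − 1.5·IQR, min), min(Q3 + 1.5·IQR, max) ],

so a single outlying sample cannot stretch the interval. From the two class
intervals it derives the overlap region (their intersection) and a binary
**gene mask** marking the samples the gene classifies unambiguously (inside
their own class's interval, outside the overlap). Each gene gets the
**proportional overlapping score**

    POS(i) = (⟨overlap⟩ / ⟨total⟩) · (|V| / N) · 4·θ1·θ2,   θc = |Vc| / |V|,

where *V* is the set of samples in the overlap region: overlap length,
overlapped-sample fraction, and the class-balance factor 4·θ1·θ2, which
equals 1 when the overlapping samples split evenly between classes. POS lies
in [0, 1]; **lower = more discriminative**. Each gene is also assigned its
**relative dominant class** (RDC) — the class with the larger class-size-
relative share of mask-covered samples.

Selection then proceeds in two stages: a greedy search finds the minimum
gene subset whose combined masks cover every coverable sample (greedy set
cover, highest updated bit-count first, POS as tie-break), and the remaining
genes, split by RDC and sorted by ascending POS, are interleaved round-robin
to extend the panel to the requested *r* genes.

The package also ships a selection-stability index over repeated
cross-validation subsamples, a synthetic two-class generator with planted
ground truth, a Wilcoxon rank-sum baseline selector, and a CV error-rate
benchmark harness (kNN / random forest / SVM).

## Worked example

```r
library(POSelect)

sim <- simulateExpression(nPerClass = c(18, 18), nInformative = 3,
                          nPartial = 4, nNoise = 43, seed = 7)
sim
#> POSExperiment: 50 genes x 36 samples
#> classes: 18 x '1' (1), 18 x '2' (2)

res <- selectGenes(sim, r = 8, seed = 1)
res
#> SelectionResult: r = 8 -> 8 genes ( 1 in minimum subset )
#>             geneId rank        pos rdc inMinimumSubset maskOnes     source
#> 1 g001_informative    1 0.00000000   1            TRUE       36 min_subset
#> 2       g029_noise    2 0.45074393   1           FALSE        5     ranked
#> 3 g002_informative    3 0.00000000   2           FALSE       35     ranked
#> 4       g012_noise    4 0.47310376   1           FALSE        6     ranked
#> 5 g003_informative    5 0.00000000   2           FALSE       35     ranked
#> 6       g025_noise    6 0.53546969   1           FALSE        5     ranked
#> 7     g006_partial    7 0.01059424   2           FALSE       30     ranked
#> 8       g044_noise    8 0.56548449   1           FALSE        4     ranked
```

Reading the output: `g001_informative` alone covers all 36 samples
(`maskOnes = 36`), so the minimum covering subset is that single gene and it
heads the list regardless of score. The other planted genes score POS = 0
(disjoint class intervals) and rank top of their dominant-class group; the
partial-overlap gene scores just above 0. The even ranks come from the
class-1 group: the round-robin alternates between the two RDC groups so the
panel stays balanced per class, and in this draw the best class-1 candidates
after the covering gene are noise genes — visible at a glance from their POS
around 0.5, versus 0–0.01 for the planted genes.

```r
st <- subsampleStability(sim, k = 8, folds = 5, repeats = 4, seed = 1)
st
#> StabilityAssessment: k = 8, lambda = 20, frequency score = 0.6850
```

The stability index (1 = every subsample selects the same 8 genes, 1/20 =
all 20 selections pairwise disjoint) summarises how reproducible the panel
is under resampling.

The same pipeline is scriptable from a shell via the bundled launcher:

```sh
Rscript inst/scripts/pos.R simulate --out-prefix sim --seed 7
Rscript inst/scripts/pos.R select --matrix sim_matrix.tsv \
    --labels sim_labels.tsv --n-genes 8 --seed 1 --out panel.tsv
```

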