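---
title: "Overlap-based gene selection with the proportional overlapping score"
author: "POSelect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overlap-based gene selection with the proportional overlapping score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(POSelect)
```

## The problem

In two-phenotype expression studies (tumour vs normal, responder vs
non-responder) with thousands of genes and a few dozen samples, most genes
are irrelevant to the contrast, and classifiers built on all of them overfit
and are hard to interpret. A filter-style selector scores each gene's
relevance and keeps a small, informative panel. POSelect implements a filter
built on a simple geometric idea: a gene is useful exactly to the extent
that the expression intervals of the two classes do *not* overlap, and it is
useful *for* the class whose samples it places unambiguously.

## Core intervals

For gene $i$ and class $c$ the method computes the empirical quartiles
$Q_1^{(i,c)}, Q_3^{(i,c)}$ and the interquartile range
$IQR^{(i,c)} = Q_3 - Q_1$ of the class-$c$ expressions, and defines the
**core interval**

$$
I_{i,c} = \bigl[\; \max(Q_1 - 1.5\,IQR,\ \min_j x_{ij}),\;\;
                 \min(Q_3 + 1.5\,IQR,\ \max_j x_{ij}) \;\bigr],
$$

a Tukey-fence interval clipped to the observed class range. The fence makes
the interval robust: a single aberrant expression value cannot stretch it,
so one outlying sample does not make two well-separated classes look
overlapping. The clip matters for the score, not the memberships: an
interval extending past every observation would never change which samples
fall inside it, but it would inflate the interval *lengths* that enter the
score below.

Derived per gene:

* the **total core interval** $I_i$, spanning the union of the two class
  intervals;
* the **overlap region** $I_i^v = I_{i,1} \cap I_{i,2}$ (possibly empty);
* the **non-outlier set** $S_i$ — samples lying inside their *own* class's
  core interval;
* the **overlapping set** $V_i$ — samples lying inside the overlap region;
* the **non-overlapping set** $S_i \setminus V_i$.

Interval membership is tested on closed intervals: the wording "falls
inside" carries no strictness, the closed reading is the conservative one,
and it keeps the constant gene (a zero-length interval) well defined. One
design question is whether $V_i$ should be restricted to non-outlier
samples. Both readings are available (`overlapOnNonoutlier`), but they are
provably identical: the overlap region is the intersection of the two class
intervals, so any sample inside it is inside its own class's interval and
hence a non-outlier. A test asserts this equivalence.

Quartiles default to R's `quantile` type 7 (linear interpolation of order
statistics), the convention of the statistical environment this method
family grew up in. The rule is a tunable (`quartileType`, types 1–9) and is
recorded in every result because all downstream scores depend on it.

## Gene masks

The mask of gene $i$ is the indicator of its non-overlapping set: bit $j$ is
1 iff $x_{ij}$ lies in the core interval of sample $j$'s own class and
outside the overlap region — the gene assigns that sample to its class
unambiguously. A sample fenced out of its own class interval always gets
bit 0, even when its expression is far from the overlap region: the gene's
claim about that sample is not trustworthy. The aggregate mask of a gene set
is the bitwise OR of its rows; the aggregate over all genes lists every
sample that *any* gene can classify.

## The proportional overlapping score

$$
POS_i \;=\; \frac{\langle I_i^v\rangle}{\langle I_i\rangle}
       \;\cdot\; \frac{|V_i|}{N}
       \;\cdot\; 4\,\theta_1\theta_2,
\qquad
\theta_c = \frac{|V_{i,c}|}{|V_i|},
$$

three factors in $[0,1]$: the relative length of the overlap region, the
fraction of samples inside it, and a class-balance factor. $\theta_1\theta_2$
is maximised at $\theta_1=\theta_2=\tfrac12$ where it equals $\tfrac14$; the
multiplier 4 therefore scales the product to 1 at the balanced worst case,
and $POS_i \in [0,1]$ with *lower = more discriminative*. The balance factor
is the method's distinctive ingredient: of two genes with identical overlap
geometry, the one whose overlapping samples come 10:2 from the two classes
overlaps "less", in a classification sense, than the one split 6:6 — most of
its ambiguous samples still carry a usable majority signal. The score ratio
between those two cases is forced to $5/9$ by the formula, which the test
suite pins down.

Edge cases, in the order they are resolved: a gene whose total interval has
zero length (every expression identical in both classes) is maximally
uninformative and scores 1; a gene with disjoint class intervals, or with no
sample inside the overlap region, scores 0. The denominator of the
middle factor is $N$ (all samples) by default; the non-outlier count
$|S_i|$ is available via `sampleDenominator = "nonoutlier"` for comparison
(it can only raise a score, since $V_i \subseteq S_i$ and $|S_i| \le N$).

## Relative dominant class

Each gene is assigned the class it serves best, *relative to class size*:
$RDC_i = \arg\max_c \frac{1}{|\tilde S_c|}\sum_{j \in \tilde S_c} m_{ij}$,
where $\tilde S_c$ is the set of class-$c$ samples. The relative form keeps
the assignment meaningful when class sizes are unbalanced. Exact ties are
distributed on both classes at random: the tied genes, in ascending POS
order (ties by index), are assigned to the two classes alternately starting
from a seeded random class. A single tied gene thus lands in a random class,
while a pool of ties is split evenly between the classes — the balanced
reading, consistent with why RDC exists at all (keeping the final panel
balanced per class). Reruns with the same seed are bit-identical.

## Minimum covering subset

The smallest gene set whose aggregate mask equals the aggregate over all
genes is approximated greedily: repeatedly take the gene with the most 1
bits in its *updated* mask (bits of already-covered samples are cleared each
round), breaking ties by lowest POS, then by lowest index. Each round covers
at least one new sample, so the loop terminates, and the recomputed counts
make the selection order non-increasing in covered-sample count. Greedy set
cover carries the classical $\ln N + 1$ approximation guarantee and is not
globally minimal in general; the test suite checks the coverage identity and
the bound against an exhaustive set-cover oracle on small random instances.
The exact exponential search is deliberately kept out of production paths.

## Final selection

The user asks for $r$ genes. The minimum subset $G^*$ comes first, in
selection order and regardless of its POS values — those genes jointly
classify the maximum coverable number of training samples. The remaining
genes are split by RDC into two groups, each sorted by ascending POS, and
interleaved round-robin starting from class 1 (the first label encountered;
the starting group is a convention, recorded in the result parameters). The
top $\nu = r - |G^*|$ of this ranking extend $G^*$. When $|G^*| \ge r$ the
whole subset is returned with a warning rather than truncated — truncation
would silently break the coverage property — and `strictR = TRUE` restores
an exact-$r$ contract for callers that need it (the resampling helpers use
it internally, where fixed-size selections are required).

## Stability

`subsampleStability()` reruns the full selection on every training portion
of a repeated stratified $k$-fold split (re-seeded per repeat) and scores
the $\lambda = \text{folds} \times \text{repeats}$ fixed-size selections
with $\sum_f c_f^2 / (\lambda^2 k)$, where $c_f$ counts the subsamples
selecting feature $f$. The score is 1 iff all selections are identical and
$1/\lambda$ iff they are pairwise disjoint. The index is adopted from the
selection-stability literature; a pairwise-Jaccard variant with the same
boundary values is available via `method = "jaccard"`.

A subtlety worth knowing: even on perfectly separable planted data the
score need not be exactly 1. With normally distributed within-class noise,
a training subsample occasionally contains a sample beyond its own class's
fence; that sample's mask bit drops to 0, the affected planted genes'
RDC proportions break their tie asymmetrically, and the round-robin can
then admit one noise gene into a small panel. This is a property of the
published procedure, not an implementation artefact; with evenly spaced
within-class values (no fence exclusions) the score is exactly 1, which the
test suite demonstrates.

## Synthetic data

`simulateExpression()` generates the structures the method reasons about,
with per-gene ground truth: *informative* genes (class means separated by
`classShift = 6` within-class standard deviations — far enough that the
core intervals are disjoint at the default 18 + 18 samples), *partial*
genes (shift calibrated so an expected `overlapFraction` of samples falls
inside the overlap region; the calibration works from the expected core
bound $\min(2.70, \Phi^{-1}\bigl(\tfrac{n - 0.375}{n + 0.25}\bigr))$ of a
standard normal class of size $n$), *scale* genes (equal means, class-2
spread inflated `scaleRatio`-fold — visible to interval analysis, invisible
to a rank-sum location test), and *noise* genes (identical class
distributions). Outliers are injected per gene: with probability
`outlierRate` one randomly chosen sample is shifted by `outlierMagnitude`
spread units (6 by default, large enough to leave any core interval). The
base distribution is standard normal per class; `heavyTails = TRUE`
substitutes a variance-matched $t_3$ to stress the fences.

What the generator does *not* emulate: gene–gene correlation, platform
noise, batch effects, intensity-dependent variance. Passing tests on this
generator show that the interval logic, scoring, covering and ranking behave
as specified — not that the method wins on any particular real dataset.

## Evaluation harness

`wilcoxonRank()` ranks genes by two-sample rank-sum p-value, the standard
univariate baseline. `benchmarkSelection()` runs repeated stratified CV,
performs each selection on the training folds only (no information from the
held-out fold reaches the selector), trains a classifier (kNN with
$k \approx \sqrt{n}$ rounded to the nearest odd number, random forest with
500 trees, or SVM with package defaults) on the selected genes and reports
mean test error per panel size; `errorLogRatio()` summarises
$\log(\text{err}_{\text{baseline}}/\text{err}_{\text{POS}})$. Classifiers
are evaluation plumbing: the package core imports none of them.

## Problem sizes used by the checks

The shipped checks run at deliberately desk-sized conditions: the score
bound is verified by exhaustively scoring all 6400 multiset pairs of class
sizes 2–6 on the grid $\{0,1,2\}$; greedy covering is compared with the
exhaustive oracle on 500 random mask matrices with $P \le 12$, $N \le 16$;
parameter recovery uses 5 planted genes among 195 noise genes at 18 + 18
samples; stability uses $10 \times 50$ subsampling on a 40-gene, 30 + 30
dataset; the benchmark uses 10 scale genes among 90 noise genes at 30 + 30
samples under $5 \times 5$ CV.

## Known limitations

* Binary classes only; the containers enforce it.
* The greedy subset is minimal in the algorithmic sense, not provably
  globally minimal.
* POS is a ranking statistic; it has no significance calibration, and no
  redundancy handling beyond what the covering step removes.
* Selection quality on real data depends on preprocessing; the package
  assumes expressions arrive normalised.
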