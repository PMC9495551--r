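---
title: "Methods: ceRNA regulatory-module discovery with cernaMod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA regulatory-module discovery with cernaMod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cernaMod` turns paired tumor/normal expression matrices of three RNA
classes (mRNA, lncRNA, miRNA) into direction-consistent miRNA–lncRNA–mRNA
regulatory modules. This vignette explains the statistical machinery, the
choices that were genuinely open, and what the synthetic validation does and
does not establish.

## Differential expression

Counts are normalized with trimmed-mean-of-M-values (TMM) factors. The TMM
computation is delegated to edgeR (reference sample by upper-quartile
proximity, 30% two-sided M-trim, 5% A-trim, delta-method precision weights,
factors rescaled to geometric mean one); the test suite checks it against an
independent from-scratch implementation of the trimmed-mean formula.
Normalized abundance is `log2(CPM + 0.5)`, where CPM uses the
factor-adjusted library size. Placing the 0.5 pseudocount on the CPM scale
(rather than on the raw count) keeps log-CPM exactly invariant to rescaling
a library — counts and library size scale together — while still mapping a
zero count to a finite floor.

Per feature, the log2 fold change is the mean tumor-minus-normal log-CPM
difference over pairs, and the p-value comes from a paired Wilcoxon
signed-rank test on those per-pair differences (normal approximation with
tie and continuity correction; features with all-zero differences get
p = 1). The statistic is pluggable: `test_differential()` accepts any
function mapping the difference matrix to p-values, because the downstream
logic consumes only (log2FC, p, FDR). A distribution-free paired test was
chosen as the default rather than re-implementing a negative-binomial exact
test; it is honest about what it is, and at the pipeline's operating point
(paired design, n = 100 pairs, planted |log2FC| = 2) its power is
effectively one, which the acceptance suite verifies.

Significance requires |log2FC| > 1 *and* BH FDR < 0.05. For mRNA and lncRNA
the whole test is repeated on 50 random subsamples of 4/5 of the *pairs*
(both members of a pair always kept together, so the paired statistic stays
valid) and only features significant in every round are *stable*; miRNA is
analyzed once. Both thresholds are applied inside each round — the
alternative (gating only the final intersection) would let a feature
hovering at the fold-change boundary pass on the strength of rounds it
failed. A master seed draws one child seed per round, so any round is
individually reproducible.

Quality control mirrors the upstream protocol: features with more than 1/3
missing samples (RNA-Seq) or more than 2 missing samples (miRNA) are
dropped, where missing means NA, not zero.

## Interaction network and MCC

Edges between stable DE mRNAs are kept when the supplied interaction
confidence is strictly greater than 700 (STRING-style 0–1000 score) and the
two genes are significantly co-expressed. Co-expression is a two-sided
Pearson test (t-distribution, n − 2 df) on log-CPM with tumor and normal
samples pooled; pooling matches the description of the cohort as one sample
set, but which sample set (or abundance scale) the original protocol used
is not stated, so this is a documented choice, not a derivation. Pairs with
zero variance are flagged non-significant (r undefined, p = 1) rather than
erroring, so screens over thousands of pairs keep running.

Hubs are ranked by Maximal Clique Centrality,
`MCC(v) = sum over maximal cliques C containing v of (|C|-1)!`, counting
cliques of size ≥ 2 — an isolated node scores 0, and a node whose maximal
cliques are all single edges scores exactly its degree, so no special
casing is needed. Maximal cliques come from igraph's Bron–Kerbosch
implementation (with pivoting) behind a node-count guard (default 5000);
the acceptance suite proves equality with exhaustive subset enumeration on
200 random graphs of up to 12 nodes.

## The classifiers

Two fully connected sigmoid-output nets are trained to separate tumor from
normal: the mRNA model (hidden 400, 100, with a normalization layer after
each hidden layer) on the network mRNAs, and the ceRNA model (hidden 400,
100, 40, no normalization layers) on the ceRNA-network nodes. The
"regularization layer" is implemented as batch normalization: the phrase it
renders describes per-feature normalization after the neuron layer, which
is exactly what batch norm does; an L2 penalty would regularize weights,
not features. The hidden activation (unstated upstream) is ReLU, the field
default for fully connected classifiers.

Training is minibatch Adam (default moments 0.9/0.999, eps 1e-8) on binary
cross-entropy, batch size 16, learning rate 1e-4, stratified 70/30
train/validation splits repeated 50 times with fresh seeds. The protocol's
epoch count is ≥ 1000; the package defaults to 200 epochs, which at these
problem sizes reaches the same training plateau at a fifth of the cost —
pass `epochs = 1000` to honor the original. The inner loop is compiled
(RcppArmadillo) with all randomness (weight initialization, shuffling,
splits) generated on the R side, so training is bit-deterministic under a
fixed seed on a given BLAS. A trailing minibatch of size 1 is dropped — it
carries no batch statistics. Per-epoch accuracy/loss curves are recorded
for the designated model; the other 49 repeats contribute final metrics
only.

The 50 repeats estimate the accuracy distribution, but attribution needs
one model; the package designates the first repeat's model (an option to
average contribution tables over repeats was considered and rejected as
conflating models with different active features). Model evaluation uses
ROC/AUC by trapezoid over all score cut-offs, equal to the normalized
Mann–Whitney U statistic; the comparison panel (KNN k = 5, RBF SVM,
decision tree, naive Bayes, logistic regression, random forest) runs at
library defaults under the same split.

## Attribution scores

Per-sample feature attributions are computed by backpropagating
difference-from-reference multipliers (the rescale rule) through the
trained net against each reference in a background set, then averaging over
the background. Inference-mode batch norm is affine and is folded into the
adjacent linear layer, so every layer is either exactly linear or an
elementwise nonlinearity with multiplier Δout/Δin (the derivative in the
Δin → 0 limit). Two consequences matter:

* **Local accuracy is exact**: attributions sum to
  `f(x) − mean over background of f(ref)` to machine precision, for every
  sample. The test suite asserts this at 1e-3 but the error observed is at
  floating-point level.
* **Agreement with exact Shapley values is regime-dependent.** For a
  network whose ReLUs do not switch between the sample and the reference,
  the rescale attribution *equals* the interventional Shapley value (both
  reduce to the linear closed form `w_i (x_i − mean background_i)`). At a
  heavily kinked ReLU the two provably diverge — e.g.
  `f = sigmoid(relu(x1 + x2))` at `x = (1, −1)` against reference (0, 0)
  has rescale attributions (0, 0) but Shapley (±0.115). The oracle test
  therefore compares against exhaustive Shapley enumeration (2^n
  coalitions, absent features imputed by background means, n ≤ 12) on a
  seeded 8-feature network operating mostly in its active regime, where
  agreement within 5% is the designed behavior.

Attributions explain the probability output (the scale the model is
evaluated on); the logit scale would be equally defensible. The background
is up to 100 training samples drawn under a fixed seed — large enough for a
stable expectation, small enough to keep the cost linear. A feature's
*contribution score* is the arithmetic mean over samples of its absolute
attribution. Pruning removes features whose score is exactly zero after
rounding at 1e-12 — the intent is removing features the model provably
ignores (zero weights, or constant features identical to every reference),
not small-but-informative ones — then rebuilds the input layer and
retrains.

## Screening and modules

Candidate mRNAs satisfy MCC > 8 and contribution score > 1e-4, both strict
inequalities as published. Triplets are enumerated over the
validated-target tables only (a correlated pair missing from the tables is
never considered), with miRNAs and lncRNAs restricted to stable significant
DE features and mRNAs to the candidate set, and kept when r(miRNA, mRNA) <
0, r(miRNA, lncRNA) < 0, r(mRNA, lncRNA) > 0 with all three two-sided
p-values below 0.05. The sign-plus-two-sided-p reading resolves an
ambiguous "Z-score > 0" phrasing in the source protocol; a one-sided test
would halve the p-values but also hard-code the direction into the
statistic, and the explicit sign gate keeps the constraint visible.

The ceRNA network joins triplet pairings with interaction edges among
included mRNAs; the second classifier and its contribution scores select
potential ceRNAs (score > 1e-4, same scale and cut as the mRNA model since
both explain probability outputs); and each miRNA's validated targets in
the resulting subnetwork are partitioned by DE direction. Every group with
at least one mRNA becomes a module. When both direction groups are
non-empty the package emits both and marks the larger as primary, because
the module rule as stated does not license discarding the minority group.
The miRNA's own direction is deliberately unconstrained relative to its
members (negative regulation makes the opposite direction typical, and the
planted modules follow that pattern, but the rule does not require it).
Modules without a lncRNA are kept but flagged, mirroring the expectation
that a ceRNA module contains one.

## The synthetic study and what it shows

`sim_config()` defaults define the study conditions: 100 tumor/normal
pairs; 600 mRNAs, 150 lncRNAs, 80 miRNAs with 100/60/30 planted DE features
at |log2FC| = 2; negative-binomial counts (dispersion 0.1) around
log-uniform baselines (50–500 mean counts); lognormal library sizes (about
±30%, making TMM non-trivial) and a mild per-patient effect shared within a
pair; 10 planted modules of one miRNA, one lncRNA and five mRNAs each (50
triplets). Each module has a standard-normal per-sample latent factor added
to member log-means with coefficient `sd_noise * sqrt(rho / (1 - rho))`
(sign +1 for mRNA/lncRNA, −1 for the miRNA), which yields pairwise
correlations near the target strength rho = 0.7 after counting noise; 0.7
is a free choice of "clearly coupled but noisy", as the source protocol
reports no correlation magnitudes. The interaction graph plants a clique
among each module's mRNAs (confidence 750–999) over an Erdős–Rényi
background (p = 0.01, confidences 150–1000); target tables contain the
planted pairs plus 200 decoy pairs per table.

Choices a reader should know about:

* One lncRNA per module matches the shape of the modules the source study
  reports and makes the planted triplet list closed under the screen's
  combinatorial enumeration — with several lncRNAs per module every
  (mRNA, lncRNA) cross-pairing would be a genuine ceRNA triplet too.
* Decoy target pairs connect features *without planted disease signal*.
  Decoys among DE features would be confounded in pooled correlations:
  any two features shifted in the same direction correlate across a pooled
  tumor/normal cohort regardless of regulation. Real validated-target
  tables contain such confounded pairs, so measured precision reflects the
  sign/significance machinery, not robustness to that confounding — a
  stated limitation, not an oversight.
* The generator does not simulate reads, isoforms, batch effects,
  covariates, or the RPM→RPKM conversion; feature lengths are implicitly
  constant, so FPKM would be proportional to CPM and the pipeline uses TMM
  log-CPM as its normalized abundance throughout.

Passing the recovery tests therefore shows the pipeline's stages compose
correctly and recover structure of the planted kind at realistic noise; it
does not certify performance on real cohorts, where effect sizes are
heterogeneous, correlations confounded, and target annotations incomplete.

## Numerical details and degenerate inputs

* BH adjustment, Pearson tests, AUC and the clique/MCC machinery are each
  validated against independent brute-force oracles in the test suite.
* Batch-norm epsilon 1e-5; attribution multiplier fallback to the
  derivative when |Δz| < 1e-7; He-uniform weight initialization.
* All-zero samples are rejected by name in TMM; single-class labels are
  rejected before training or ROC; an empty candidate set or subnetwork
  warns rather than errors; the clique guard errors above 5000 nodes
  unless raised.
* Determinism: every stochastic step (generator, subsampling, splits,
  initialization, shuffling, background draws, baselines) restores the
  caller's RNG state and derives from explicit seeds; a pipeline rerun
  with the same config writes byte-identical outputs (manifest timing
  aside) in single-threaded execution.

## Problem sizes in the test and acceptance suites

Unit tests run on deliberately tiny fixtures (tens of features, 8–20
pairs, 12-node graphs). The acceptance suite runs the study conditions in
full — 100 pairs, the complete stability-selection protocol, the published
architectures with 200 epochs and 50 split repeats, 1000 null features for
calibration — sizes chosen so the whole suite completes comfortably on a
single CPU while exercising the pipeline at the scale its defaults define.
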