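# cernaMod

Discovery of miRNA–lncRNA–mRNA regulatory modules from paired tumor/normal
expression profiles.

## The problem

Competing endogenous RNAs (ceRNAs) are mRNAs and long non-coding RNAs that
regulate each other by competing for shared microRNA binding: when a lncRNA
sponges a miRNA, the miRNA's mRNA targets are de-repressed. Operationally, a
ceRNA triplet is an (mRNA, miRNA, lncRNA) trio in which the miRNA is
negatively correlated with both partners, the partners are positively
correlated with each other, and both pairings are experimentally validated
miRNA–target relationships. A *regulatory module* is one miRNA together with
its regulated mRNAs and lncRNAs sharing one up/down expression direction —
a compact, interpretable candidate mechanism for the disease under study.

`cernaMod` implements an end-to-end pipeline that extracts such modules from
paired case/control expression matrices of three RNA classes, for
bioinformaticians who want to run, extend, or stress-test this class of
analysis. Because the real cohorts this style of analysis is built on are
controlled-access, the package ships a seeded synthetic-data generator with
planted ground truth, so every stage — and the pipeline as a whole — is
validated by recovery experiments rather than by eyeballing.

## The pipeline

1. **Differential expression with stability selection.** TMM normalization
   (trimmed mean of M-values), per-feature log2 fold change on log-CPM, a
   paired Wilcoxon signed-rank test, BH-FDR. Significance requires
   |log2FC| > 1 and FDR < 0.05. For mRNA/lncRNA the analysis is repeated on
   50 random subsamples of 4/5 of the pairs and only features significant in
   *every* round are kept; miRNA is analyzed in a single pass.
2. **Interaction network.** Edges between stable DE mRNAs survive when the
   interaction confidence exceeds 700 (STRING-style 0–1000 score) and the
   genes are significantly co-expressed (Pearson p < 0.05). Hubs are scored
   by Maximal Clique Centrality, MCC(v) = Σ over maximal cliques C ∋ v of
   (|C|−1)!.
3. **Neural classifier + attribution.** A fully connected net (hidden
   layers 400 and 100, batch normalization after each, sigmoid output)
   separates tumor from normal on the network mRNAs' log-CPM; training uses
   Adam (lr 1e-4), binary cross-entropy, batch size 16, stratified 70/30
   splits repeated 50 times. Per-feature contribution scores are
   Shapley-style additive attributions (backpropagated
   difference-from-reference multipliers averaged over a background set),
   summarized as the mean |attribution| per feature. Zero-contribution
   features are pruned and the model relearned.
4. **Candidate and triplet screening.** Candidate mRNAs have MCC > 8 *and*
   contribution > 1e-4. Triplets over the validated-target tables are kept
   under the ceRNA sign/significance pattern above.
5. **ceRNA classifier, potential ceRNAs, modules.** A second net (hidden
   400/100/40, no normalization layers) is trained on the ceRNA-network
   nodes; RNAs with contribution > 1e-4 form the potential-ceRNA
   subnetwork, and each miRNA's same-direction targets become a module.
   Modules are benchmarked against six conventional classifiers (KNN, SVM,
   decision tree, naive Bayes, logistic regression, random forest) by AUC.

## Worked example

```r
library(cernaMod)
bundle <- run_pipeline(pipeline_config(seed = 42L))
bundle$manifest[c("n_stable_de", "n_network_nodes", "n_candidates",
                  "n_triplets", "n_potential_cernas", "n_modules")]
#> $n_stable_de        190
#> $n_network_nodes     59
#> $n_candidates        50
#> $n_triplets          50
#> $n_potential_cernas  70
#> $n_modules           10

triplet_recovery(bundle$triplets, bundle$dataset$truth)[c("recall", "precision")]
#> $recall    1
#> $precision 1

bundle$modules[[2]][c("mirna_id", "direction", "mrna_ids", "lncrna_ids")]
#> $mirna_id  "MIR0001"
#> $direction "up"
#> $mrna_ids  "MR0001" "MR0002" "MR0003" "MR0004" "MR0005"
#> $lncrna_ids "LNC0001"
```

Under the default study conditions (100 tumor/normal pairs, 50 planted
triplets at correlation strength 0.7, planted |log2FC| = 2) the pipeline
recovers all 10 planted modules exactly (member Jaccard 1.0), the ceRNA
classifier reaches validation accuracy 1.0, and every classifier reaches
AUC ≥ 0.91 on the module members (six of the seven reach 1.0; the decision
tree's coarse scores give 0.92). The run takes roughly ten minutes on one
CPU; outputs (DE table, networks, contribution tables, triplets,
`modules.json`, classifier AUCs, manifest) are written when `outdir` is
given.

The same workflow is laid out as numbered scripts under `analysis/`
(`01_simulate.R` … `06_benchmark_classifiers.R`), each a thin driver over
the package functions that prints what it found and writes its tables under
`results/`.

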