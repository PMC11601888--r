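# funlnc

Most long noncoding RNAs (lncRNAs) have no known function, and experimental
screens cover only a sliver of the >10 000 annotated loci in any one cell
type. `funlnc` predicts which lncRNAs are *functional* in a specific
cellular context (e.g. human embryonic stem cells, or a cancer) from the
regulatory company they keep: it assembles an upstream/downstream
multi-omic network around every lncRNA, summarizes it into a 57-column
feature matrix, trains a random-forest classifier on a curated
positive/negative set, and prioritizes high-confidence functional lncRNAs
with an empirical permutation score.

## Model

**Network.** Upstream edges connect a lncRNA promoter (TSS ± 2 kb by
default) to TF ChIP-seq peaks, TF motif hits, histone-mark peaks,
methylation sites and SNPs by direct overlap (half-open BED semantics), and
to typical enhancers (TE), super-enhancers (SE) and chromatin-accessibility
regions either by distance (midpoint within 50 kb of the TSS) or through 3D
chromatin interaction anchor pairs (BEDPE). Downstream edges come from
curated lncRNA–mRNA / miRNA / protein pair tables. Every edge records its
assignment manner and biosample.

**Features.** Three categories, 57 columns: C1 upstream proximal (8 — e.g.
the distinct-TF count `TF_num,j = Σ_n TF_{n,j}` with `TF_{n,j} ∈ {0,1}`,
core pluripotency TF count over {SOX2, MYC, NANOG, OCT4}, activating
histone-mark types, methylation count/normalized signal, risk/common SNP
counts); C2 upstream distal (46 — per-manner counts, signal sums/maxima and
normalized ranks of SE/TE/accessibility elements, plus the total 3D contact
frequency); C3 downstream (3 — distinct mRNA, miRNA, protein partners).

**Classifier.** A random forest (500 CART trees, Gini splitting, mtry tuned
by stratified 10-fold CV maximizing AUROC) on standardized,
correlation-screened predictors, trained on an 80/20 split that is either
stratified-random or group-aware (single-linkage clusters of k-mer Jaccard
sequence similarity never straddle train and test).

**Permutation score.** For each lncRNA with observed probability `p_i`, the
model is re-applied to `B = 1000` column-permuted feature matrices giving
`r_i,1..B`; the score is

    Score(lnc i) = -log10( #{k : p_i < r_i,k} / B )

and predicted-functional lncRNAs with score > 2 are called high-confidence
(HCFun_lncs). A `safe` estimator `-log10((c+1)/(B+1))` (the default) keeps
the score finite when no permutation beats the observation.

## Worked example

A three-lncRNA toy network whose every feature value can be checked by
hand:

```r
library(funlnc)
ex <- worked_micro_example()
M <- build_feature_matrix(ex$network)
M["lncA", c("tf_chip_count", "tf_chip_core_count",
            "histone_act_type_count", "se_d_count",
            "interaction_frequency")]
#>          tf_chip_count     tf_chip_core_count histone_act_type_count
#>                      2                      2                      2
#>             se_d_count  interaction_frequency
#>                      1                      3
```

lncA's promoter holds SOX2 and NANOG peaks (2 distinct TFs, both core),
H3K27ac + H3K4me3 (2 activating mark types), one super-enhancer 40 kb away,
and one anchor pair of contact frequency 3; lncC has no regulators and gets
an all-zero row.

End to end on the package's simulated world (200 lncRNAs, 60% functional,
TF/histone/TE rates 8 vs 2 peaks per promoter):

```r
b   <- simulate_dataset(sim_config(seed = 1), "sim")
net <- build_network_bundle(b)
M   <- build_feature_matrix(net)
lab <- read_labels(b)
sp  <- split_random(lab, 0.8, seed = 1)
model <- fit_classifier(M, sp$train, cv_folds = 10, seed = 1)
evaluate_predictions(predict_and_label(model, M), sp$test)
#> AUROC 1.000  AUPRC 1.000  precision 1.000  recall 1.000  (n = 40)

scored <- random_permutation_score(model, M, B = 1000, seed = 1)
sum(scored$hc_flag)
#> [1] 109   # HCFun_lncs among 120 predicted Fun_lncs
```

The held-out AUROC/AUPRC here mirror, at desk scale, the ~0.95/0.97 range
reported for this kind of model on real hESC data; the permutation score
then narrows 120 predicted functional lncRNAs to 109 high-confidence calls.

The same stages are scriptable:

```sh
funlnc simulate --n 200 --seed 1 --out sim/
funlnc run --bundle sim/ --seed 1 --B 1000 --out run/
```

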