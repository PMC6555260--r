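# pathDTI

Ranking candidate drug-target interactions (DTIs) from a heterogeneous
network of drug similarities, target similarities and known interactions.
The package is aimed at computational biologists who have precomputed
drug-drug chemical similarities (e.g. Tanimoto on structures) and
target-target sequence similarities (e.g. normalised Smith-Waterman) plus
a list of confirmed interactions, and want a ranked list of unobserved
pairs to prioritise for experimental validation — a setting with severe
class imbalance, since known interactions are vastly outnumbered by
unknown pairs.

## Method

Three stages, all implemented and tested in this package:

1. **Similarity diffusion.** Each similarity network is diffused by a
   random walk with restart,
   `W^{t+1} = (1 - a) N W^t + a I`, where `N` is the row-normalised
   transition matrix (self-similarity excluded) and `a` the restart
   probability, iterated until `||W^{t+1} - W^t||_1 < 1e-6`. The converged
   walk probabilities are topology-aware similarities; each node keeps its
   `k` most similar neighbours.
2. **Path-category features.** Every pair `(d_i, t_j)` is summarised by
   the simple paths of length 2-3 edges connecting it, grouped into six
   node-type categories (D-D-T, D-T-T, D-T-T-T, D-D-T-T, D-D-D-T,
   D-T-D-T), with intermediate nodes restricted to the endpoints'
   neighbour sets. A path's weight is the product of its edge weights
   (DTI edges count 1). Per category the path set yields its weight sum
   (V1), maximum (V2) and count (V3) — an 18-dimensional feature vector.
3. **Gradient-boosted ranking.** A stage-wise ensemble of depth-capped
   regression trees is fitted to the logistic loss
   `sum(log(1 + exp(-2 y F)))` with Newton leaf values damped by an L2
   penalty, random feature subsets per round and constant shrinkage.
   Scores `F0 + (1/z) * sum_k lambda_k T_k(x_k)` rank all unknown pairs.

Evaluation follows stratified five-fold cross-validation with test
interactions masked before feature construction, reporting ROC-AUC,
step-rule PR-AUC and per-drug top-k recall. See the methods vignette
(`vignettes/path-category-dti.Rmd`) for assumptions, parameter defaults
and numerical conventions.

## Worked example

The package ships a small worked micro-network (7 drugs, 5 targets)
whose edge weights make the feature construction easy to follow by hand:

```r
library(pathDTI)
fx <- workedExampleFixture()
net <- fx$network
KD <- selectKNeighbors(drugSimilarity(net), fx$k)
KT <- selectKNeighbors(targetSimilarity(net), numTargets(net) - 1)
buildPairFeatures(
    net, drugSimilarity(net), targetSimilarity(net), KD, KT, "d7", "t3"
)
#> v1_c1 v1_c2 v1_c3 v1_c4 v1_c5 v1_c6 v2_c1 v2_c2 v2_c3 v2_c4 v2_c5 v2_c6 v3_c1
#>  0.16  0.16  0.08  0.08  0.02  1.00  0.16  0.16  0.05  0.05  0.02  1.00  1.00
#> v3_c2 v3_c3 v3_c4 v3_c5 v3_c6
#>  1.00  2.00  2.00  1.00  1.00
```

Reading the C3 block (third position of each group): pair (d7, t3) is
connected by exactly two D-T-T-T paths, `d7-t5-t2-t3` (weight
0.1 x 0.3 = 0.03) and `d7-t5-t4-t3` (weight 0.1 x 0.5 = 0.05), so V1 is
their sum 0.08, V2 their maximum 0.05 and V3 their count 2. The single
D-D-D-T path `d7-d3-d2-t3` gives the C5 triple (0.02, 0.02, 1).

End to end on a generated planted-signal network (4 matched clusters of
drugs and targets, 40 x 40 nodes):

```r
gen <- generateNetwork(syntheticSpec(seed = 1))
report <- runCrossValidation(
    gen$network,
    config = gbdtConfig(
        nTrees = 200, maxDepth = 1, featureFraction = 1,
        minSamplesLeaf = 80, seed = 7
    ),
    restart = 0.2, k = 9, seed = 1, ks = c(10, 20, 40)
)
print(report)
#> Five-fold cross-validation report
#>   pooled ROC-AUC 0.8292, AUPR 0.3029
#>   per fold:
#>     fold 1: AUC 0.8721, AUPR 0.3798
#>     fold 2: AUC 0.8601, AUPR 0.3559
#>     fold 3: AUC 0.8182, AUPR 0.3885
#>     fold 4: AUC 0.8307, AUPR 0.2271
#>     fold 5: AUC 0.8057, AUPR 0.3037
#>   top-k recall (mean over drugs):
#>     k = 10: 0.9966
#>     k = 20: 1.0000
#>     k = 40: 1.0000
```

The pooled ROC-AUC of 0.83 sits close to the information ceiling of this
benchmark (about 0.82 in expectation — within matched cluster blocks the
labels are pure noise), and the AUPR of 0.30 is well above the 0.09
positive prevalence; on a label-permuted copy of the same network the
pipeline scores near 0.5, as it should.

## Command line

```sh
exec/pathdti simulate --output-dir sim --seed 1
exec/pathdti cv --drug-sim sim/drug_sim.tsv --target-sim sim/target_sim.tsv \
    --interactions sim/interactions.tsv --output-dir cv_out --k 9 --a 0.2
exec/pathdti predict --drug-sim sim/drug_sim.tsv --target-sim sim/target_sim.tsv \
    --interactions sim/interactions.tsv --output sim/candidates.tsv
```

Inputs are labelled TSV matrices plus a two-column interaction edge
list; every run writes a log of the fully resolved configuration.

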