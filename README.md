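# midnet

Predicting miRNA–disease associations by fusing **network behavior**
and **node attribute** information.

Most computational miRNA–disease predictors use only the known
association matrix itself. `midnet` takes a different route: it builds
a heterogeneous miRNA–protein–disease network from miRNA–protein and
protein–disease association catalogues — deliberately containing *no*
direct miRNA–disease edge, so features cannot leak labels — and
represents every miRNA and disease by

* **behavior features**: GraRep embeddings of the network. With
  transition matrix `A = D⁻¹S`, each step `k = 1..K` forms the
  log-shifted, column-normalised positive matrix
  `Xᵏ = max(0, log(Aᵏᵢⱼ/Γⱼ) − log β)` and factorises it by truncated
  SVD, `Wᵏ = U_d Σ_d^{1/2}`; the global representation is
  `W = [W¹ | … | Wᴷ]`;
* **attribute features**: the 64-dimensional 3-mer composition of the
  miRNA sequence, and the disease's semantic-similarity profile from
  MeSH-style ontology DAGs with decay contributions
  `C_C(d) = Δ · max{C_C(d′) : d′ child of d}` and
  `SS(A,B) = Σ_{d∈D(A)∩D(B)} (C_A(d)+C_B(d)) / (C(A)+C(B))`.

A labeled pair is the 128-dimensional concatenation
`[miRNA behavior | miRNA attribute | disease behavior | disease
attribute]` (32 + 32 per node by default). A 100-tree random forest is
trained on known positives plus 1:1 uniformly sampled negatives and
evaluated under stratified 5-fold cross-validation (Acc, Sen, Spec,
Prec, MCC, AUC, AUPR); candidate miRNAs are ranked per disease by the
forest's positive-class vote fraction.

A first-class synthetic-world generator (`generateWorld()`) plants a
group structure that links miRNA and disease groups through shared
protein hubs, with a `signal` knob from 0 (nothing learnable) to 1
(fully determined), so the entire pipeline is testable without any
external download.

## Worked example

```r
library(midnet)

w <- generateWorld(signal = 1, seed = 1)   # 60 miRNA / 120 protein / 40 disease
w
#> SyntheticWorld: signal = 1 , seed = 1
#>   network: 220 nodes / 2012 edges; 491 positive pairs; 4 groups

report <- runPipeline(w, seed = 1)         # embed + attributes + RF + 5-fold CV
report
#> CVReport (random_forest, 5 folds)
#>   acc   0.9633 +/- 0.0127
#>   sen   0.9796 +/- 0.0162
#>   spec  0.9471 +/- 0.0151
#>   prec  0.9488 +/- 0.0143
#>   mcc   0.9273 +/- 0.0256
#>   auc   0.9840 +/- 0.0094
#>   aupr  0.9792 +/- 0.0135
```

With the planted signal at full strength, the fused features recover
the group structure almost perfectly (mean AUC 0.984 over five folds);
at `signal = 0` the same pipeline sits at chance (AUC ≈ 0.5), and AUC
rises monotonically with the signal.

Ranking candidates for one disease:

```r
f <- pipelineFeatures(w)
ds <- buildTrainingSet(w@positives, nodeIds(w@network, "miRNA"),
                       nodeIds(w@network, "disease"),
                       f$embedding, f$attributes, seed = 1)
model <- fitModel(ds, seed = 1)
ranked <- rankCandidates(model, "dis-001", embedding = f$embedding,
                         attributes = f$attributes)
head(ranked, 5)
#>    rank   mirna disease score
#> 23    1 mir-029 dis-001  0.85
#> 43    2 mir-053 dis-001  0.78
#> 30    3 mir-037 dis-001  0.74
#> 13    4 mir-017 dis-001  0.34
#> 1     5 mir-002 dis-001  0.32
```

The score is the fraction of trees voting "associated"; known training
positives for the query disease are excluded, so the list surfaces
novel candidates. `confirmTopN(ranked, 50, list(db = ids))` annotates
a top-50 list against any evidence sets you supply.

A thin command-line front-end over the same functions lives at
`inst/scripts/midnet-cli.R` (subcommands `simulate`, `network`,
`embed`, `semsim`, `seqfeat`, `featurize`, `evaluate`, `predict`).

See `vignettes/midnet-methods.Rmd` for the model, its assumptions,
parameter defaults and the generator's design.

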