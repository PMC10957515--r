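# ngnnDTI

Drug–target interaction (DTI) prediction from molecular graphs, for
computational chemists and method developers who want a fully
inspectable, CPU-trainable implementation of a nested-GNN DTI
architecture — including its data pipeline, cold-start evaluation
protocol and interpretability exports — with no GPU, downloads or
external weights required.

## The model

Both molecules are graphs. A drug SMILES becomes a heavy-atom graph
with 78-dim atom features (element / degree / H-count one-hots +
aromaticity); a protein structure becomes a residue graph whose edges
are Cα–Cα contacts below 8 Å (plus the peptide backbone), with 54-dim
residue features (one-hot, position-probability-matrix column,
class flags, physicochemical descriptors).

The encoder is a *nested* GNN: after GCN base layers
`H' = σ(D^(-1/2)(A+I)D^(-1/2) H W)` interleaved with a virtual node
`v' = σ(v W₀ + (Σᵢ Hᵢ) W₁)` (added back to every node), each node is
replaced by the sum of its k-hop subgraph,
`h_u = Σ_{j : d(u,j) ≤ k} h_j`, so node embeddings represent
neighbourhood substructures. The two graphs exchange information
through a cross attention-free transformer (cross-AFT); per query
position n and dimension i,

    Y[n,i] = σ(Q[n,i]) · Σ_{n'} exp(K[n',i] + w[n,n']) V[n',i]
                         / Σ_{n'} exp(K[n',i] + w[n,n'])  + H_q[n,i]

with queries from one molecule, keys/values from the other and a
learned pairwise bias `w`. The same algebra yields an implicit
attention tensor `a[n,n',i]` used for per-dimension atom/residue
saliency. Pooled interaction outputs are fused with (stub or real)
pretrained sequence embeddings into a 128-D space per branch and
classified by an MLP + sigmoid. Everything — forward, hand-derived
backprop, Adam — is implemented in base R matrix algebra and verified
against loop oracles and numerical gradients.

## Worked example

Train a small model on the planted-rule synthetic benchmark (drugs
interact with targets iff the drug carries a CF₃ tail *and* the target
contains the WHW motif):

```r
library(ngnnDTI)

g <- smilesToGraph("c1ccccc1C(F)(F)F")
g
#> MolecularGraph (drug): 10 nodes, 10 undirected edges, 78 features/node
#>   labels: C C C C C C C F F F

ds <- generateSyntheticDtiset(nDrugs = 10, nTargets = 8, seed = 7)
cfg <- modelConfig(
  encoder = encoderConfig(kHops = 2, nLayers = 1, hiddenDim = 8),
  maxDrugLen = 64, maxProtLen = 64, mlpHidden = 16, dropout = 0
)
inputs <- prepareModelInputs(ds, cfg)   # featurize entities once
sp <- splitSamples(ds$samples, splitSpec("random", seed = 1))  # 7:1:2
fit <- trainModel(sp$train, sp$val, inputs, cfg,
                  runConfig(epochs = 15, patience = 15, seed = 1))
ev <- evaluateModel(fit$params, cfg, sp$test, inputs)
sprintf("test AUROC %.3f  AUPRC %.3f  sens %.3f  spec %.3f",
        ev$auroc, ev$auprc, ev$sensitivity, ev$specificity)
#> "test AUROC 0.921  AUPRC 0.928  sens 0.889  spec 0.857"
```

AUROC/AUPRC are threshold-free ranking metrics (1 = perfect, 0.5 =
chance); sensitivity and specificity are the true-positive and
true-negative rates at threshold 0.5. An 80-sample toy run already
ranks held-out pairs far above chance; the 500-sample default reaches
AUROC ≥ 0.95 (see below). Cold-start splits
(`splitSpec("unseen_drug")`), affinity binarization
(`kdToPkd`, `binarizeDavis`, `binarizeKiba`), negative sampling
(`sampleBiosnapNegatives`) and implicit-attention exports
(`dtiForward(..., withAttention = TRUE)`, `topWeightPositions`,
`exportProteinAnnotation`) are documented on their help pages. A thin
command-line front end covering
featurize/simulate/split/train/evaluate/interpret lives at
`inst/scripts/ingnn.R`.

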