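Package: ngnnDTI
Title: Nested Graph Neural Networks with Cross Attention-Free
    Transformers for Drug-Target Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts binary drug-target interactions from molecular
    graphs. Drugs are parsed from SMILES into atom-featurized graphs;
    protein targets are turned into residue graphs via Calpha contact
    maps computed from 3D structures, with position-probability-matrix
    and physicochemical residue features. Both graphs are encoded by a
    nested graph neural network (k-hop subgraph pooling over a GCN base
    layer with a virtual node), exchanged through a cross
    attention-free transformer interaction module, fused with
    pretrained sequence embeddings, and classified by an MLP head. The
    package includes the full data pipeline (affinity binarization,
    cold-start splits, negative sampling, a planted-rule synthetic
    generator), CPU training and evaluation, and implicit-attention
    interpretability exports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    bio3d,
    igraph,
    pROC,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
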