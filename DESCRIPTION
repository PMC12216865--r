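Package: morphoTx
Title: Cross-Modality Representation Learning for Cell Painting and
    Transcriptomics Compound Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Learns compound embeddings from paired Cell Painting (CP)
    morphological profiles and transcriptomics (TX) expression profiles, so
    that new compounds screened only by Cell Painting inherit signal from the
    transcriptomic modality. Implements CLIP-style contrastive (InfoNCE)
    pretraining of a CP and a TX encoder, and a bimodal masked autoencoder
    that reconstructs both modalities from CP alone; both yield CP-only
    embeddings. Ships the full evaluation battery used to benchmark feature
    types: Murcko-scaffold-grouped 70/10/20 splits, k-nearest-neighbour
    cluster quality for replicate and mechanism-of-action clustering, t-SNE
    visualisation, multitask bioactivity classification scored by AUROC and
    baseline-corrected (RIPtoP) AUPRC, and paired Wilcoxon signed-rank
    comparisons grouped by protein target family. A linear-Gaussian
    synthetic-screen generator with known latent structure makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, grDevices, graphics, data.table, S4Vectors
Suggests: testthat (>= 3.0.0), jsonlite, withr
biocViews: Software, Cheminformatics, Transcriptomics, Classification,
    Clustering, DimensionReduction
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
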