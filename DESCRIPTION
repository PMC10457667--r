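Package: nclt
Title: Neighborhood-Contrastive Label Transfer from scRNA-seq to scATAC-seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Semi-supervised cross-modal annotation of scATAC-seq cells from
    labeled scRNA-seq references. Cells from both modalities are embedded by
    a shared encoder trained with four losses: a projection regularizer that
    promotes variable, orthogonal, zero-mean embedding dimensions; a feature
    alignment loss over best-matched cross-modal cell pairs; cross-entropy
    on the labeled reference; and a neighborhood-contrastive loss that
    preserves each target cell's k-nearest-neighbor structure computed on a
    low-dimensional representation of the raw chromatin-accessibility
    features. Includes confidence-based novel-cell-type detection, open-set
    evaluation metrics (accuracy, per-type F1, AUROC, OSCR), a synthetic
    two-modality benchmark generator with known ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
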