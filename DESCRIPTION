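Package: surftask
Title: Surface-Based Prediction of Individual Task fMRI Contrast Maps from
    Resting-State Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts individual task fMRI contrast maps on the cortical
    surface from resting-state vertex-to-ROI functional connectomes. Provides
    an icosphere mesh hierarchy with one-ring topology and pooling maps, a
    spherical convolutional network (parameterized differential operator
    kernels in a U-Net with skip connections) trained with a
    reconstructive-contrastive margin loss and a two-phase schedule, an
    ensembled parcel-wise linear-regression baseline, group-average and
    repeat-scan references, thresholded Dice / Dice-AUC / whole-brain R^2 /
    subject-identification evaluation, transfer-learning modes (head
    replacement, backbone-only finetuning with channel masking), GIFTI and
    CIFTI-2 surface I/O, and a seeded synthetic cohort generator with known
    ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    xml2,
    jsonlite,
    pracma,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'baselines.R'
    'cifti.R'
    'cli-helpers.R'
    'connectome.R'
    'diffops.R'
    'experiment.R'
    'gifti.R'
    'icomesh.R'
    'metrics.R'
    'model.R'
    'surface-io.R'
    'synthcohort.R'
    'train.R'
    'utils.R'
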