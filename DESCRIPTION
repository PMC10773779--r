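Package: strokefuse
Title: Multimodal Prognosis Scoring for Acute Ischemic Stroke from MRI and Clinical Metadata
Version: 0.1.0
Authors@R: person("strokefuse", "developers", email = "strokefuse@example.org", role = c("aut", "cre"))
Description: A cross-modal attention network for binary good/poor prognosis
    classification of acute ischemic stroke patients from 2-D brain MRI slices
    and 19 tabular clinical fields. Implements a multi-scale global-local
    attention image branch over a VGG16-style backbone, an MLP metadata
    encoder, sigmoid cross-modal attention gating of the fused feature,
    cross-validated evaluation metrics with an ablation harness, Grad-CAM
    saliency with a lesion-localization score, and a seeded synthetic
    lesion-image + metadata cohort generator for end-to-end testing. The
    neural-network engine (dense, batch/layer normalisation, multi-head
    self-attention, convolution, Adam, hand-written backward passes) is
    implemented in base R.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
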