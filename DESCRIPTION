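Package: negbold
Title: Multimodal Analysis of Negative BOLD Responses Under Cortical Disinhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how mild pharmacological disinhibition of the
    cerebral cortex (low-dose GABA-A antagonism) alters the coupling between
    neuronal activity and hemodynamics. Implements block-design BOLD fMRI trial
    averaging with unsupervised support-vector-machine activation mapping and
    response metrics (percent signal change, full width at half maximum),
    gradient-artifact removal from raw extracellular recordings by
    one-dimensional mathematical morphology, spike detection and two-feature
    unit sorting with interneuron classification, resting-state firing-rate
    change distributions with chi-squared comparisons, peri-event histograms
    and evoked-response statistics, and tissue-oxygen (PO2) trace
    quantification. A synthetic-data module generates all three modalities
    (BOLD trial volumes, raw 32 kHz extracellular traces, 20 Hz PO2 traces)
    with known ground truth so that every stage is verifiable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    cluster,
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
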