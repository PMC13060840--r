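Package: saxsfold
Title: SAXS-Guided Protein Structure Modelling Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes pair distance distribution functions P(r), Debye
    scattering intensities I(q), radii of gyration and Dmax from atomic
    coordinates; provides a differentiable (soft-histogram) P(r) with exact
    analytic gradients, an L1 SAXS loss, a weighted composite training loss
    and a chi-squared profile fit; implements SAXS-conditioned cross-attention
    updates for MSA and pair representations, an inference-time adapter
    optimization loop that generates SAXS-consistent conformational
    ensembles, dataset curation utilities (NMR model splitting, length and
    sequence-similarity filtering, random cropping, apo-holo target
    selection), structural evaluation metrics (Kabsch RMSD, accuracy tiers,
    ensemble diversity), and deterministic synthetic structure generators for
    testing the full pipeline without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
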