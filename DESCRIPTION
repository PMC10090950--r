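Package: trailr
Title: Turnover and Replication Analysis by Isotope Labeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Joint analysis of stable-isotope (15N) metabolic labeling time
    courses in mammalian tissues. Estimates per-protein turnover rate
    constants (kt) from the decay of unlabeled TMT reporter signal, cell
    division rates (kdiv) from 15N isotopologue spectra of genomic-DNA mono-
    and dinucleotides (with natural-abundance deconvolution and correction
    for nucleotide recycling), and cell-cycle-corrected degradation rates
    (kdeg = kt - kdiv). Includes cross-tissue and intracomplex dispersion
    statistics with randomized nulls, protein sequence feature analysis
    (hydropathy, isoelectric point, residue-class composition, disordered
    regions), ground-truth simulators for both data streams, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
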