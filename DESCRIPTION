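Package: catres
Title: Catalytic Residue Prediction from Side-Chain Orientation and Rigidity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts enzyme catalytic residues from a single protein
    structure, without homology information. Every residue is scored by the
    tendency of local residue groups to point their side chains at a common
    center, detected by scanning a 30x30x30 grid of candidate site centers,
    combined with weighted-contact-number (WCN) rigidity and the
    co-occurrence preferences of amino-acid types within known catalytic
    sites. Sequence conservation from a PSI-BLAST position-specific scoring
    matrix can optionally be fused into the ranking. Includes per-protein
    ROC / recall-precision evaluation with vertical curve averaging, and a
    synthetic-structure generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
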