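Package: strandHB
Title: Strand-Level Hydrogen-Bond Analysis of Protein-DNA Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects hydrogen bonds between protein side chains and DNA
    bases in protein-dsDNA complex structures, using either HBPLUS-style
    geometric criteria or a Mayo 12-10 hydrogen-bond energy function, and
    compares the contribution of the two DNA strands to binding
    specificity.  Assembles Watson-Crick duplexes, labels major/minor
    groove edge atoms, identifies base pairs in which both bases are
    engaged by side-chain hydrogen bonds, assigns Kabsch-Sander secondary
    structure to DNA-interacting residues, computes secondary-structure
    propensities against several backgrounds, and runs normality-gated
    two-sample comparisons between specificity groups.  Includes an
    idealized B-DNA fixture generator with planted ground truth for fully
    offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, bio3d, jsonlite
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
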