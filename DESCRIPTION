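Package: cvfold
Title: Constraint-Conditioned Protein Structure Optimization and Ensemble Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for conditioning protein complex models on user-defined
    collective-variable (CV) constraints and for auditing the results.
    Implements positional restraint, attractive and repulsive distance losses
    over Calpha residue groups, a confidence regularizer built from pLDDT,
    pTM and ipTM, scheduled annealing of the constraint and regularizer
    weights, and gradient descent over a pluggable differentiable structure
    generator. Ships the evaluation stack used to assess disordered-complex
    models: multimer confidence ranking (0.8 x ipTM + 0.2 x pTM), mean pLDDT,
    PAE block summaries, Calpha contact-probability maps at a 12 Angstrom
    cutoff, and per-domain heavy-atom RMSD with replicate statistics. A
    deterministic fixture generator produces toy multi-domain complexes and
    synthetic ensembles with planted contacts so every operation is testable
    at desk scale, including a preset for the G3BP1-GR20 dipeptide-repeat
    complex.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
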