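Package: dupscan
Title: Duplicate Detection for Protein Backbone Depositions via Rigid Invariants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a complete, continuous rigid-motion invariant of protein
    main-chain traces (the backbone rigid invariant, an m x 9 matrix of local
    coordinates of the N, CA and C atoms of each residue in a frame attached to
    the preceding residue) and its nine-component column average, and uses the
    Chebyshev lower bound between the two to run a cascade search for
    (nearly) identical chain coordinates across structure depositions.
    Includes PDB/mmCIF chain extraction with auditable cleaning filters,
    exact invariant inversion back to coordinates, mirror-image
    discrimination, per-pair forensic reports (maximum atomic deviation,
    relabelled residues), a deterministic synthetic-fixture generator with
    planted ground truth, and a command-line scanner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
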