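Package: rnasse
Title: RNA Secondary-Structure Element Graphs and Coarse-Grained Helix Geometry
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Represents RNA molecules as graphs of secondary-structure
    elements (stems, hairpin loops, interior loops, multiloop segments and
    single-stranded ends), fits cylinder axes to helices from atomic
    coordinates, measures inter-stem angles and ray offsets together with a
    relaxed coaxial-stacking call in junctions, and classifies pseudoknots
    by topological genus into H-type and kissing-hairpin families.  Reads
    and writes dot-bracket (including extended bracket alphabets and
    '&'-separated chains), bpseq, ct, PDB and mmCIF files as well as
    DSSR-style JSON base-pair and stacking annotations, and ships a
    synthetic-fixture generator for ideal A-form-like helices and toy PDB
    files with modified, missing and insertion-coded residues.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
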