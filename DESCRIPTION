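Package: orthoarch
Title: Comparative Gene-Architecture Analysis of Plant Ortholog Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of ortholog gene families across
    plant species, built around the starch synthase III family in monocots and
    dicots: inference of exon/intron structure by splice-aware cDNA-to-genomic
    alignment, intron phase classification, indel cataloguing, Nei-Gojobori
    Ka/Ks estimation with Jukes-Cantor correction, Poisson-corrected protein
    distances with neighbor-joining trees and bootstrap support, consensus
    protein construction with group conservation scores, protein motif
    architecture comparison, IUPAC promoter element scanning, Kabsch structure
    superposition with Q-scores, and FPKM-based expression calls. Includes a
    synthetic ortholog-family generator with known ground truth for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
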