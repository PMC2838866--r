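Package: denovotag
Title: De Novo Peptide Sequence Tags from High-Resolution Tandem Mass
    Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Infers partial peptide sequences (sequence tags) directly from
    high-resolution tandem mass spectra. Observed fragment ions are deisotoped
    to neutral monoisotopic masses and assembled into a spectrum graph whose
    four typed edges encode the possible mass relationships among adjacent and
    complementary y/b ions. The spectrum graph is transformed into a sequence
    graph of candidate residues, all valid paths are enumerated under simple-path
    and short-circuit constraints, and paths are scored purely by fragment mass
    accuracy. Consensus tags derived from the top two paths trade tag length for
    accuracy. Also provides accurate parent-mass annotation of database-search
    identifications against surrounding full scans, with median recalibration,
    threshold filtering and target-decoy false discovery rates; readers and
    writers for the FT1/FT2 and DTA text formats; a verification harness with
    error-type classification; and a ground-truthed synthetic spectrum generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
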