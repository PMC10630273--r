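Package: lyticmine
Title: Mining and Comparative Analysis of Bacteriophage Lytic Cassettes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative genomics of the lysis machinery of
    bacteriophages infecting gram-positive hosts such as Enterococcus.
    Reads annotated phage genomes from GenBank flat files and protein
    domain scans in InterProScan tab-separated format, classifies proteins
    into lytic roles (holin, endolysin, holin-like) by product keywords and
    Pfam domain evidence, extracts holin-endolysin lytic cassettes as gene
    neighbourhoods, stratifies genomes into five size groups, and tabulates
    catalytic x cell-wall-binding (CWB) domain combinations. Endolysins are
    segmented into catalytic domain, proline/lysine-rich interdomain linker
    and CWB region; unannotated C-terminal regions are clustered into
    putative unknown CWB (UCWB) families. Gene-shuffling (holin replacement
    in otherwise conserved cassettes) and domain-shuffling (catalytic or
    CWB module exchange between near-identical endolysins) events are
    called from region-wise global-alignment identities. A synthetic genome
    generator with a ground-truth event ledger makes the whole pipeline
    testable without any network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
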