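Package: glycoscan
Title: Detection, Classification and Removal of Sugar Moieties in Molecular Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Perceives circular (furanose, pyranose, heptose) and linear
    (open-chain, 4-7 carbon) sugar moieties in molecular structures read from
    SMILES or SDF files, classifies them as terminal or non-terminal, and
    removes terminal sugars iteratively to obtain aglycones. Circular sugar
    candidates are filtered by the ratio of exocyclic oxygen atoms to ring
    heavy atoms, with configurable handling of spiro rings, keto groups and
    glycosidic-bond requirements. Per-molecule glycosylation profiles are
    aggregated into dataset-level statistics (moiety counts, ring-class and
    chain-length distributions, exocyclic-oxygen-ratio histograms). Additional
    tools group stereoisomers by stereo-insensitive canonical SMILES, count
    substructure occurrences of a curated sugar-moiety library, curate
    collections by MaxMin diversity picking and cross-set exclusion, and
    generate synthetic glycosylated molecules with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
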