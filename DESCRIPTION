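Package: subtadscope
Title: Differential TAD/subTAD Architecture Analysis on Binned Hi-C Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing 3D chromatin architecture between paired
    conditions from binned Hi-C contact matrices and ChIP-seq/RNA-seq feature
    tables. Implements matrix balancing, distance-decay expected profiles,
    diamond-window insulation scores, two-scale (TAD/subTAD) boundary calling
    and cross-condition boundary classification, differential peak-occupancy
    classification, permutation-based colocalization enrichment (observed over
    expected), aggregate pileup analysis around anchors and anchor pairs, and
    boundary-expression integration. Ships a paired-condition synthetic-genome
    generator with a machine-readable ground-truth change record for
    end-to-end validation of the full workflow.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
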