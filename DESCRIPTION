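Package: amidering
Title: Ring-Current Analysis of Anomalous Amide Proton Chemical Shifts
Version: 0.1.0
Authors@R:
    person("BMRB-PDB", "Federation Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A federated analysis pipeline for anomalous backbone amide 1H
    chemical shifts. Reads assigned chemical shifts and NOE distance
    restraints in an NMR-STAR dialect and multi-model coordinate ensembles
    in mmCIF, builds filtered per-(residue, atom) chemical-shift reference
    statistics with the standard corpus-filtering rules, computes Z-scores,
    locates the nearest aromatic ring (PHE, TYR, TRP, HIS) for every amide
    proton with ensemble-averaged distance and azimuth angle, classifies
    amide-aromatic restraints, and summarises the fraction of restrained
    amides per Z-score bin. Includes a synthetic-corpus generator that
    plants point-dipole ring-current perturbations with recorded ground
    truth, so the full pipeline is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
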