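Package: ddfetal
Title: Noninvasive Fetal Blood-Group Genotyping from Duplex Droplet Digital PCR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for noninvasive prenatal genotyping of the
    RHD, RHCE and KEL blood-group loci from cell-free DNA in maternal
    plasma measured by duplex droplet digital PCR (ddPCR). Classifies
    per-droplet two-channel fluorescence amplitudes into positive and
    negative tallies, estimates molecular loads by Poisson partitioning
    statistics, computes the cell-free fetal DNA fraction from fetus- and
    maternal-specific positive droplet counts, and calls the fetal
    genotype under droplet-count decision rules with non-template-control
    quality gates and a repeat zone around the calling limit. Includes a
    droplet-partitioning simulator that stands in for instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
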