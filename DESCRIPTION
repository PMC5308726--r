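Package: plasmatrack
Title: Tumor-Informed Monitoring of Somatic Mutations in Plasma Cell-Free DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tumor-informed analysis of circulating tumor DNA from targeted
    panel sequencing. Calls tumor-specific somatic single-nucleotide variants
    from paired tumor/normal read observations using per-read quality filters,
    depth and allele-frequency thresholds, and a one-sided Fisher exact test;
    then detects those mutations in serial plasma draws restricted to the
    tumor-identified positions at ultra-low allele frequency (>= 0.0005, >= 2
    supporting reads), builds allele-frequency trajectories, flags molecular
    recurrence with lead time relative to imaging, and summarises paired
    tumor-plasma diagnostic accuracy (sensitivity, specificity, PPV, NPV,
    accuracy) per gene. A seeded synthetic-cohort generator emulating a
    53-gene panel sequenced to ~3810x mean depth drives the whole analysis
    with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    ggplot2,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
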