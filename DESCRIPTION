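Package: archstats
Title: Archaic Introgression Statistics, Geographic Trends and Coalescent
    Simulation of Serial-Founder Demographies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying putative archaic-hominin legacies in modern
    human genomes and for testing whether the observed geographic patterns can
    arise from introgression followed by neutral drift. Implements the
    ABBA-BABA D statistic with zygosity conditioning, the derived-archaic-
    allele frequency statistics nd_NEA and nd_DEN (with African-panel
    conditioning and transition/transversion partitions), the f4 statistic,
    allele frequency difference (AFD), Hudson's FST and expected
    heterozygosity, all computed from a multi-taxon aligned site table built
    from human and archaic variant calls with a chimpanzee outgroup. A
    coalescent simulator of a serial-founder out-of-Africa demography with
    Neanderthal and Denisovan admixture pulses (run through msprime) generates
    the same site tables, enabling end-to-end calibration experiments such as
    migration-rate sweeps. Companion analyses include great-circle and
    waypoint land-route distances, geographic trend regressions, per-
    chromosome leave-one-out consistency correlations and megabase-window f4
    genome scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    arrow,
    data.table (>= 1.14),
    geosphere,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with msprime (>= 1.0) and numpy, available
    as 'python' on the PATH (only required for coalescent simulation).
Config/testthat/edition: 3
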