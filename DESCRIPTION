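Package: nucleoscan
Title: Positioned Nucleosome Detection from Single-End MNase-Seq
Version: 0.1.0
Authors@R:
    person("Maintainer", "Packages", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies positioned nucleosomes from single-end sequencing of
    MNase-digested mononucleosomal DNA. Read 5' ends are converted into a
    beta-discretized nucleosome-center probability landscape, which is scanned
    with a triangle statistic built from median-unbiased odds estimates;
    calls are decorrelated with a clump-picking N-statistic, and per-candidate
    false discovery rates are estimated by Monte Carlo read shaking.
    Reads BAM, SAM, and BED alignments; writes TXT, WIG, and BedGraph tracks.
    Includes a synthetic read generator with known ground truth and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicAlignments,
    Rsamtools,
    parallel,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
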