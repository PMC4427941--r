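Package: cfmethylome
Title: Cell-Free DNA Methylome Analysis: DMRs, Placental Hypomethylated
    Domains, Fragmentomics and Robust Trisomy Z-Scores
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of whole-genome bisulfite sequencing of
    circulating cell-free DNA and its tissue contributors. Reads
    Bismark-style cytosine reports and collapses strand-specific CpG
    calls; summarises methylation globally, per context and within
    region sets; calls differentially methylated regions between sample
    groups with a per-site Welch t-statistic, |t| filtering and
    proximity grouping; detects megabase-scale placenta hypomethylated
    domains from 50 kbp genomic bins; relates cell-free DNA fragment
    length to methylation, including methyl-CpG immunoprecipitation
    size fractions; and scores chromosome-21 representation with a
    robust euploid-anchored z-score. A seeded synthetic-data generator
    emulates the statistical structure of all of these inputs with
    known ground truth, and a deterministic pipeline orchestrates
    end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
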