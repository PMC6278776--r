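Package: somamosaic
Title: Somatic Mosaicism of Interrupted DMPK CTG Expansions from
    Small-Pool PCR Allele Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies somatic instability of expanded CTG repeats at the
    DMPK locus from single-molecule small-pool PCR allele-size data.
    Parses repeat-interruption pattern strings, computes per-sample
    allele-frequency-distribution statistics (10th-percentile progenitor
    allele length estimate, 90th-10th percentile instability range, modal
    expansion size, 5'-end views), fits the associated linear-model suite
    relating instability and age at onset to progenitor length and age at
    sampling, runs the nonparametric comparison matrix (Wilcoxon rank-sum
    and signed-rank tests with Shapiro-Wilk normality gates), and
    simulates synthetic patient cohorts with an expansion-biased,
    length- and age-dependent somatic mutation process attenuated by
    repeat interruptions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
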