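Package: emscreen
Title: Enzymatic Methyl-Seq Conversion QC and Stacked cfDNA Cancer Screening
Version: 0.1.0
Authors@R: person("emscreen", "developers", email = "emscreen@example.org",
    role = c("aut", "cre"))
Description: Tools for quality control of enzymatic methyl sequencing (EM-seq)
    of cell-free DNA and for building a stacked classifier for hepatocellular
    carcinoma (HCC) screening from targeted methylation panels. Implements
    per-read methylation-context calling against a reference, counting of
    unconverted non-CpG (CH) cytosines, removal of incompletely converted
    reads carrying three or more unconverted CH sites, per-CpG methylation
    quantification with conversion-efficiency estimation and
    incomplete-conversion hotspot detection, marker selection rules and
    five-probe in-silico-converted capture panel design, simulators for
    spike-in control DNA and three-class plasma cohorts, a two-layer stacked
    gradient-boosting plus logistic model producing a tumor score, and
    confusion-matrix and ROC reporting with DeLong confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    data.table,
    Rcpp,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    Rsamtools
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
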