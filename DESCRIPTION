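Package: karyobias
Title: Karyomorphometric Descriptors and Inter-Observer Bias Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the standard quantitative karyomorphometric descriptors
    of a mitotic metaphase plate from per-chromosome arm-length measurements:
    total haploid chromosome length (THL), mean centromeric asymmetry (MCA),
    and the coefficients of variation of chromosome length (CVCL) and of
    centromeric index (CVCI). Provides an inter-observer reliability analysis
    for repeated measurements of the same plate (per-trait coefficients of
    variation, Pearson correlation matrix with exact t-based p values, and
    plot-ready boxplot/scatter exports), together with a Monte-Carlo simulator
    of multi-observer measurement error that encodes an observer-level
    short-arm overestimation bias, so the coupling between THL inflation and
    MCA deflation can be studied on synthetic data. Includes CSV readers and
    writers for long-format arm measurement tables and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
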