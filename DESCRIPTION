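Package: yaptaz
Title: Quantification of YAP/TAZ Expression, Localization and the CIN25
    Signature in Cholangiocarcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for the computational analyses used in
    studies of the Hippo pathway effectors YAP and TAZ in cholangiocarcinoma:
    semiquantitative immunohistochemistry scoring on tissue microarrays with
    positivity cross-tabulation, automated nuclear-to-cytoplasmic ratio
    quantification from two-channel immunofluorescence fields with
    cell-density stratification, CIN25 gene-signature scoring with k-means
    clustering and Kaplan-Meier survival stratification, and siRNA knockdown
    readouts via 2^-ddCt relative quantification. Ships seeded synthetic-data
    generators for every input family so each stage carries
    parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    survival
Suggests:
    testthat (>= 3.0.0),
    mclust,
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
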