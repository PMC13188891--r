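Package: biphasr
Title: Biphasic Backcross Mapping of Insecticide-Resistance Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for biphasic linkage mapping of
    incompletely dominant Bt-resistance loci in Lepidoptera. Includes a
    cross/selection/sequencing simulator exploiting female achiasmatic
    meiosis (female-informative backcrosses assign a trait to a chromosome;
    male-informative backcrosses fine-map within it), a bulked-segregant
    (BSA-seq) allele-frequency scan with per-chromosome kernel density
    profiles and peak-shift linkage calls, amplicon-sequencing fine mapping
    with QC filters and a candidate-interval caller, dominance-coefficient
    estimation from diagnostic-PCR genotype counts, and an RPKM-based
    midgut expression screen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
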