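Package: climbiome
Title: Climate-Stratified Soil Microbiome Co-Occurrence Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how soil bacterial co-occurrence structure
    varies across Koppen-Geiger climate zones. Provides ESV (exact sequence
    variant) table import and filtering, alpha/beta diversity and
    distance-decay statistics, per-zone sparse co-occurrence network
    inference by neighborhood selection on centered log-ratio transformed
    counts with StARS stability selection, bootstrap-normalized comparison
    of network topology between zones, hub-taxon detection, and
    hypergeometric taxon-pair overrepresentation tests. A synthetic-data
    generator with known ground-truth dependence structure supports
    end-to-end validation without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    biomformat,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
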