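Package: culthitch
Title: Individual-Based Simulation of Cultural Hitchhiking under Intergroup Exogamy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time, individual-based meta-population simulator of
    cultural hitchhiking: age-structured demography with mortality, exogamous
    marriage, postmarital migration and community fission; vertical,
    horizontal and oblique transmission of neutral cultural traits with
    sex-biased role-model choice; and frequency-dependent community-level
    adoption of adaptive traits. Includes the experiment sweep machinery and
    summary statistics (community type and lineage counts, per-trait variant
    proportions by community type, effective growth rates) used to quantify
    hitchhiking strength and intergroup cultural diversity, plus tidy
    accessors and ggplot2 diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
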