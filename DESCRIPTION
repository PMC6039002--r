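Package: mztdyn
Title: Global DNA-Methylation Dynamics Across the Maternal-to-Zygotic
    Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic discrete-time simulator of global DNA-methylation
    dynamics across the maternal-to-zygotic transition (MZT) in a dioecious
    species. Couples logistic embryo growth and geometric decay of a parental
    repressor to a nucleocytoplasmic-ratio-linked switch from pre- to
    post-zygotic-genome-activation (ZGA) methylation kinetics over three site
    states (homo-, hemi-, unmethylated). Supports multi-generation runs with
    fertilization (gametic averaging) and sex-specific environmental
    perturbation of rates, equilibrium (fixed-point) analysis, a grid explorer
    of maintenance/de-novo rate combinations compatible with target gametic
    methylation levels, and an empirical calculator of net (de-)methylation
    enzyme activity between developmental stages.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
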