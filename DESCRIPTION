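Package: httkin
Title: Chemical-Kinetic Model of Co-Translational Huntingtin Misprocessing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a chemical-kinetic model linking CAG-repeat expansion
    in huntingtin exon 1 to co-translational misprocessing. Builds per-codon
    translation dwell-time schedules for the N17/polyglutamine/proline-rich
    layout, computes the time available for co-translational factor binding
    (tau_AFB) and the relative misprocessed fraction f_mp as functions of the
    CAG-repeat number, estimates the effective in-vivo first-order binding
    rate from a bimolecular rate constant and chaperone concentrations,
    validates the closed-form survival probability with a Monte-Carlo
    single-ribosome simulation, and correlates f_mp with repeat number and
    age of symptom onset. Ships synthetic-data generators for onset and
    chaperone tables so the full pipeline is testable without external
    downloads.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
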