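Package: selwin
Title: Windows of Selection and Dominance in the Evolution of
    Insecticide Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how declining insecticide concentration drives the
    evolution of resistance in diploid disease vectors. Implements a
    single-locus diploid selection recursion under partial exposure, the
    per-generation selective advantage of a resistance allele, conversion of
    genotype bioassay mortalities into simulation inputs (effectiveness,
    resistance restoration, dominance), and generations-to-resistance
    simulation. Detects and measures windows of selection and windows of
    dominance on mortality-versus-concentration or mortality-versus-time
    curves, computes dominance, selective-advantage and time-to-resistance
    profiles along the deployment axis, and ships a log-logistic bioassay
    simulator (binomial sampling, exponential concentration decay, best /
    intermediate / worst dominance scenarios) so every stage is testable
    without laboratory data.
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
    scales,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
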