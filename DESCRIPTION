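Package: dsbhr
Title: Double-Strand Break Quantification and Homolog Recombination
    Statistics for Polyploid Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies gamma-induced DNA double-strand breaks (DSBs) and
    their repair from pulsed-field gel (PFGE/CHEF) band-intensity tables
    using the Poisson random-breakage zero-class estimator (N = -ln F,
    with the DSB density per megabase recovered as the slope of N versus
    chromosome size), and provides the companion statistics for
    homologous-chromosome recombination assays in tetraploid yeast:
    recombination frequencies per survivor, Luria-Delbruck fluctuation
    analysis by the Lea-Coulson method of the median with bootstrap
    confidence intervals, summary-statistics t tests, dose-response
    survival and dose-modifying factors, PCR genotyping of reciprocal
    exchange products, and the G2 sister-chromatid segregation correction.
    Includes seeded synthetic-data generators (Poisson chromosome
    breakage with repair kinetics, fluctuation cultures, tetraploid
    reciprocal-exchange segregation, exponential survival) so the whole
    pipeline can be exercised and validated without gel images or colony
    counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
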