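Package: wheatgap
Title: Wheat Ideotype Design and Genetic Yield Gap Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for designing wheat ideotypes and
    quantifying the genetic yield gap under water-limited conditions. The
    package couples a seeded stochastic daily weather generator (two-state
    Markov precipitation occurrence, autocorrelated temperatures,
    wet/dry-conditioned radiation) to a daily process-based wheat growth
    simulator (thermal-time phenology with photoperiod response, Beer's-law
    light interception, radiation-use-efficiency biomass accumulation, a
    single-bucket soil water balance, heat and drought damage to grain number
    around flowering, and stress-accelerated leaf senescence). A (1+16)
    self-adaptive evolution strategy searches seven cultivar traits for the
    combination maximising multi-year mean yield subject to yield-stability
    (CV of yield at most 10 percent) and harvest-index (at most 0.64)
    constraints, and a reporting layer computes genetic yield potential and
    the genetic yield gap, absolute and as a percentage, per site and
    aggregated.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    geosphere,
    jsonlite
Config/testthat/edition: 3
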