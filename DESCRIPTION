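Package: hazetol
Title: Quantifying Population Psychological Tolerance to Haze from Social-Media Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building a composite index of population psychological
    tolerance to haze pollution from microblog text, PM2.5 series and
    socio-economic indicator panels. Implements naive-Bayes sentiment scoring
    with a 0.5 polarity threshold, TF-IDF keyword extraction and a co-word
    topic index, AHP pairwise-comparison weighting with consistency testing,
    entropy weighting and combined weights, a prefecture-level tolerance
    index, base-10 trajectory coding of class-state sequences with a
    five-way change-type taxonomy, and a seeded synthetic-data generator so
    the full pipeline is testable without scraping or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
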