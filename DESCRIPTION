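Package: vulnprofiles
Title: Economic and Health Vulnerability Profiles of Older Europeans from
    Weighted Survey Microdata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds composite economic and health vulnerability indicators
    from person-level survey microdata on the population aged 50+, using
    literature-based binarization rules (at-risk-of-poverty thresholding with
    OECD-modified equivalisation, EURO-D depression cutoff, GALI/ADL/IADL
    limitation counts, BMI classes, health-care utilisation). Clusters
    respondents into vulnerability profiles with a k-prototypes algorithm for
    mixed numeric/categorical data extended to honour per-record survey
    calibration weights, selects the number of profiles by the elbow
    criterion, and measures the effect of a deterministic pandemic-style
    shock cascade (sector job losses, chronic-disease health worsening,
    downstream financial distress and mental-health deterioration) on the
    indicators and profile composition. Includes a synthetic microdata
    generator with per-country calibrated weights, regional heterogeneity
    and a planted latent-profile structure so the full pipeline is testable
    without access-restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
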