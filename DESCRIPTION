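Package: airwaycfd
Title: One-Dimensional Airway Network Modelling of Asthma with Fixed Airway Obstruction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for contrasting asthma phenotypes with and without fixed
    airway obstruction from quantitative computed tomography (QCT) derived
    airway trees. Provides a healthy-reference airway diameter model for
    Korean adults, stochastic completion of CT-unresolved conducting airways
    by volume filling with Horsfield ordering, a dynamic one-dimensional
    airway-network flow and pressure solver over a sinusoidal breathing
    cycle (alveolar, pleural and transpulmonary pressure decomposition,
    workload and hysteresis), parametric-response-map functional metrics
    (emphysema and functional small airway disease percentages), normalized
    structural metrics, a normality-gated two-group statistical battery with
    Benjamini-Hochberg correction and Spearman correlations, and a synthetic
    cohort generator so the full pipeline runs without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
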