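Package: cordox
Title: Cerebral and Spinal Cord Autoregulation Indices from NIRS Oximetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed oximetry indices for assessing cerebral and spinal cord
    autoregulation from near-infrared spectroscopy (NIRS) recordings: the
    Spearman rank correlation between mean arterial pressure (MAP) and tissue
    oxygenation index (TOI) over fixed dose windows (COx, T-SOx, L-SOx), with
    three-state classification of each window (pressure-passive, intact,
    paradoxical), dose-response summaries, MAP-TOI regressions and
    percent-change statistics, and the nonparametric group-comparison tests
    used with such indices (repeated-measures ANOVA with Scheffe post hoc,
    Friedman with Steel-Dwass post hoc, Wilcoxon signed-rank). Includes a
    protocol-conformant hemodynamic simulator that generates stepwise
    vasoactive-infusion experiments with known per-window ground truth for
    validating the classification pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
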