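Package: nestbudget
Title: Quantifying Biparental Care from Nest Event Logs and Evaluating
    Sampling-Window Designs
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying parental effort of biparental birds from
    behavioural event logs coded off nest-box video: exact interval algebra for
    individual, joint and total care and nest-attendance time budgets; fixed
    1h/3h sampling-window partitions and effort matrices; intraclass
    repeatability from one-way ANOVA (Harper's method) with window-width
    comparisons; window-versus-daily prediction accuracy via OLS R-squared with
    nonparametric bootstrap confidence intervals; linear mixed models for
    diurnal trends (AIC-selected polynomial of period) and division of labour
    (sex by reproductive-stage likelihood-ratio tests); and a continuous-time
    two-parent behavioural simulator with diurnal modulation, stage effects,
    individual random effects and partner coupling that emits synthetic event
    logs with the statistical structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
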