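Package: priorweight
Title: Bayesian Prior Weighting in Goal-Directed Visuomotor Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing precision-weighted cue combination in an
    effort-based visuomotor task. Provides a generative observer model of
    performance estimation, a synthetic-cohort simulator emulating a
    placebo-controlled crossover drug study in Parkinson's disease, slope-based
    and hierarchical Bayesian estimation of prior weighting with MCMC
    diagnostics, posterior predictive checks and WAIC/PSIS-LOO model
    comparison, group-level inference (moderated regression with
    Johnson-Neyman regions, Pitman's paired-variance test, JZS Bayes factors,
    repeated-measures ANCOVA, plausible-values analysis), and
    contrast-to-noise quantification for neuromelanin-sensitive volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
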