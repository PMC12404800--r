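Package: criterionshift
Title: Signal-Detection Analysis and Design Machinery for False-Feedback
    Recognition-Memory Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying response-criterion shifts in old/new
    recognition memory induced by false performance feedback. Provides
    equal-variance signal-detection indices (d', criterion c, beta) with
    explicit extreme-rate corrections, effect-size arithmetic (Cohen's d,
    probability of superiority, dominance percentages), simulation-based
    power analysis for minimal-effect and equivalence testing against a
    smallest effect size of interest (SESOI), a seeded generator that
    simulates a full two-session experiment (counterbalanced stimulus
    design, latent SDT responders, probabilistic false feedback,
    condition-dependent criterion shifts, state and trait memory-distrust
    scales), and an inference pipeline covering exclusions, trait-scale
    scoring, ANOVAs with eta-squared confidence intervals, Welch TOST
    equivalence tests, regressions, and crossed random-intercept mixed
    models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
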