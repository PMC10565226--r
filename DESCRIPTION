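Package: gazepref
Title: Preferential-Looking Analysis of Paired-Stimulus Eye-Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for preferential-looking studies in which two stimuli
    compete for gaze on one screen. Provides a dispersion-based (lead-sample)
    fixation detector, area-of-interest dwell-time metrics, quality-control
    and mirror-pair curation with observation weights, and a from-scratch
    linear mixed-effects engine with a participant random intercept and a
    heteroscedastic residual variance (group-specific scale combined with
    fixed precision weights), including REML/ML fitting, likelihood-ratio
    and AIC model comparison, backward fixed-effect reduction, and estimated
    marginal means with inner-outer denominator degrees of freedom. A
    synthetic gaze-stream generator emulating a two-snake threat-display
    experiment makes the whole pipeline runnable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, yaml
Suggests: testthat (>= 3.0.0), nlme, emmeans, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
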