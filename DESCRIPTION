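Package: svapath
Title: Psychometric, Mediation and Resting-State Analyses of Short-Video Addiction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying pathways from bullying victimization to
    short-video addiction in adolescents. Scores 6-point Likert scales
    (short-video addiction, bullying victimization subdimensions, positive
    and negative affect), classifies addiction risk by gender-specific
    cutoffs, and computes descriptive statistics, Cronbach's alpha and
    Harman's single-factor test. Estimates simple mediation models with
    percentile bootstrap confidence intervals, proportion mediated and
    addicted/non-addicted subgroup analyses. For resting-state fMRI-like
    data, computes the amplitude of low-frequency fluctuations (ALFF) in
    the 0.01-0.1 Hz band, parcel-level brain-behavior associations with
    covariate control and multiplicity correction, and inter-subject
    representational similarity analysis (IS-RSA) between behavioral and
    parcel-wise ALFF-pattern dissimilarity matrices, with Mantel
    permutation inference. Includes synthetic-data generators with known
    mediation structure and planted trait-amplitude coupling so every
    stage can be validated against ground truth, and a config-driven
    pipeline runner.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
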