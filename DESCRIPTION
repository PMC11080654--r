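Package: hybridgp
Title: Two-Stage Genomic Prediction of Hybrid Performance in Multi-Environment Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and two-stage analysis of hybrid genomic prediction in a
    two-pool breeding program. Builds hybrid additive-dosage and
    dominance-indicator genotypes from inbred parents, applies marker quality
    control, constructs VanRaden additive and Vitezica dominance relationship
    matrices and averaged Gaussian kernels, fits per-environment mixed models
    by REML (variance components, BLUPs, BLUEs, likelihood-ratio tests,
    heritability), and fits single- and multi-trait GBLUP and RKHS models with
    optional genotype-by-environment interaction kernels via a Gibbs sampler.
    Includes CV1, CV0 and CV00 cross-validation schemes and a synthetic-data
    generator emulating unbalanced multi-environment trials with augmented
    block and randomized complete block designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
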