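Package: drugTargetMR
Title: Sex-Specific Drug-Target Mendelian Randomization with Mediation by
    Attenuation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Univariable and multivariable Mendelian randomization (MR) for
    sex-specific drug-target analyses: harmonization of GWAS summary
    statistics, instrument selection (genome-wide significance, LD pruning,
    proxy substitution, F-statistic screening), Wald ratio, inverse-variance
    weighted estimation with multiplicative random effects (including a
    generalized least-squares form for correlated variants), weighted median,
    MR-Egger, Steiger directionality filtering, multivariable MR with
    Sanderson-Windmeijer conditional F-statistics and Q instrument-validity
    diagnostics, cross-sex meta-analysis and z-contrasts, and mediation by
    attenuation. Includes a seeded generator of sex-stratified cohorts and
    derived per-sex GWAS summary statistics so every pipeline stage can be
    exercised without access to individual-level biobank data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
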