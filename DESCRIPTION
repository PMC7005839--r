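Package: foodaddictr
Title: Operant Food-Addiction Phenotyping: Schedule State Machines,
    Criterion Attribution, Cohort Statistics and Count-Based DE Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-level analysis of rodent operant self-administration
    experiments used to phenotype food addiction-like behavior. Provides
    deterministic state machines for fixed-ratio, progressive-ratio and
    punished (footshock) schedules of reinforcement that turn timed
    lever-press streams into event logs; scoring of the three addiction-like
    criteria (persistence during the pellet-free period, progressive-ratio
    breaking point, shocks endured); percentile-based criterion attribution
    against a control group and 2-of-3 addicted/non-addicted classification
    with acquisition and exclusion rules; the accompanying statistical layer
    (Mann-Whitney, chi-square goodness of fit against control frequencies,
    Pearson correlation); a latent-trait synthetic cohort simulator so the
    whole pipeline runs at desk scale; and a minimal negative-binomial
    differential-expression stage (median-of-ratios normalization, exact
    conditional test, fold-change/p/abundance filters, top-variance PCA)
    for gene-by-sample count matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    DESeq2
Config/testthat/edition: 3
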