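Package: oraltopics
Title: Paired Plaque-Abscess Microbiome Analysis with Topic Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community-ecology analysis of paired supragingival-plaque and
    odontogenic-abscess 16S cohorts: cohort filtering and rank agglomeration,
    compositional transforms (TSS, CLR, CSS-log), ordination with a
    transform-by-distance selection sweep, paired differential abundance with
    three-method consensus confidence tiers, latent Dirichlet allocation of
    scaled relative abundances via collapsed Gibbs sampling with four-metric
    topic-number selection, cross-validated specimen-type classification, and
    hypergeometric pathway over-representation. Includes a seeded
    Dirichlet-multinomial generator of paired cohorts with known latent-topic
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    vegan,
    ranger,
    uwot,
    jsonlite,
    digest,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    pROC
Config/testthat/edition: 3
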