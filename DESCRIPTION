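Package: vaxtweets
Title: Dual-Source Twitter Surveillance of HPV Vaccine Sentiment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for infoveillance of human papillomavirus (HPV)
    vaccine communication on Twitter. Simulates labelled tweet corpora with the
    statistical structure of an HPV-vaccine keyword stream and two imperfect
    collection views (search API versus firehose), reconciles the views by
    tweet ID with full exclusion accounting, trains and evaluates
    Moore-Penrose pseudoinverse linear and Gini decision-tree sentiment
    classifiers with leave-one-out AUC and learning curves, applies
    rounded-zero and certainty discard rules, computes keyword-word
    association scores, and produces sentiment cross-tabulations with
    chi-square, one-way ANOVA and Mood's median tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    MASS,
    pROC,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
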