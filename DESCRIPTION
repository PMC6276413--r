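Package: lipidgrs
Title: Genetic Risk Scores and Model Selection for Blood Lipid Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to predict blood lipid phenotypes (total cholesterol,
    LDL-c, HDL-c and triglycerides) from obesity-related SNP genotypes and
    lifestyle covariates. Implements phenotype-driven genotype risk coding
    into per-lipid genetic risk scores (ANOVA prescreen, post hoc
    Bonferroni/Dunnett-T3 grouping, binarized t selection and prevalence
    filtering), multiple linear model selection by exhaustive best subsets,
    least-angle regression and bootstrapped stepwise, Harrell bootstrap
    optimism correction, squared partial correlation decomposition,
    Hardy-Weinberg and AMOVA cohort quality checks, Friedewald LDL-c
    derivation and dyslipidemia classification, plus a synthetic cohort
    generator with known ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    car,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    vcfR
Config/testthat/edition: 3
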