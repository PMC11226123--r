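Package: twinliab
Title: Liability-Threshold Twin Models for Binary Phenotypes with Unknown Zygosity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variance decomposition of binary phenotypes from twin and sibling
    pairs when zygosity is unknown. Fits ACE and ADE liability-threshold
    models by direct maximum likelihood on 2x2 concordance tables, using the
    same-sex versus opposite-sex twin design with a Weinberg-rule adjustment
    of the genetic correlation in the mixed same-sex group. Includes
    maximum-likelihood tetrachoric correlation estimation, a closed-form
    method-of-moments (Falconer-type) solver, sibling-substitution designs for
    sex-specific fits, stratified fits with two-sample Z tests for
    heritability differences, and a seeded synthetic twin-registry generator
    so every stage of the pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), pracma, optparse, withr, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
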