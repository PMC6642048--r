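Package: tmecoexpr
Title: Pan-Cancer T-Cell Co-Expression Ranking and Checkpoint Target
    Complementarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks genes by their co-expression with the pan T-cell marker
    CD3E across cancer-type cohorts, scores candidate immunotherapy targets
    for complementarity to PD-1 (PDCD1) and jointly to CTLA-4 (CTLA4)
    checkpoint blockade, runs preranked gene-set enrichment on the resulting
    ranking with a gene-permutation null, and compares CD3E-PDCD1 expression
    coupling between checkpoint-therapy responders and non-responders.
    Includes a latent-factor expression simulator with known ground-truth
    correlation structure so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
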