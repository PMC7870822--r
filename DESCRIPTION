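Package: reticulotype
Title: Individualized Perturbed-Correlation Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds patient-specific protein-protein interaction networks
    (reticulotypes) from bulk expression data. A Pearson correlation reference is
    fitted over a small control cohort; adding a single patient profile perturbs
    each gene pair's correlation, and pairs whose change is significant by a
    two-tailed Z-test with Bonferroni correction are mapped onto a consolidated
    protein-protein interactome to form that patient's network. Includes network
    topology summaries, node/edge overlap coefficients, unique-edge reports, a
    Grubbs outlier screen, hypergeometric gene-set enrichment with
    Benjamini-Hochberg correction, association of network features with clinical
    variables, a fully parameterized synthetic cohort generator with known ground
    truth, and an end-to-end pipeline driven by a YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
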