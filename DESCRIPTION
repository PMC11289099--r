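Package: pgnet
Title: Proteogenomic Network Analysis of GWAS and pQTL Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-phase proteogenomic analytical framework for complex
    disease: case/control variant association with Firth-penalized logistic
    regression and fixed-effects inverse-variance meta-analysis; protein
    quantitative trait locus (pQTL) mapping with cis/trans classification and
    intersection with GWAS signals; LD-aware gene-based association scores;
    GWAS-weighted dense-module discovery on protein-protein interaction
    networks with permutation-based neighborhood enrichment; two-sample
    Mendelian randomization (Wald ratio, IVW, weighted median) with a global
    horizontal-pleiotropy test; approximate-Bayes-factor colocalization and
    single-causal-variant fine-mapping; pathway enrichment against a panel
    background and converging-evidence triangulation. Includes a synthetic
    cohort generator (LD-blocked genotypes, liability-threshold phenotypes,
    genetically driven protein abundances, scale-free interaction networks
    with planted modules) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    metafor,
    withr
Config/testthat/edition: 3
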