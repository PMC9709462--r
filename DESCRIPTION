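Package: ohra
Title: Occupational Health Risk Assessment of Workplace Chemical Toxicants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for occupational health risk assessment (OHRA) of airborne
    chemical toxicants. Implements six widely used scoring models (EPA hazard
    quotient, COSHH control banding, the Singaporean semi-quantitative method,
    and the ICMM, Australian and Romanian risk matrices), harmonizes their
    ordinal outputs onto a common risk-ratio scale, compares methods with
    nonparametric statistics (Kruskal-Wallis, Mann-Whitney, Spearman), and
    verifies whether each method's risk ordering across industries and hazards
    reproduces catalog-assigned inherent risk. Includes a seeded lognormal
    exposure-data simulator for end-to-end testing without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
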