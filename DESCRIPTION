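Package: saltpanel
Title: Comprehensive Salt-Tolerance Evaluation of Rice Germplasm Panels
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end evaluation of seedling-stage salt tolerance in rice
    germplasm panels: derived stress indices (relative SPAD, electrolyte
    leakage, Na+/K+ ratios), control-versus-stress F and t statistics with
    significance stars, Pearson correlation matrices, correlation-matrix
    principal component analysis with membership-function and index-weight
    composite D-value scoring and ranking, haplotype-phenotype association
    with protected LSD and compact letter displays (including SSR
    repeat-dose trends and multigene combinatorial haplotypes), and
    comparative-Ct (2^-ddCt) relative expression. Includes a seeded
    synthetic-panel generator emulating a two-class (tolerant/sensitive)
    germplasm panel under 125 mmol/L NaCl so the whole pipeline is testable
    without field data, plus a bundled reference worked example for
    validating the composite-scoring arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
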