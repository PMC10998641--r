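Package: boolstg
Title: Bushiness and Convergence of Boolean Network State Transition Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the 'bushiness' (phase-space contraction) and
    convergence rate of synchronous Boolean network dynamics through
    garden-of-Eden states of the complete state transition graph, and
    provides rule-table descriptors of local dynamics: an adaptation of
    Wuensche's Z-parameter to Boolean functions via input permutations
    (Z_max, Z_min, Z_ave, Z_mid, with closed forms for nested canalyzing
    functions) and the average sensitivity. Includes readers and writers
    for the BoolNet plain-text format, truth-table classification and
    enumeration of effective, unate, read-once and nested canalyzing
    functions, constrained ensemble generation over those classes with
    fixed biological fixed points, and rank-based evaluation of local
    descriptors as proxies for global graph structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
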