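Package: treequery
Title: Querying, Rooting and Incongruency Screening for Gene-Tree Collections
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for handling collections of gene trees against a reference
    species tree: a text collection format bundling a taxonomy (with synonyms)
    and many gene trees with sequence-to-species maps; an extended-Newick
    tree-pattern language with taxonomic inclusion/exclusion, branch-support,
    duplication/speciation and direct-link constraints, and a matcher that
    finds all occurrences of a pattern in every tree of a collection; two
    species-tree-aware rooting strategies (unicity-score minimisation and
    taxonomic-distance maximisation, with a deterministic tie-break cascade);
    and a leaf-to-root masking algorithm that detects taxonomic
    incongruencies, scores them with a perturbation index and classifies
    intra- versus inter-domain switches. Includes a seeded synthetic
    collection generator and a command-line interface.
License: GPL (>= 2)
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), ape, jsonlite, yaml, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
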