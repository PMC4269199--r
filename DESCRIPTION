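Package: deepspring
Title: Comparative Diversity Analysis of Thermal Spring and Deep
    Subsurface Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for asking whether thermal springs act as windows to the
    deep subsurface biosphere from 16S rRNA amplicon surveys.  Implements
    within-site diversity (Shannon entropy, Pielou's evenness, Chao1 richness
    with standard errors, rarefaction), between-site comparison (Sorensen and
    Morisita indices, Morisita dissimilarity matrices, average-linkage
    dendrograms with Newick export), exhaustive environmental best-subset
    (bioenv-style) correlation against community dissimilarity, great-circle
    distance matrices, geothermal circulation-depth estimation, phylum by
    environment correlation screens with multiple-testing control,
    sequence-level procedures (prefix dereplication, eachgap distances,
    abundance-greedy preclustering, average-linkage OTU clustering, cross-site
    shared-OTU detection, k-mismatch read mapping, contaminant screening),
    Shannon-entropy oligotyping, and seeded synthetic-data generators for
    spring-like and subsurface-like community regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    geosphere,
    Biostrings
Suggests:
    vegan,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
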