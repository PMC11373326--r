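Package: orthosketch
Title: FracMinHash Sketching for Ortholog-Group Functional Profiling of
    Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Alignment-free functional profiling of shotgun metagenomes
    against a database of ortholog groups (KEGG-Ortholog-style protein
    families). Protein sequences of each group and six-frame translations
    of the sequencing reads are reduced to FracMinHash sketches (scaled
    MinHash: retain exactly the k-mers whose 64-bit hash falls below a
    fixed fraction of the hash space), groups present in the sample are
    detected by containment overlap between sketches, and relative
    abundances are derived from abundance-weighted overlaps. Includes
    ground-truth construction from read mappings and gene coordinates,
    a six-metric evaluation suite (purity, completeness, top-quantile
    completeness, weighted Jaccard, Pearson, Bray-Curtis), and a
    self-contained synthetic benchmark generator (protein families,
    genomes, lognormal community abundances, error-prone reads) so the
    whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    Biostrings,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
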