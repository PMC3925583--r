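Package: bitbiclust
Title: Frequent Closed Itemset Mining and Biclustering of Binary Matrices via
    Bit-Table Algebra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Level-wise (Apriori-style) discovery of all frequent closed
    itemsets in high-dimensional binary data, with support counting expressed
    as matrix and vector inner products on a bit-table representation.
    Each closed itemset is equivalently reported as an inclusion-maximal
    bicluster of the binary matrix, so the tool applies directly to binarized
    gene-expression data (genes as transactions, samples as items, or the
    transpose). Includes fold-change binarization of real-valued expression
    matrices, seeded synthetic data generation with planted biclusters,
    brute-force reference enumerators for validation, and readers/writers for
    FIMI transaction files, dense CSV/TSV and MatrixMarket sparse matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
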