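---
title: "Mining frequent closed itemsets and biclusters with bit-table algebra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining frequent closed itemsets and biclusters with bit-table algebra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bitbiclust)
```

## The model

The input is a binary matrix $B^0 \in \{0,1\}^{N_0 \times m}$ — the
*bit-table* — with transactions as rows and items as columns. In the
gene-expression setting a binarized expression matrix plays this role: after
thresholding, genes are the transactions and samples (conditions) the items,
or the transpose, depending on which side the patterns of interest live on.

An itemset $J$ is a set of columns; a transaction supports $J$ when it has a
1 in every column of $J$. The support $\sigma(J)$ is the number of
supporting transactions, $J$ is *frequent* when $\sigma(J) \ge$ `minsupp`,
and a frequent $J$ is *closed* when no proper superset has the same support.
Closed itemsets are the canonical lossless compression of the frequent set:
every frequent itemset's support is recoverable from them.

The same objects have a biclustering reading. A *bicluster* is a pair (row
set, column set) whose induced submatrix is all ones; it is
*inclusion-maximal* when neither side can be extended. With a minimum row
count imposed, inclusion-maximal biclusters and frequent closed itemsets are
in bijection: the itemset is the column set, and the row set is the set of
all supporting transactions. Row-maximality is automatic (the row set is
*all* supporting rows by definition); column-maximality is exactly
closedness. The package exposes both views (`extract_closed()`,
`itemset_to_bicluster()`), and the test suite asserts the bijection
literally against an independent enumerator.

## The algorithm

Mining is level-wise in itemset size $k$, following the classic
candidate-generation / support-counting scheme, but every step is matrix
algebra on the bit-table rather than database scans over stored itemsets:

* **Supports as inner products.** The support of the itemset encoded by
  column $b_j$ is $b_j^\top b_j$ (the count of ones), and the support of the
  union of the itemsets encoded by columns $i$ and $j$ is the $(i,j)$ entry
  of the cross-product matrix $S = (B^{k-1})^\top B^{k-1}$. One `crossprod()`
  per level therefore yields the supports of *all* joinable candidates at
  once.
* **Candidate columns as Hadamard products.** The occurrence column of a
  candidate $(k{+}1)$-itemset is the elementwise (AND) product of its two
  parents' columns, so the next level's table never requires revisiting
  $B^0$.
* **Prefix join.** Two frequent $(k{-}1)$-itemsets are joinable when their
  lexicographically ordered first $k-2$ item indices agree and their last
  items differ. The index table $L^{k-1}$ (one strictly increasing tuple of
  original item indices per column) is kept lexicographically sorted, so
  joinable pairs live in contiguous prefix blocks and are enumerated only
  there.
* **Shrinking the table.** Columns below `minsupp` are erased, and rows
  whose sum drops to zero — transactions supporting no frequent itemset of
  the current size — are deleted, with the original transaction identity
  preserved in `row_ids`. Both are pure optimizations: the reported
  (itemset, support) pairs are provably unchanged, and the suite verifies
  this by toggling them.

Closed extraction then needs only immediate supersets: support is
anti-monotone, so if any proper superset of $J$ ties $\sigma(J)$, some
immediate superset does, and since that superset's support is $\ge$
`minsupp` it is itself in the mined levels. The brute-force oracle
(`enumerate_closed_bruteforce()`) instead applies the definition against
*all* proper supersets; agreement between the two on every tested instance
validates the argument.

### A fused level step

`join_candidates()` materializes the occurrence column of every joinable
candidate, which is the transparent, modular reading of the algorithm and is
what the unit tests exercise. Inside `mine_frequent()` the level step is
fused: candidate supports are read off $S$ *before* any column is built, and
Hadamard columns are materialized only for candidates already known
frequent. The two routes are output-identical (tested on every random
instance); only the memory footprint differs. This is what lets a
$1000 \times 1000$ run at 10% density pass under the default memory guard:
at `minsupp = 20` roughly half a million candidate pairs are scored through
one cross-product, but only the few thousand frequent ones ever become
columns.

## Tunable parameters

* `minsupp` — minimum support. Internally an absolute transaction count
  (supports are integer counts, so all arithmetic is exact); a fraction in
  (0,1) is accepted for convenience and converted by
  `ceiling(fraction * N0)`.
* `min_items` (default 1) — minimum itemset size reported. The default is
  the most inclusive convention: single-item closed sets are reported.
  Raising it to a block width turns the output into a planted-bicluster
  detector.
* `max_level` — optional cap on itemset size; mining stops after that level.
* `subset_filter` (default TRUE) — discard candidates with an infrequent
  $(k{-}1)$-subset before support counting (downward closure). Output-
  invariant by construction; the toggle exists so tests can prove it.
* `delete_zero_rows` (default TRUE) — drop dead transactions per level.
  Also output-invariant and toggleable.
* `max_cells` (default 5e6) — the memory guard. Dense candidate columns are
  the method's stated trade-off; a level that would materialize more than
  `max_cells` entries aborts with an instructive error instead of exhausting
  memory. Raise it deliberately for large dense problems.

## Binarization

`binarize()` converts a real-valued genes-by-samples matrix into the level-0
bit-table with a fold-change cutoff (default 2, i.e. twofold):

* `scale = "ratio"` (default): values are expression ratios; a call is 1
  when the value is `>= cutoff` (`mode = "up"`), or additionally when it is
  `<= 1/cutoff` (`mode = "abs"`, calling down-regulation too).
* `scale = "log2"`: values are log2 ratios; the thresholds become
  `log2(cutoff)` and `|x| >= log2(cutoff)`.

Whether "twofold change" should call down-regulated entries is genuinely
convention-dependent, so both modes are explicit arguments rather than a
silent choice; the default is up-calls only. Missing entries are mapped to 0
(absence of evidence of expression) and counted in a warning. Binarization
is a pure entrywise function — it commutes with row/column permutation —
and its call density is non-increasing in the cutoff; both properties are
tested.

## Synthetic data

`random_binary()` draws each entry independently 1 with a given density —
the uniform-density regime used for the package's scaling and equivalence
checks — and `implant_blocks()` plants all-ones blocks (optionally degraded
by entrywise dropout noise) for exact-recovery tests. Both are
seed-addressable with a fixed, fully specified generator (Mersenne-Twister,
inversion sampling), so every downstream count in this package is
reproducible bit-for-bit given the seed. No canonical realization of "a
random 1000×1000 matrix at 10% density" exists, which is precisely why
published pattern counts on such matrices are irreproducible without the
seed; here the seed is always surfaced.

These generators emulate only the *combinatorial* structure of binarized
expression data (marginal density, planted all-ones modules). They do not
model gene-gene correlation, sample batch structure, or dropout patterns of
real single-cell data, so passing equivalence and recovery tests
demonstrates algorithmic correctness, not biological fidelity of patterns
on real matrices.

## Numerical and design choices

* **Integer arithmetic throughout.** Entries are small integers and supports
  are integer counts; no tolerance appears anywhere. Cross-products go
  through BLAS in double precision, but all values are exact integers far
  below 2^53 and are coerced back to integer.
* **Ordering and ties.** Items are densely re-indexed in first-appearance
  order at input, candidate tuples and all outputs are kept in lexicographic
  order of original item indices, and result files sort by (size,
  lexicographic). Runs are therefore byte-reproducible; there are no
  arbitrary tie-breaks.
* **Degenerate inputs.** Duplicate transactions add support; duplicate item
  columns are legal and collapse into a single closed itemset carrying both
  labels; an all-zero column is simply infrequent; empty tables and empty
  levels propagate as empty results, not errors.
* **Orientation.** Rows are transactions. A `transpose` flag at the I/O and
  binarization layer lets the user decide whether genes or samples play the
  transaction role; the package never guesses.
* **Output indexing.** Transaction ids in result files are 0-based positions
  in the input file (the itemset-mining community convention), while
  MatrixMarket files keep their native 1-based coordinates.

## Validation problem sizes

The shipped suite validates the pipeline by exact equivalence with
brute-force enumeration on 300 seeded random instances (5–25 transactions,
4–15 items, density 0.05–0.6, minsupp 1–5), by hand-derived toy tables, by
exact recovery of 1–3 planted blocks, and by a seeded 1000×1000 run at 10%
density and `minsupp = 20` whose output is spot-checked with the independent
closedness verifier. The brute-force enumerators cap the item count at 24
(tests stay at ≤ 15) to keep the $2^m$ enumeration tractable.

## Limitations

* Dense integer columns, not compressed bitsets: memory is the stated
  trade-off for the simplicity of the algebra, bounded by the `max_cells`
  guard rather than by word-level popcount tricks.
* Exact, noise-free patterns only: a bicluster is an all-ones submatrix.
  Noise-tolerant bicluster definitions are out of scope.
* Mining is single-threaded and in-memory; out-of-core tables are not
  supported.
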