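# bitbiclust

Exhaustive discovery of **frequent closed itemsets** — equivalently,
**inclusion-maximal biclusters** — in high-dimensional binary data, with all
support counting done by matrix algebra on a bit-table.

## The problem and who this is for

A binary matrix with transactions as rows and items as columns arises both
in market-basket analysis and in transcriptomics, where a real-valued
expression matrix is first thresholded into expressed/not-expressed calls
(genes as transactions, samples as items, or the transpose). Two classic
questions coincide on such data:

* *Frequent closed itemset mining*: find every set of columns J supported by
  at least `minsupp` rows (support σ(J) = number of rows with a 1 in every
  column of J) such that no proper superset of J has the same support.
* *Biclustering*: find every inclusion-maximal all-ones submatrix with at
  least `minsupp` rows.

With the row threshold imposed, the two answers are in bijection: the
closed itemset is the bicluster's column set and the bicluster's row set is
all supporting transactions. `bitbiclust` mines these patterns exactly —
no heuristics, no sampling — for anyone analysing binarized expression
data, presence/absence matrices, or transaction databases.

## The method

Mining is level-wise in itemset size k on the bit-table B⁰:

* the support of the itemset encoded by column *b* is the inner product
  *bᵀb* (the count of ones);
* the supports of **all** candidate (k+1)-itemsets come from one
  cross-product per level, S = (Bᵏ)ᵀBᵏ, whose (i, j) entry counts the rows
  where columns i and j are both 1;
* a candidate's occurrence column is the Hadamard (elementwise AND) product
  of its two parents' columns, so the original database is never rescanned;
* candidates are generated by the lexicographic prefix join (two frequent
  (k−1)-itemsets join when their first k−2 ordered item indices agree),
  infrequent columns are erased, and rows whose sum drops to zero are
  deleted, with an index table Lᵏ tracking each column's original item
  indices.

Closed itemsets are extracted by eliminating every frequent itemset that has
an immediate frequent superset of equal support (sufficient, because support
is anti-monotone). Brute-force enumerators that apply the definitions
literally over all 2^m subsets ship alongside the miner and serve as its
ground truth in the test suite.

## Worked example

Four transactions over items A, B, C — t1 = ABC, t2 = AB, t3 = AC,
t4 = BC — mined at `minsupp = 2`:

```r
library(bitbiclust)
B <- bit_table(rbind(c(1, 1, 1),
                     c(1, 1, 0),
                     c(1, 0, 1),
                     c(0, 1, 1)), item_labels = c("A", "B", "C"))
res <- mine_closed(B, minsupp = 2)
res$closed
#>   size support items item_idx    rows
#> 1    1       3     A        1 1, 2, 3
#> 2    1       3     B        2 1, 2, 4
#> 3    1       3     C        3 1, 3, 4
#> 4    2       2   A B     1, 2    1, 2
#> 5    2       2   A C     1, 3    1, 3
#> 6    2       2   B C     2, 3    1, 4
```

Six closed itemsets: each single item (support 3 — present in three
transactions) and each pair (support 2). The triple ABC has support 1 and is
filtered out at this threshold. Every line is also an inclusion-maximal
bicluster; for instance `itemset_to_bicluster(c("A", "B"), B)` is the 2×2
all-ones block on rows {t1, t2}:

```r
itemset_to_bicluster(c("A", "B"), B)
#> bicluster: 2 rows x 2 cols [A B]
```

For expression data, `binarize()` turns a genes-by-samples matrix into the
bit-table with a fold-change cutoff (default twofold, up-calls only;
`mode = "abs"` also calls down-regulation), and `random_binary()` /
`implant_blocks()` generate seeded synthetic inputs. A command-line front
end with `mine`, `binarize`, `synth` and `oracle` subcommands is installed
at `inst/scripts/bitbiclust.R`.

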