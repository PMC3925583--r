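test_that("frequent singletons erase infrequent columns and dead rows", {
  l1 <- frequent_singletons(toy4(), mining_config(2))
  expect_identical(ncol(l1$bit_table$values), 3L)
  expect_identical(l1$supports, c(3L, 3L, 3L))
  expect_identical(nrow(l1$bit_table$values), 4L)
  expect_identical(l1$index_table[, 1], 1:3)

  l1 <- frequent_singletons(toy4(), mining_config(4))
  expect_identical(ncol(l1$bit_table$values), 0L)

  ones <- bit_table(matrix(1L, 5, 4))
  l1 <- frequent_singletons(ones, mining_config(5))
  expect_identical(ncol(l1$bit_table$values), 4L)
  expect_identical(l1$supports, rep(5L, 4))

  # a row supporting no frequent item is deleted and row_ids follow
  B <- bit_table(rbind(c(1, 0), c(1, 0), c(0, 1)))
  l1 <- frequent_singletons(B, mining_config(2))
  expect_identical(l1$bit_table$row_ids, c(1L, 2L))
})

fake_level <- function(index_table, n_rows = 4L) {
  # a syntactically valid level whose columns are irrelevant to the join
  bitbiclust:::new_level_result(
    ncol(index_table), matrix(1L, n_rows, nrow(index_table)),
    seq_len(n_rows), index_table, rep(n_rows, nrow(index_table)))
}

test_that("candidates join only inside shared-prefix blocks", {
  # L2 = {AB, AC, AD, BC}: AB/AC/AD share prefix A; BC has no partner
  L2 <- fake_level(rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(2L, 3L)))
  cand <- join_candidates(L2, subset_filter = FALSE)
  expect_identical(cand$tuples,
                   rbind(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L)))
  # with downward-closure filtering only ABC survives (BD, CD infrequent)
  cand_f <- join_candidates(L2, subset_filter = TRUE)
  expect_identical(cand_f$tuples, rbind(c(1L, 2L, 3L)))

  # level 1: empty shared prefix, all pairs
  L1 <- fake_level(cbind(1:3))
  cand <- join_candidates(L1)
  expect_identical(cand$tuples, rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)))

  # no shared 1-prefix, no candidates
  L2 <- fake_level(rbind(c(1L, 2L), c(3L, 4L)))
  expect_identical(nrow(join_candidates(L2)$tuples), 0L)

  bad <- fake_level(rbind(c(2L, 3L), c(1L, 2L)))
  expect_error(join_candidates(bad), "lexicographically")
})

test_that("candidate columns are the Hadamard products of their parents", {
  l1 <- frequent_singletons(toy4(), mining_config(2))
  cand <- join_candidates(l1)
  V <- l1$bit_table$values
  expect_identical(cand$columns[, 1], V[, 1] * V[, 2])   # AB
  expect_identical(cand$columns[, 3], V[, 2] * V[, 3])   # BC
})

test_that("prune keeps frequent candidates and deletes zero rows", {
  l1 <- frequent_singletons(toy4(), mining_config(3))
  cand <- join_candidates(l1)                 # AB:2 AC:2 BC:2
  l2 <- prune(cand, mining_config(3))
  expect_identical(ncol(l2$bit_table$values), 0L)

  l2 <- prune(cand, mining_config(2))
  expect_identical(l2$supports, c(2L, 2L, 2L))
  expect_identical(nrow(l2$bit_table$values), 4L)  # every row holds a pair

  l1 <- frequent_singletons(toy3(), mining_config(2))
  l2 <- prune(join_candidates(l1), mining_config(2))
  expect_identical(l2$index_table, rbind(c(1L, 2L)))   # only AB
  expect_identical(l2$supports, 3L)
  expect_identical(nrow(l2$bit_table$values), 3L)
})

test_that("mine_frequent reproduces exhaustive enumeration on the toys", {
  cfg <- mining_config(2)
  freq <- frequent_itemsets(mine_frequent(toy4(), cfg))
  expect_identical(nrow(freq), 6L)
  expect_identical(itemset_keys(freq),
                   itemset_keys(enumerate_frequent_bruteforce(toy4(), cfg)))

  cfg1 <- mining_config(1)
  freq1 <- frequent_itemsets(mine_frequent(toy4(), cfg1))
  expect_identical(nrow(freq1), 7L)
  expect_identical(itemset_keys(freq1),
                   itemset_keys(enumerate_frequent_bruteforce(toy4(), cfg1)))

  empty <- bit_table(matrix(integer(0), 0, 0))
  expect_identical(length(mine_frequent(empty, cfg)), 0L)
})

test_that("fractional minsupp converts by ceiling against the table size", {
  a <- frequent_itemsets(mine_frequent(toy4(), mining_config(0.5)))
  b <- frequent_itemsets(mine_frequent(toy4(), mining_config(2)))
  expect_identical(itemset_keys(a), itemset_keys(b))
})

test_that("max_level caps itemset size", {
  levels <- mine_frequent(toy4(), mining_config(1, max_level = 2))
  expect_identical(length(levels), 2L)
})

test_that("the memory guard trips before materializing an oversized level", {
  B <- random_binary(30, 12, 0.8, seed = 5)
  expect_error(mine_frequent(B, mining_config(1, max_cells = 100)),
               "max_cells")
})

test_that("the fused level step equals the modular join-then-prune route", {
  for (s in 1:25) {
    inst <- random_instance(s)
    cfg <- mining_config(inst$minsupp)
    prev <- frequent_singletons(inst$B, cfg)
    while (ncol(prev$bit_table$values) > 0L) {
      fused <- bitbiclust:::next_level(prev, cfg)
      modular <- prune(join_candidates(prev, cfg$subset_filter), cfg)
      expect_identical(fused$index_table, modular$index_table)
      expect_identical(fused$supports, modular$supports)
      expect_identical(fused$bit_table$values, modular$bit_table$values)
      expect_identical(fused$bit_table$row_ids, modular$bit_table$row_ids)
      prev <- fused
    }
  }
})

test_that("every reported itemset's immediate subsets are reported with no smaller support", {
  for (s in 1:15) {
    inst <- random_instance(s)
    freq <- frequent_itemsets(mine_frequent(inst$B,
                                            mining_config(inst$minsupp)))
    key <- vapply(freq$item_idx, paste, character(1), collapse = ",")
    sup <- stats::setNames(freq$support, key)
    for (i in which(freq$size > 1)) {
      for (d in seq_len(freq$size[i])) {
        sub <- paste(freq$item_idx[[i]][-d], collapse = ",")
        expect_true(sub %in% key)
        expect_gte(sup[[sub]], freq$support[i])
      }
    }
  }
})
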