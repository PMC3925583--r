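test_that("closed extraction keeps exactly the itemsets with no equal-support superset", {
  res <- mine_closed(toy4(), 2)
  expect_identical(res$closed$items, c("A", "B", "C", "A B", "A C", "B C"))
  expect_identical(res$closed$support, c(3L, 3L, 3L, 2L, 2L, 2L))

  # A and B are absorbed by AB (equal support 3)
  res <- mine_closed(toy3(), 2)
  expect_identical(res$closed$items, "A B")
  expect_identical(res$closed$support, 3L)

  res <- mine_closed(toy3(), 1)
  expect_identical(res$closed$items, c("A B", "A B C"))
  expect_identical(res$closed$support, c(3L, 1L))
})

test_that("closed output is sorted by size then lexicographically and honors min_items", {
  res <- mine_closed(toy4(), 2)
  expect_identical(res$closed$size, c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_true(!is.unsorted(res$closed$size))

  res2 <- mine_closed(toy4(), 2, min_items = 2)
  expect_identical(res2$closed$items, c("A B", "A C", "B C"))
})

test_that("a closed itemset maps to its inclusion-maximal bicluster", {
  B <- toy4()
  b <- itemset_to_bicluster(c("A", "B"), B)
  expect_identical(b$rows, c(1L, 2L))
  expect_identical(b$labels, c("A", "B"))

  b <- itemset_to_bicluster("A", B)
  expect_identical(b$rows, c(1L, 2L, 3L))

  ones <- bit_table(matrix(1L, 3, 3))
  b <- itemset_to_bicluster(1:3, ones)
  expect_identical(b$rows, 1:3)
  expect_identical(b$cols, 1:3)

  zero <- bit_table(matrix(0L, 2, 2))
  expect_error(itemset_to_bicluster(1L, zero), "no transaction")
})

test_that("bicluster row sets preserve the itemset's support", {
  for (s in 1:10) {
    inst <- random_instance(s)
    res <- mine_closed(inst$B, inst$minsupp, biclusters = TRUE)
    expect_identical(vapply(res$biclusters, function(b) length(b$rows),
                            integer(1)),
                     res$closed$support)
    # distinct itemsets give distinct biclusters (injectivity)
    expect_identical(anyDuplicated(bicluster_keys(res$biclusters)), 0L)
  }
})

test_that("the independent closedness checker agrees with extraction", {
  expect_true(verify_closedness(c("A", "B"), toy3()))
  expect_false(verify_closedness("A", toy3()))   # sup(A)=3=sup(AB)
  single <- bit_table(matrix(c(1, 0, 1), ncol = 1))
  expect_true(verify_closedness(1L, single))     # no extensions exist

  for (s in 1:10) {
    inst <- random_instance(s)
    cfg <- mining_config(inst$minsupp)
    levels <- mine_frequent(inst$B, cfg)
    freq <- frequent_itemsets(levels)
    closed_keys <- itemset_keys(extract_closed(levels, cfg))
    for (i in seq_len(nrow(freq))) {
      k <- paste(paste(freq$item_idx[[i]], collapse = ","), freq$support[i],
                 sep = ":")
      expect_identical(verify_closedness(freq$item_idx[[i]], inst$B),
                       k %in% closed_keys)
    }
  }
})

test_that("closed sets shrink as minsupp grows", {
  for (s in 1:10) {
    inst <- random_instance(s)
    lo <- itemset_keys(mine_closed(inst$B, inst$minsupp)$closed)
    hi <- itemset_keys(mine_closed(inst$B, inst$minsupp + 2)$closed)
    expect_true(all(hi %in% lo))
  }
})
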