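test_that("brute-force frequent enumeration matches hand counts on the toys", {
  freq <- enumerate_frequent_bruteforce(toy4(), mining_config(2))
  expect_identical(freq$items, c("A", "B", "C", "A B", "A C", "B C"))
  expect_identical(freq$support, c(3L, 3L, 3L, 2L, 2L, 2L))

  expect_identical(nrow(enumerate_frequent_bruteforce(toy4(),
                                                      mining_config(4))), 0L)

  one <- enumerate_frequent_bruteforce(matrix(1L, 1, 1), mining_config(1))
  expect_identical(nrow(one), 1L)
  expect_identical(one$support, 1L)
})

test_that("literal all-supersets closedness matches hand counts on the toys", {
  closed <- enumerate_closed_bruteforce(toy4(), mining_config(2))
  expect_identical(closed$items, c("A", "B", "C", "A B", "A C", "B C"))

  closed <- enumerate_closed_bruteforce(toy3(), mining_config(2))
  expect_identical(closed$items, "A B")
  expect_identical(closed$support, 3L)

  # every column identical: a single closed itemset containing all items
  closed <- enumerate_closed_bruteforce(matrix(1L, 4, 3), mining_config(1))
  expect_identical(nrow(closed), 1L)
  expect_identical(closed$size, 3L)
  expect_identical(closed$support, 4L)
})

test_that("all-supersets and immediate-superset closedness agree everywhere", {
  # validates the anti-monotonicity argument behind extract_closed
  for (s in 1:40) {
    inst <- random_instance(s)
    cfg <- mining_config(inst$minsupp)
    expect_identical(
      itemset_keys(extract_closed(mine_frequent(inst$B, cfg), cfg)),
      itemset_keys(enumerate_closed_bruteforce(inst$B, cfg)))
  }
})

test_that("brute-force maximal biclusters match hand counts on the toys", {
  expect_identical(
    length(enumerate_maximal_biclusters_bruteforce(toy4(), min_rows = 2)),
    6L)
  expect_identical(
    enumerate_maximal_biclusters_bruteforce(matrix(0L, 4, 4)), list())
  ones <- enumerate_maximal_biclusters_bruteforce(matrix(1L, 4, 3))
  expect_identical(length(ones), 1L)
  expect_identical(ones[[1]]$rows, 1:4)
  expect_identical(ones[[1]]$cols, 1:3)
})

test_that("closed itemsets and maximal biclusters are in bijection", {
  for (s in 1:25) {
    inst <- random_instance(s)
    closed <- enumerate_closed_bruteforce(inst$B, mining_config(inst$minsupp))
    bcs <- enumerate_maximal_biclusters_bruteforce(inst$B,
                                                   min_rows = inst$minsupp)
    expect_identical(nrow(closed), length(bcs))
    expect_identical(
      sort(vapply(closed$item_idx, paste, character(1), collapse = ",")),
      sort(vapply(bcs, function(b) paste(b$cols, collapse = ","),
                  character(1))))
  }
})

test_that("the enumerators refuse tables above the item cap", {
  wide <- matrix(0L, 2, 25)
  expect_error(enumerate_frequent_bruteforce(wide, mining_config(1)), "cap")
  expect_error(enumerate_closed_bruteforce(wide, mining_config(1)), "cap")
  expect_error(enumerate_maximal_biclusters_bruteforce(wide), "cap")
})
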