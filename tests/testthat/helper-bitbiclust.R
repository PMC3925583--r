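# Shared fixtures: two tiny worked tables whose frequent/closed sets are
# known by hand, plus canonicalization helpers for set-equality assertions
# and the seeded random-instance generator used by the equivalence suites.

# t1=ABC, t2=AB, t3=AC, t4=BC
toy4 <- function() {
  bit_table(rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 1), c(0, 1, 1)),
            item_labels = c("A", "B", "C"))
}

# t1=AB, t2=AB, t3=ABC
toy3 <- function() {
  bit_table(rbind(c(1, 1, 0), c(1, 1, 0), c(1, 1, 1)),
            item_labels = c("A", "B", "C"))
}

# order-insensitive (itemset, support) fingerprint
itemset_keys <- function(df) {
  sort(paste(vapply(df$item_idx, paste, character(1), collapse = ","),
             df$support, sep = ":"))
}

bicluster_keys <- function(bcs) {
  sort(vapply(bcs, function(b) {
    paste(paste(b$rows, collapse = ","), paste(b$cols, collapse = ","),
          sep = "|")
  }, character(1)))
}

# instance s of the seeded random family: 5-25 transactions, 4-15 items,
# density 0.05-0.6, minsupp 1-5
random_instance <- function(s) {
  set.seed(1000L + s)
  nr <- sample(5:25, 1)
  nc <- sample(4:15, 1)
  d <- stats::runif(1, 0.05, 0.6)
  ms <- sample(1:5, 1)
  list(B = random_binary(nr, nc, d, seed = 2000L + s), minsupp = ms)
}
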