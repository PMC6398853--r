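test_that("worked example: one moved item separates the two partitions", {
  p1 <- c(1L, 1L, 2L, 2L)  # {{1,2},{3,4}}
  p2 <- c(1L, 2L, 2L, 2L)  # {{1},{2,3,4}}
  expect_identical(transfer_distance(p1, p2), 1L)
  expect_identical(transfer_distance(p2, p1), 1L)
  expect_equal(transfer_similarity(p1, p2), 1 - 1 / 3)
  expect_equal(mirkin_similarity(p1, p2), 1 - 6 / 16)  # c = 1, d = 2 pairs
})

test_that("solve_lsap handles forced optima and rejects bad input", {
  cost <- matrix(1, 4, 4) - diag(4)
  perm <- solve_lsap(cost)
  expect_identical(as.integer(perm), 1:4)
  expect_equal(attr(perm, "cost"), 0)
  expect_identical(as.integer(solve_lsap(matrix(3.5, 1, 1))), 1L)
  expect_error(solve_lsap(matrix(1, 2, 3)), "square")
  expect_error(solve_lsap(matrix(c(1, NA, 0, 1), 2, 2)), "finite")
  expect_error(solve_lsap(matrix(c(1, Inf, 0, 1), 2, 2)), "finite")
  expect_error(solve_lsap(1:4), "matrix")
})

test_that("solve_lsap attains the brute-force minimum on random matrices", {
  set.seed(7)
  for (rep in 1:60) {
    n <- sample(2:6, 1L)
    cost <- matrix(sample(-10:10, n * n, replace = TRUE), n, n)
    perm <- solve_lsap(cost)
    expect_true(!anyDuplicated(perm))
    expect_equal(attr(perm, "cost"), brute_lsap(cost)$cost)
  }
})

test_that("transfer distance matches the exhaustive matching oracle", {
  set.seed(11)
  for (rep in 1:120) {
    n <- sample(2:7, 1L)
    p1 <- random_partition(n, sample(1:4, 1L))
    p2 <- random_partition(n, sample(1:4, 1L))
    expect_identical(transfer_distance(p1, p2),
                     brute_transfer_distance(p1, p2))
  }
})

test_that("transfer distance is a metric on label-invariant partitions", {
  parts <- all_partitions(4L)  # all 15 partitions, exhaustive triples
  for (a in parts) {
    expect_identical(transfer_distance(a, a), 0L)
    for (b in parts) {
      dab <- transfer_distance(a, b)
      expect_identical(dab, transfer_distance(b, a))
      expect_lte(dab, length(a) - 1L)
      for (cc in parts) {
        expect_lte(dab, transfer_distance(a, cc) + transfer_distance(cc, b))
      }
    }
  }
  set.seed(3)
  for (rep in 1:40) {  # random triples at larger n
    n <- 50L
    a <- random_partition(n, 6L)
    b <- random_partition(n, 6L)
    cc <- random_partition(n, 6L)
    expect_lte(transfer_distance(a, b),
               transfer_distance(a, cc) + transfer_distance(cc, b))
  }
})

test_that("similarities live in [0,1] and detect identity up to relabeling", {
  set.seed(5)
  for (rep in 1:50) {
    n <- sample(2:8, 1L)
    p1 <- random_partition(n, 4L)
    p2 <- random_partition(n, 4L)
    ts <- transfer_similarity(p1, p2)
    ms <- mirkin_similarity(p1, p2)
    expect_gte(ts, 0); expect_lte(ts, 1)
    expect_gte(ms, 0); expect_lte(ms, 1)
    relab <- max(p1) + 1L - p1  # arbitrary relabeling
    expect_equal(mirkin_similarity(relab, p1), 1)
    expect_equal(transfer_similarity(relab, p1), 1)
    expect_equal(transfer_similarity(relab, p2), ts)
    expect_equal(mirkin_similarity(relab, p2), ms)
  }
  expect_equal(transfer_similarity(1:5, rep(1L, 5L)), 0)  # singletons vs block
})

test_that("Mirkin similarity matches pair counting and the Rand index", {
  skip_if_not_installed("e1071")
  set.seed(13)
  for (rep in 1:40) {
    n <- sample(3:8, 1L)
    p1 <- random_partition(n, 4L)
    p2 <- random_partition(n, 4L)
    ms <- mirkin_similarity(p1, p2)
    expect_equal(ms, brute_mirkin(p1, p2))
    # independent cross-check: MS = 1 - (1 - Rand) (N - 1) / N
    rand <- e1071::classAgreement(table(p1, p2))$rand
    expect_equal(ms, 1 - (1 - rand) * (n - 1) / n)
  }
})

test_that("canonicalization orders clusters by size then first member", {
  expect_identical(canonicalize_partition(c(3L, 3L, 1L)), c(1L, 1L, 2L))
  # tie in sizes: cluster containing the earliest item gets the lower id
  expect_identical(canonicalize_partition(c(2L, 1L, 2L, 1L)),
                   c(1L, 2L, 1L, 2L))
  set.seed(17)
  for (rep in 1:40) {
    p <- random_partition(sample(2:12, 1L), 5L)
    cp <- canonicalize_partition(p)
    expect_identical(canonicalize_partition(cp), cp)  # idempotent
    sizes <- cluster_sizes(cp)
    expect_true(all(diff(sizes) <= 0))
    expect_identical(sort(unique(cp)), seq_len(max(cp)))
    expect_identical(transfer_distance(p, cp), 0L)  # same partition
  }
})

test_that("partition overlap has the right margins", {
  set.seed(19)
  p1 <- random_partition(20L, 4L)
  p2 <- random_partition(20L, 3L)
  ov <- partition_overlap(p1, p2)
  expect_identical(rowSums(ov), as.double(cluster_sizes(p1)))
  expect_identical(colSums(ov), as.double(cluster_sizes(p2)))
  expect_identical(sum(ov), 20L)
})

test_that("partition serialization round-trips and canonicalizes on load", {
  p <- c(2L, 2L, 1L, 2L)
  for (ext in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_partition(p, path)
    back <- read_partition(path)
    expect_identical(back, canonicalize_partition(p))
  }
})

test_that("mismatched or degenerate inputs are rejected", {
  expect_error(transfer_distance(c(1, 1), c(1, 2, 2)), "length")
  expect_error(transfer_similarity(1L, 1L), "at least 2")
  expect_error(mirkin_similarity(c(1, 2), c(1, 1, 2)), "length")
  expect_error(as_partition(c(1, NA)), "missing")
  expect_error(as_partition(c(1.5, 2)), "whole numbers")
  expect_error(as_partition(integer(0)), "at least one")
})
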