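test_that("initialisation yields singletons whose find costs 1", {
  s <- mfset_initial(1)
  expect_equal(s$parent, 1L)
  s5 <- mfset_initial(5)
  expect_equal(s5$parent, 1:5)
  expect_equal(s5$size, rep(1L, 5))
  for (x in 1:5) expect_equal(mfset_find(s5, x)$comparisons, 1)
  expect_error(mfset_initial(0))
  expect_error(mfset_find(s5, 6), "unknown element")
})

test_that("merge is union by size with second-under-first tie break", {
  s <- mfset_initial(2)
  mfset_merge(s, 1, 2)
  expect_equal(s$parent, c(1L, 1L))       # tie: second under first
  expect_equal(s$size[1], 2L)

  s2 <- mfset_initial(4)
  mfset_merge(s2, 1, 2); mfset_merge(s2, 1, 3)   # size-3 tree rooted at 1
  mfset_merge(s2, 4, 1)                           # singleton attaches below
  expect_equal(s2$parent[4], 1L)
  expect_equal(s2$size[1], 4L)

  before <- s2$parent
  mfset_merge(s2, 1, 2)                           # same set: no-op
  expect_equal(s2$parent, before)
  expect_error(mfset_merge(s2, 1, 9), "unknown element")
})

test_that("find compresses the walked path and counts endpoints inclusively", {
  s <- mfset_from_parents(c(1L, 1L, 2L, 3L))     # chain 1 <- 2 <- 3 <- 4
  res <- mfset_find(s, 4)
  expect_equal(res$comparisons, 4)
  expect_equal(res$root, 1)
  expect_equal(s$parent, c(1L, 1L, 1L, 1L))      # whole path re-parented
  expect_equal(mfset_find(s, 4)$comparisons, 2)
  expect_equal(mfset_find(s, 1)$comparisons, 1)  # root self-find, no change
  expect_equal(s$find_log, c(4L, 2L, 1L))
})

test_that("compression matches a brute-force re-parent simulation on small forests", {
  set.seed(123)
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    s <- mfset_initial(n)
    shadow <- s$parent
    for (m in seq_len(sample(1:7, 1))) {
      ab <- sample(n, 2)
      mfset_merge(s, ab[1], ab[2])
    }
    shadow <- s$parent                    # same pre-find shape
    for (f in 1:3) {
      x <- sample(n, 1)
      res <- mfset_find(s, x)
      oracle <- oracle_mfset_find(shadow, x)
      expect_equal(res$comparisons, oracle$comparisons)
      expect_equal(res$root, oracle$root)
      expect_equal(s$parent, oracle$parents)
      shadow <- oracle$parents
    }
  }
})

test_that("union by size bounds tree height logarithmically before compression", {
  set.seed(5)
  for (rep in 1:10) {
    n <- 32
    s <- mfset_initial(n)
    for (m in 1:40) {
      ab <- sample(n, 2)
      mfset_merge(s, ab[1], ab[2])
    }
    depth_of <- function(x) {
      d <- 1L
      while (s$parent[x] != x) { x <- s$parent[x]; d <- d + 1L }
      d
    }
    for (x in seq_len(n)) {
      root <- x; while (s$parent[root] != root) root <- s$parent[root]
      expect_lte(depth_of(x), floor(log2(s$size[root])) + 1)
    }
  }
})

test_that("find changes neither set membership nor its own cost direction", {
  set.seed(9)
  s <- mfset_initial(12)
  for (m in 1:8) { ab <- sample(12, 2); mfset_merge(s, ab[1], ab[2]) }
  roots_before <- vapply(1:12, function(x) {
    r <- x; while (s$parent[r] != r) r <- s$parent[r]; r
  }, integer(1))
  for (x in 1:12) {
    costs <- vapply(1:3, function(i) mfset_find(s, x)$comparisons, integer(1))
    expect_true(all(diff(costs) <= 0))
  }
  roots_after <- vapply(1:12, function(x) mfset_find(s, x)$root, integer(1))
  expect_equal(roots_after, roots_before)
})

test_that("the baseline curve over trie positions settles at 2", {
  # single word: its positions are one set, finds cost at most 2
  cv <- mfset_asl_curve(rep("abcdef", 1), passes = 5)
  expect_true(all(diff(cv$comparisons) <= 0))
  expect_equal(tail(cv$comparisons, 1), 2)
  expect_equal(nrow(mfset_asl_curve("abc", passes = 0)), 0)
  expect_error(mfset_asl_curve(character(0)), "non-empty")
})

test_that("trie positions enumerate distinct prefixes exactly", {
  tp <- trie_positions(c("netbeans", "network", "netbeans"))
  expect_equal(tp$n, oracle_prefix_count(c("netbeans", "network")))
  expect_equal(length(tp$paths), 2)
  expect_equal(tp$paths[["netbeans"]][1:3], tp$paths[["network"]][1:3])
  expect_equal(tp$terminals[["netbeans"]], tp$paths[["netbeans"]][8])
})
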