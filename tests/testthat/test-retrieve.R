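test_that("retrieving a single node counts depth+1 and rewires its ancestors", {
  net <- intra_network()
  memorize_word(net, "netbeans")
  path <- word_record(net, "netbeans")$path
  res <- retrieve_node(net, "netbeans", 4)  # the "b", depth 4
  expect_identical(res$status, "success")
  expect_equal(res$comparisons, 5)
  # b and its former ancestors t, e, n all hang off the root now
  for (i in 1:4) expect_equal(node_depth(net, path[i]), 1)
  # the second "e" (child of b) followed its parent up
  expect_equal(node_depth(net, path[5]), 2)
  expect_identical(res$output, c("n", "e", "t", "b"))
})

test_that("a node already at depth 1 costs 2 and moves nothing", {
  net <- intra_network()
  memorize_word(net, "ab")
  res1 <- retrieve_node(net, "ab", 1)
  expect_equal(res1$comparisons, 2)
  expect_length(res1$rewired, 0)
})

test_that("word retrieval compresses the whole path to the root", {
  net <- intra_network()
  memorize_word(net, "netbeans")
  res <- retrieve_word(net, "netbeans")
  expect_identical(res$status, "success")
  expect_equal(res$comparisons, 9)
  expect_identical(res$output, strsplit("netbeans", "")[[1]])
  for (id in word_record(net, "netbeans")$path) {
    expect_equal(node_depth(net, id), 1)
  }
  expect_equal(retrieve_word(net, "netbeans")$comparisons, 2)
})

test_that("absent words fail without side effects", {
  net <- intra_network()
  memorize_words(net, c("netbeans", "network"))
  before <- all_depths(net)
  res <- retrieve_word(net, "zebra")
  expect_identical(res$status, "failure")
  expect_length(res$output, 0)
  expect_identical(all_depths(net), before)
  # an unregistered superstring also fails
  expect_identical(retrieve_word(net, "networks")$status, "failure")
  # out-of-range node position fails without side effects
  expect_identical(retrieve_node(net, "network", 50)$status, "failure")
  expect_identical(retrieve_node(net, "ghost", 1)$status, "failure")
  expect_identical(all_depths(net), before)
})

test_that("learn-on-fail memorizes the absent word after the failed search", {
  net <- intra_network()
  memorize_word(net, "net")
  res <- retrieve_word(net, "nets", learn_on_fail = TRUE)
  expect_identical(res$status, "failure")
  expect_identical(retrieve_word(net, "nets")$status, "success")
})

test_that("recognition answers membership and still strengthens", {
  net <- intra_network()
  memorize_word(net, "network")
  expect_true(recognize(net, "network")$found)
  expect_false(recognize(net, "networks")$found)
  expect_equal(retrieve_word(net, "network")$comparisons, 2)
})

test_that("retrieval comparisons match a geodesic oracle on the edge list", {
  net <- intra_network()
  memorize_word(net, "netbeans")
  memorize_word(net, "network")
  tsv <- tempfile(fileext = ".tsv")
  write_edge_tsv(net, tsv)
  edges <- read.table(tsv, sep = "\t", stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  terminal <- word_record(net, "network")$terminal
  oracle <- as.integer(igraph::distances(g, v = "sn", to = terminal)) + 1L
  expect_equal(retrieve_word(net, "network")$comparisons, oracle)
})

test_that("compression never increases any node's depth", {
  set.seed(7)
  words <- random_words(20, 7)
  net <- intra_network()
  memorize_words(net, words)
  for (i in 1:40) {
    before <- all_depths(net)
    w <- sample(registered_words(net), 1)
    if (i %% 4 == 0) retrieve_node(net, w, sample(nchar(w), 1)) else retrieve_word(net, w)
    after <- all_depths(net)
    expect_true(all(after[names(before)] <= before))
  }
})

test_that("repeated retrieval of one word is non-increasing in cost", {
  set.seed(11)
  words <- random_words(15, 11)
  net <- intra_network()
  memorize_words(net, words)
  for (w in unique(words)) {
    costs <- vapply(1:4, function(i) retrieve_word(net, w)$comparisons, integer(1))
    expect_true(all(diff(costs) <= 0))
    expect_equal(costs[4], 2)
  }
})

test_that("retrieval on a chain matches merge-find-set compression element for element", {
  word <- "abcdefgh"
  L <- nchar(word)
  schedule <- c(L, 3L, L, 5L, 1L, 5L, 7L)
  net <- intra_network()
  memorize_word(net, word)
  # chain of L+1 elements: element 1 is the root (the super node), element
  # i+1 holds the word's i-th letter
  s <- mfset_from_parents(c(1L, seq_len(L)))
  for (pos in schedule) {
    smirn_cost <- retrieve_node(net, word, pos)$comparisons
    mf_cost <- mfset_find(s, pos + 1L)$comparisons
    expect_equal(smirn_cost, mf_cost)
  }
})
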