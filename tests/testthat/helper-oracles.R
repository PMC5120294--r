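# Brute-force oracles kept deliberately independent of the package internals.

# number of distinct prefixes across a word list (= expected letter-node count)
oracle_prefix_count <- function(words) {
  prefixes <- character()
  for (w in unique(words)) {
    for (i in seq_len(nchar(w))) prefixes <- c(prefixes, substr(w, 1, i))
  }
  length(unique(prefixes))
}

# all prefix strings of a word list (canonical trie shape, id-free)
oracle_prefix_set <- function(words) {
  out <- character()
  for (w in unique(words)) {
    for (i in seq_len(nchar(w))) out <- c(out, substr(w, 1, i))
  }
  sort(unique(out))
}

# prefix strings present in a network's lexical trie, by walking trie links
trie_prefix_set <- function(net) {
  out <- character()
  walk <- function(id, acc) {
    trie <- get(id, envir = net$nodes)$trie
    for (i in seq_along(trie)) {
      s <- paste0(acc, names(trie)[i])
      out <<- c(out, s)
      walk(unname(trie[i]), s)
    }
  }
  walk("sn", "")
  sort(out)
}

# plain re-parenting simulation of find-with-compression on a parent vector;
# returns the new parent vector and the comparison count
oracle_mfset_find <- function(parents, x) {
  path <- x
  while (parents[x] != x) {
    x <- parents[x]
    path <- c(path, x)
  }
  root <- x
  for (v in path) parents[v] <- root
  parents[root] <- root
  list(parents = parents, comparisons = length(path), root = root)
}

# deterministic random lowercase words
random_words <- function(n, seed, min_len = 1, max_len = 9) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(letters[1:6], sample(min_len:max_len, 1), replace = TRUE),
          collapse = "")
  }, character(1))
}

# depth of every letter node, named by id
all_depths <- function(net) {
  ids <- node_ids(net)
  setNames(vapply(ids, function(i) node_depth(net, i), integer(1)), ids)
}
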