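#' Create an empty intra-modular memory network
#'
#' The intra-modular network is a rooted inverted tree of letter nodes hanging
#' under a symbol-less super node `"sn"` (the sole input/output point). Each
#' node carries two kinds of links: a *physical* parent pointer, which
#' retrieval strengthening may rewire onto the root, and a *lexical* child
#' index (one child per symbol), which records the trie structure laid down at
#' memorization time and is only ever altered by forgetting. Prefix matching
#' during memorization follows the lexical index, so flattening the physical
#' tree never garbles the stored vocabulary.
#'
#' The network is an environment and is modified in place by
#' [memorize_word()], [retrieve_word()] and [forget_tick()].
#'
#' @param alphabet character vector of admissible single-symbol tokens.
#'   Defaults to the lowercase letters; any token set (e.g. musical tones)
#'   works.
#' @return an object of class `smirn_intra`.
#' @examples
#' net <- intra_network()
#' memorize_word(net, "network")
#' node_count(net)
#' @export
intra_network <- function(alphabet = letters) {
  stopifnot(is.character(alphabet), length(alphabet) >= 1L,
            all(nchar(alphabet) == 1L), !anyDuplicated(alphabet))
  net <- new.env(parent = emptyenv())
  net$nodes <- new.env(parent = emptyenv())
  net$words <- new.env(parent = emptyenv())
  net$word_order <- character()
  net$alphabet <- alphabet
  net$clock <- 0L
  net$next_id <- 0L
  assign("sn", list(id = "sn", symbol = NA_character_, parent = NA_character_,
                    lex_parent = NA_character_, children = character(),
                    trie = character(), virtual = FALSE, last_access = 0L),
         envir = net$nodes)
  class(net) <- "smirn_intra"
  net
}

.node <- function(net, id) get(id, envir = net$nodes, inherits = FALSE)

.node_set <- function(net, node) assign(node$id, node, envir = net$nodes)

.node_exists <- function(net, id) {
  exists(id, envir = net$nodes, inherits = FALSE)
}

.new_node <- function(net, symbol, parent_id, virtual = FALSE) {
  net$next_id <- net$next_id + 1L
  id <- paste0("n", net$next_id)
  assign(id, list(id = id, symbol = symbol, parent = parent_id,
                  lex_parent = if (virtual) NA_character_ else parent_id,
                  children = character(), trie = character(),
                  virtual = virtual, last_access = net$clock),
         envir = net$nodes)
  p <- .node(net, parent_id)
  p$children <- c(p$children, id)
  if (!virtual) p$trie[symbol] <- id
  .node_set(net, p)
  id
}

.delete_node <- function(net, id) {
  nd <- .node(net, id)
  p <- .node(net, nd$parent)
  p$children <- setdiff(p$children, id)
  .node_set(net, p)
  if (!nd$virtual && !is.na(nd$lex_parent) && .node_exists(net, nd$lex_parent)) {
    lp <- .node(net, nd$lex_parent)
    lp$trie <- lp$trie[lp$trie != id]
    .node_set(net, lp)
  }
  rm(list = id, envir = net$nodes)
}

.reparent <- function(net, id, new_parent) {
  nd <- .node(net, id)
  if (identical(nd$parent, new_parent)) return(invisible())
  old <- .node(net, nd$parent)
  old$children <- setdiff(old$children, id)
  .node_set(net, old)
  np <- .node(net, new_parent)
  np$children <- c(np$children, id)
  .node_set(net, np)
  nd$parent <- new_parent
  .node_set(net, nd)
  invisible()
}

#' Depth of a node below the root
#'
#' Number of physical parent-pointer steps from the node to the root `"sn"`.
#' The root has depth 0.
#'
#' @param net a `smirn_intra` network.
#' @param id node identifier.
#' @return non-negative integer.
#' @export
node_depth <- function(net, id) {
  d <- 0L
  limit <- length(ls(net$nodes)) + 1L
  while (!is.na(.node(net, id)$parent)) {
    id <- .node(net, id)$parent
    d <- d + 1L
    if (d > limit) stop("cycle detected in parent pointers")
  }
  d
}

## all nodes on the physical root path of `ids`, excluding the root itself
.ancestor_closure <- function(net, ids) {
  seen <- new.env(parent = emptyenv())
  for (v in ids) {
    while (!identical(v, "sn") && !exists(v, envir = seen, inherits = FALSE)) {
      assign(v, TRUE, envir = seen)
      v <- .node(net, v)$parent
    }
  }
  ls(seen)
}

## Strengthening: snapshot the ancestor closure, then batch re-parent every
## member onto the root. Child links of moved nodes are untouched, so their
## descendants simply become shallower. Returns ids actually moved.
.strengthen <- function(net, ids) {
  closure <- .ancestor_closure(net, ids)
  moved <- character()
  for (v in closure) {
    if (!identical(.node(net, v)$parent, "sn")) {
      .reparent(net, v, "sn")
      moved <- c(moved, v)
    }
  }
  moved
}

## walk the lexical trie from the root; returns the matched node ids
.lexical_match <- function(net, symbols) {
  at <- "sn"
  matched <- character(length(symbols))
  k <- 0L
  for (s in symbols) {
    nxt <- unname(.node(net, at)$trie[s])
    if (is.na(nxt) || length(nxt) == 0L) break
    k <- k + 1L
    matched[k] <- nxt
    at <- nxt
  }
  matched[seq_len(k)]
}

.get_record <- function(net, word) {
  if (exists(word, envir = net$words, inherits = FALSE)) {
    get(word, envir = net$words, inherits = FALSE)
  } else NULL
}

.set_record <- function(net, rec) {
  if (!exists(rec$word, envir = net$words, inherits = FALSE)) {
    net$word_order <- c(net$word_order, rec$word)
  }
  assign(rec$word, rec, envir = net$words)
}

.drop_record <- function(net, word) {
  rm(list = word, envir = net$words)
  net$word_order <- setdiff(net$word_order, word)
}

#' Memorize a word
#'
#' Walks the lexical trie from the root along the word's symbols. The matched
#' prefix (an "old path") is strengthened exactly as retrieval would
#' strengthen it; the unmatched suffix is appended as a chain of new nodes
#' below the divergence node at its *current* position. Re-memorizing a fully
#' present word therefore adds no nodes but compresses its path, and
#' re-memorizing a partially forgotten word rebuilds the lost suffix and
#' removes the word's virtual node.
#'
#' @param net a `smirn_intra` network (or `smirn_inter`, in which case the
#'   word is routed to its region first).
#' @param word a single non-empty string over the network alphabet.
#' @param ... unused.
#' @return (invisibly) a list with `word`, `new_nodes` (count of nodes
#'   added), `rewired` (count of nodes moved to the root while strengthening
#'   the matched prefix) and `record`, the word's registry entry.
#' @export
memorize_word <- function(net, word, ...) UseMethod("memorize_word")

#' @export
memorize_word.smirn_intra <- function(net, word, ...) {
  stopifnot(is.character(word), length(word) == 1L)
  if (!nzchar(word)) stop("cannot memorize an empty word")
  symbols <- strsplit(word, "", fixed = TRUE)[[1]]
  bad <- setdiff(symbols, net$alphabet)
  if (length(bad)) {
    stop(sprintf("word '%s' contains symbol(s) outside the alphabet: %s",
                 word, paste(unique(bad), collapse = ", ")))
  }
  net$clock <- net$clock + 1L
  matched <- .lexical_match(net, symbols)
  k <- length(matched)
  rewired <- if (k > 0L) .strengthen(net, matched) else character()
  at <- if (k > 0L) matched[k] else "sn"
  new_ids <- character()
  if (k < length(symbols)) {
    for (s in symbols[(k + 1L):length(symbols)]) {
      at <- .new_node(net, s, at)
      new_ids <- c(new_ids, at)
    }
  }
  old <- .get_record(net, word)
  if (!is.null(old) && !is.na(old$virtual)) {
    .delete_node(net, old$virtual)
  }
  path <- c(matched, new_ids)
  for (v in path) {
    nd <- .node(net, v)
    nd$last_access <- net$clock
    .node_set(net, nd)
  }
  rec <- list(word = word, path = path, terminal = path[length(path)],
              last_access = net$clock, forgotten_suffix_len = 0L,
              virtual = NA_character_)
  .set_record(net, rec)
  invisible(list(word = word, new_nodes = length(new_ids),
                 rewired = length(rewired), record = rec))
}

#' Memorize a sequence of words
#'
#' @param net a `smirn_intra` or `smirn_inter` network.
#' @param words character vector of words, memorized in order (duplicates
#'   strengthen).
#' @return the network, invisibly.
#' @export
memorize_words <- function(net, words) {
  for (w in words) memorize_word(net, w)
  invisible(net)
}

#' Memorize every word of a text
#'
#' Convenience wrapper: [tokenize()] then [memorize_words()].
#'
#' @inheritParams memorize_words
#' @param text a character string.
#' @return the network, invisibly.
#' @export
memorize_text <- function(net, text) memorize_words(net, tokenize(text))

#' Count live letter nodes
#'
#' Number of letter nodes currently in the network, excluding the root and
#' any virtual (decay placeholder) nodes. Before any forgetting this equals
#' the number of distinct prefixes across all memorized words.
#'
#' @param net a `smirn_intra` network.
#' @return integer.
#' @export
node_count <- function(net) {
  ids <- setdiff(ls(net$nodes), "sn")
  sum(!vapply(ids, function(i) .node(net, i)$virtual, logical(1)))
}

#' Identifiers of live letter nodes (root and virtual nodes excluded)
#' @param net a `smirn_intra` network.
#' @return character vector of node ids.
#' @export
node_ids <- function(net) {
  ids <- setdiff(ls(net$nodes), "sn")
  ids[!vapply(ids, function(i) .node(net, i)$virtual, logical(1))]
}

#' Registered words, in registration order
#' @param net a `smirn_intra` network.
#' @return character vector.
#' @export
registered_words <- function(net) net$word_order

#' A word's registry record
#'
#' @param net a `smirn_intra` network.
#' @param word word string.
#' @return a list with `word`, `path` (node ids of the surviving prefix, in
#'   symbol order), `terminal` (last live path node, or the virtual node id
#'   once decay has begun), `last_access` tick and `forgotten_suffix_len`;
#'   `NULL` for unregistered words.
#' @export
word_record <- function(net, word) {
  rec <- .get_record(net, word)
  if (is.null(rec)) return(NULL)
  terminal <- if (!is.na(rec$virtual)) rec$virtual else rec$path[length(rec$path)]
  list(word = rec$word, path = rec$path, terminal = terminal,
       last_access = rec$last_access,
       forgotten_suffix_len = rec$forgotten_suffix_len)
}

#' @export
print.smirn_intra <- function(x, ...) {
  cat(sprintf("<smirn intra-modular network: %d letter node(s), %d word(s), clock %d>\n",
              node_count(x), length(x$word_order), x$clock))
  invisible(x)
}

#' Tokenize text into memorizable words
#'
#' Lowercases, strips everything that is not a letter or whitespace, splits on
#' whitespace and drops empty tokens. Order and duplicates are preserved.
#'
#' @param text character string (may be a vector; elements are joined by a
#'   space).
#' @return character vector of tokens.
#' @examples
#' tokenize("Complex network.")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text))
  text <- tolower(paste(text, collapse = " "))
  text <- gsub("[^a-z[:space:]]", "", text)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}
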