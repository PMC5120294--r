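#' @rdname retrieve_word
#' @export
retrieve_word <- function(net, word, ...) UseMethod("retrieve_word")

.retrieval_result <- function(status, comparisons, output = character(),
                              rewired = character()) {
  structure(list(status = status, comparisons = as.integer(comparisons),
                 output = output, rewired = rewired),
            class = "smirn_retrieval")
}

.path_symbols <- function(net, ids) {
  vapply(ids, function(i) .node(net, i)$symbol, character(1), USE.NAMES = FALSE)
}

#' Retrieve a word and strengthen its path
#'
#' Searches for a registered word. The search length (`comparisons`) of a
#' successful retrieval is the number of nodes visited walking the physical
#' parent chain from the root down to the word's terminal node, endpoints
#' inclusive, i.e. pre-call depth of the terminal plus one — the convention
#' under which a fully strengthened word costs exactly 2. As a side effect
#' every node on the word's path, together with all of their former proper
#' ancestors (root excepted, nodes already at depth 1 excepted), is
#' re-parented directly onto the root; child links of moved nodes are
#' preserved, so all descendants become shallower too.
#'
#' A partially forgotten word strengthens its surviving prefix the same way
#' and reports status `"partial"`. An absent word leaves the network unchanged
#' and reports `"failure"` with `comparisons` equal to the nodes visited along
#' the longest matching prefix (root inclusive) plus one failing probe; with
#' `learn_on_fail = TRUE` the word is then memorized as a fresh path.
#'
#' @param net a `smirn_intra` network (or `smirn_inter`; see [total_cost()]
#'   for the region-aware cost).
#' @param word word string.
#' @param learn_on_fail if `TRUE`, an absent word is memorized after the
#'   failed search (the search itself still reports `"failure"`).
#' @param ... unused.
#' @return an object of class `smirn_retrieval`: a list with `status`
#'   (`"success"`, `"partial"` or `"failure"`), `comparisons`, `output`
#'   (symbol path found, empty on failure) and `rewired` (ids moved to
#'   depth 1).
#' @examples
#' net <- intra_network()
#' memorize_word(net, "netbeans")
#' retrieve_word(net, "netbeans")$comparisons  # 9: depth 8 + root
#' retrieve_word(net, "netbeans")$comparisons  # 2: fully strengthened
#' @export
retrieve_word.smirn_intra <- function(net, word, learn_on_fail = FALSE, ...) {
  stopifnot(is.character(word), length(word) == 1L)
  net$clock <- net$clock + 1L
  rec <- .get_record(net, word)
  if (is.null(rec)) {
    symbols <- strsplit(word, "", fixed = TRUE)[[1]]
    matched <- tryCatch(.lexical_match(net, symbols), error = function(e) character())
    comparisons <- length(matched) + 2L
    if (isTRUE(learn_on_fail)) memorize_word(net, word)
    return(.retrieval_result("failure", comparisons))
  }
  terminal <- rec$path[length(rec$path)]
  comparisons <- node_depth(net, terminal) + 1L
  rewired <- .strengthen(net, rec$path)
  rec$last_access <- net$clock
  .set_record(net, rec)
  status <- if (rec$forgotten_suffix_len > 0L) "partial" else "success"
  .retrieval_result(status, comparisons, .path_symbols(net, rec$path), rewired)
}

#' Retrieve a single node of a stored word
#'
#' Locates the node at `position` (1-based) of a registered word's surviving
#' path, counts `depth + 1` comparisons under the pre-call parent pointers,
#' and strengthens the node together with its former proper ancestors exactly
#' as [retrieve_word()] does. An unknown word or an out-of-range position
#' yields a `"failure"` result (a single root consultation, `comparisons = 1`)
#' and leaves the network unchanged.
#'
#' @param net a `smirn_intra` network.
#' @param word registered word the node belongs to.
#' @param position 1-based index into the word's live path.
#' @return a `smirn_retrieval`; `output` is the symbol prefix up to the node.
#' @examples
#' net <- intra_network()
#' memorize_word(net, "netbeans")
#' retrieve_node(net, "netbeans", 4)$comparisons  # the "b": depth 4 + root
#' @export
retrieve_node <- function(net, word, position) {
  stopifnot(inherits(net, "smirn_intra"), is.character(word),
            length(word) == 1L, is.numeric(position), length(position) == 1L)
  net$clock <- net$clock + 1L
  rec <- .get_record(net, word)
  position <- as.integer(position)
  if (is.null(rec) || position < 1L || position > length(rec$path)) {
    return(.retrieval_result("failure", 1L))
  }
  v <- rec$path[position]
  comparisons <- node_depth(net, v) + 1L
  rewired <- .strengthen(net, v)
  rec$last_access <- net$clock
  .set_record(net, rec)
  .retrieval_result("success", comparisons,
                    .path_symbols(net, rec$path[seq_len(position)]), rewired)
}

#' Recognition query
#'
#' Yes/no membership query with the same strengthening side effects as
#' [retrieve_word()]. A partially forgotten word is *not* recognized (its
#' surviving prefix is still strengthened and the status is `"partial"`).
#'
#' @param net a `smirn_intra` or `smirn_inter` network.
#' @param word word string.
#' @param ... passed on to [retrieve_word()].
#' @return a list with `found` (logical) and `result` (the
#'   `smirn_retrieval`).
#' @export
recognize <- function(net, word, ...) {
  res <- retrieve_word(net, word, ...)
  list(found = identical(res$status, "success"), result = res)
}

#' @export
print.smirn_retrieval <- function(x, ...) {
  cat(sprintf("<retrieval %s: %d comparison(s), output '%s', %d node(s) rewired>\n",
              x$status, x$comparisons, paste(x$output, collapse = ""),
              length(x$rewired)))
  invisible(x)
}
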