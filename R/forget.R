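#' Forgetting configuration
#'
#' @param tau positive integer decay threshold, in ticks of the network's
#'   logical clock (one tick per memorize/retrieve operation or explicit
#'   [forget_tick()] call). A word untouched for more than `tau` ticks starts
#'   to decay.
#' @param enabled logical; disabled configurations make [forget_tick()] a
#'   no-op.
#' @return a list of class `smirn_forget_config`.
#' @export
forget_config <- function(tau = 1000L, enabled = TRUE) {
  tau <- as.integer(tau)
  stopifnot(length(tau) == 1L, !is.na(tau), tau >= 1L, is.logical(enabled))
  structure(list(tau = tau, enabled = enabled), class = "smirn_forget_config")
}

#' Advance time and decay stale words
#'
#' Increments the logical clock by one tick, then for every word whose last
#' access lies more than `cfg$tau` ticks in the past removes the deepest
#' remaining node of its path and advances the word's virtual node one step
#' toward the root (the first expiry creates the virtual node at the terminal
#' position). A node still on the path of any other registered word is never
#' deleted from the network — the expired word's record is truncated but the
#' shared prefix survives. A word whose last path node is removed is
#' unregistered (whole forgetting) and its virtual node disappears; the word
#' can later be re-learned from scratch.
#'
#' Virtual nodes are childless placeholders: they take no part in prefix
#' matching, comparison counting, or network statistics.
#'
#' @param net a `smirn_intra` network.
#' @param cfg a [forget_config()].
#' @return a data frame of decay events with columns `word`, `removed`
#'   (deleted node id, `NA` when the node was retained because it is shared)
#'   and `remaining` (surviving path length; 0 means whole forgetting).
#' @export
forget_tick <- function(net, cfg = forget_config()) {
  stopifnot(inherits(net, "smirn_intra"), inherits(cfg, "smirn_forget_config"))
  empty <- data.frame(word = character(), removed = character(),
                      remaining = integer(), stringsAsFactors = FALSE)
  if (!isTRUE(cfg$enabled)) return(empty)
  net$clock <- net$clock + 1L
  events <- list()
  for (w in net$word_order) {
    rec <- .get_record(net, w)
    if (net$clock - rec$last_access <= cfg$tau) next
    deepest <- rec$path[length(rec$path)]
    rec$path <- rec$path[-length(rec$path)]
    rec$forgotten_suffix_len <- rec$forgotten_suffix_len + 1L
    shared <- .node_in_other_path(net, deepest, w)
    removed <- NA_character_
    ## detach the virtual node before its parent can be deleted
    if (!is.na(rec$virtual) && identical(.node(net, rec$virtual)$parent, deepest)) {
      .reparent(net, rec$virtual,
                if (length(rec$path)) rec$path[length(rec$path)] else "sn")
    }
    if (!shared) {
      .delete_node(net, deepest)
      removed <- deepest
    }
    if (length(rec$path) == 0L) {
      if (!is.na(rec$virtual)) .delete_node(net, rec$virtual)
      .drop_record(net, w)
    } else {
      if (is.na(rec$virtual)) {
        rec$virtual <- .new_node(net, NA_character_,
                                 rec$path[length(rec$path)], virtual = TRUE)
      } else {
        .reparent(net, rec$virtual, rec$path[length(rec$path)])
      }
      .set_record(net, rec)
    }
    events[[length(events) + 1L]] <-
      data.frame(word = w, removed = removed,
                 remaining = length(rec$path), stringsAsFactors = FALSE)
  }
  if (!length(events)) return(empty)
  do.call(rbind, events)
}

## is node `id` on the live path of any registered word other than `word`?
.node_in_other_path <- function(net, id, word) {
  for (w in net$word_order) {
    if (identical(w, word)) next
    if (id %in% .get_record(net, w)$path) return(TRUE)
  }
  FALSE
}
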