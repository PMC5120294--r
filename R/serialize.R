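#' Serialize an intra-modular network to JSON
#'
#' Writes a self-contained document: `nodes` (id, symbol, physical parent,
#' virtual flag, last access tick), `words` (word, path, terminal, last
#' access, forgotten suffix length), `clock` and `alphabet`. The lexical trie
#' is not stored explicitly — every live letter node lies on at least one
#' registered word's path, so the trie is reconstructed from the word paths
#' on read.
#'
#' @param net a `smirn_intra` network.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "smirn_intra"))
  ids <- setdiff(ls(net$nodes), "sn")
  num <- order(as.integer(sub("^n", "", ids)))
  ids <- c("sn", ids[num])
  nodes <- lapply(ids, function(i) {
    nd <- .node(net, i)
    list(id = nd$id, symbol = nd$symbol, parent = nd$parent,
         virtual = nd$virtual, last_access = nd$last_access)
  })
  words <- lapply(net$word_order, function(w) {
    rec <- .get_record(net, w)
    list(word = rec$word, path = as.list(rec$path),
         terminal = if (!is.na(rec$virtual)) rec$virtual
                    else rec$path[length(rec$path)],
         last_access = rec$last_access,
         forgotten_suffix_len = rec$forgotten_suffix_len)
  })
  jsonlite::write_json(list(nodes = nodes, words = words, clock = net$clock,
                            alphabet = net$alphabet),
                       path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Read an intra-modular network from JSON
#'
#' @param path file written by [write_network_json()].
#' @return a `smirn_intra` network equivalent to the serialized one (node
#'   identifiers are preserved).
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::read_json(path)
  net <- intra_network(alphabet = unlist(doc$alphabet))
  net$clock <- as.integer(doc$clock)
  for (nd in doc$nodes) {
    if (identical(nd$id, "sn")) next
    assign(nd$id,
           list(id = nd$id,
                symbol = if (is.null(nd$symbol)) NA_character_ else nd$symbol,
                parent = nd$parent, lex_parent = NA_character_,
                children = character(), trie = character(),
                virtual = isTRUE(nd$virtual),
                last_access = as.integer(nd$last_access)),
           envir = net$nodes)
  }
  ids <- setdiff(ls(net$nodes), "sn")
  for (i in ids) {
    nd <- .node(net, i)
    p <- .node(net, nd$parent)
    p$children <- c(p$children, i)
    .node_set(net, p)
  }
  for (wd in doc$words) {
    path_ids <- unlist(wd$path)
    at <- "sn"
    for (i in path_ids) {
      nd <- .node(net, i)
      parent_nd <- .node(net, at)
      if (!i %in% parent_nd$trie) {
        parent_nd$trie[nd$symbol] <- i
        .node_set(net, parent_nd)
      }
      nd <- .node(net, i)
      nd$lex_parent <- at
      .node_set(net, nd)
      at <- i
    }
    terminal <- wd$terminal
    virtual <- if (.node(net, terminal)$virtual) terminal else NA_character_
    .set_record(net, list(word = wd$word, path = path_ids,
                          terminal = terminal,
                          last_access = as.integer(wd$last_access),
                          forgotten_suffix_len = as.integer(wd$forgotten_suffix_len),
                          virtual = virtual))
  }
  if (length(ids)) {
    real <- ids[!vapply(ids, function(i) .node(net, i)$virtual, logical(1))]
    net$next_id <- max(as.integer(sub("^n", "", ids)))
  }
  net
}

#' Write the physical edge list as two-column TSV
#'
#' One `parent<TAB>child` row per physical edge among the root and live
#' letter nodes (virtual nodes excluded), no header — ready for generic graph
#' tooling.
#'
#' @param net a `smirn_intra` network.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_tsv <- function(net, path) {
  stopifnot(inherits(net, "smirn_intra"))
  ids <- node_ids(net)
  parents <- vapply(ids, function(i) .node(net, i)$parent, character(1),
                    USE.NAMES = FALSE)
  write.table(data.frame(parent = parents, child = ids),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
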