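#' Build an inter-modular region network
#'
#' Regions are super nodes on the cortical level; each owns an independent
#' intra-modular trie whose root doubles as the region's entry point. The two
#' extreme topologies are a connected ring (traversed unidirectionally in
#' ascending region order) and the complete graph; arbitrary connected custom
#' topologies are allowed. The region count is capped by the 90-region
#' anatomical (AAL) cortical parcellation; larger values are accepted with a
#' warning.
#'
#' Words are routed to regions by a pluggable assignment rule; the default is
#' first-letter binning, with the canonical four-region grouping
#' `a-e, f-l, m-q, r-z` when `regions = 4`.
#'
#' @param regions number of regions `R >= 1`.
#' @param topology `"ring"`, `"complete"` or `"custom"`.
#' @param edges for `topology = "custom"`: a two-column matrix or data frame
#'   of undirected region-index pairs; the graph must be connected.
#' @param entry default entry region for [total_cost()].
#' @param bins character vector of `R` first-letter ranges such as
#'   `c("a-e", "f-l", "m-q", "r-z")`, or `NULL` for the default contiguous
#'   split (only available for `R <= 26`).
#' @param assignment optional function `word -> region index`, overriding
#'   first-letter binning.
#' @param alphabet alphabet handed to each region's [intra_network()].
#' @return an object of class `smirn_inter`.
#' @examples
#' inter <- inter_network(4, "ring")
#' inter_search_length(inter, 2, 1)  # wraps all the way around: 4
#' @export
inter_network <- function(regions, topology = c("ring", "complete", "custom"),
                          edges = NULL, entry = 1L, bins = NULL,
                          assignment = NULL, alphabet = letters) {
  regions <- as.integer(regions)
  stopifnot(length(regions) == 1L, !is.na(regions), regions >= 1L)
  topology <- match.arg(topology)
  if (regions > 90L) {
    warning("region count exceeds the 90-region cortical parcellation bound")
  }
  if (topology == "custom") {
    if (is.null(edges)) stop("custom topology requires an edge list")
    edges <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(edges) <- "integer"
    if (any(is.na(edges)) || any(edges < 1L) || any(edges > regions)) {
      stop("custom edge list references unknown regions")
    }
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges[, 1], to = edges[, 2]),
      directed = FALSE, vertices = data.frame(name = seq_len(regions)))
    if (!igraph::is_connected(g)) stop("custom topology graph is not connected")
  } else {
    edges <- NULL
  }
  if (is.null(assignment)) {
    if (is.null(bins)) {
      bins <- if (regions <= 26L) default_letter_bins(regions) else NULL
    } else if (length(bins) != regions) {
      stop("need exactly one first-letter bin per region")
    }
  }
  entry <- as.integer(entry)
  stopifnot(entry >= 1L, entry <= regions)
  structure(list(regions = regions, topology = topology, edges = edges,
                 entry = entry, bins = bins,
                 letter_map = if (is.null(bins)) NULL else .parse_bins(bins),
                 assignment = assignment,
                 nets = lapply(seq_len(regions),
                               function(i) intra_network(alphabet))),
            class = "smirn_inter")
}

#' Default first-letter bins for R regions
#'
#' Splits the 26 lowercase letters into `R` contiguous ranges. For `R = 4`
#' the canonical four-region grouping `a-e, f-l, m-q, r-z` is used; other
#' region counts get a near-even contiguous split.
#'
#' @param regions integer between 1 and 26.
#' @return character vector of ranges like `"a-e"`.
#' @export
default_letter_bins <- function(regions) {
  regions <- as.integer(regions)
  stopifnot(regions >= 1L, regions <= 26L)
  if (regions == 4L) return(c("a-e", "f-l", "m-q", "r-z"))
  sizes <- diff(round(seq(0L, 26L, length.out = regions + 1L)))
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1L) + 1L)
  ifelse(sizes == 1L, letters[starts],
         paste0(letters[starts], "-", letters[stops]))
}

.parse_bins <- function(bins) {
  map <- integer()
  for (i in seq_along(bins)) {
    parts <- strsplit(bins[i], "-", fixed = TRUE)[[1]]
    lo <- match(parts[1], letters)
    hi <- match(parts[length(parts)], letters)
    if (is.na(lo) || is.na(hi) || hi < lo) stop(sprintf("bad bin '%s'", bins[i]))
    map[letters[lo:hi]] <- i
  }
  if (length(map) && anyDuplicated(names(map))) stop("overlapping bins")
  map
}

#' Region a word is assigned to
#'
#' @param inter a `smirn_inter` network.
#' @param word word string.
#' @return region index in `1:R`.
#' @export
assign_region <- function(inter, word) {
  stopifnot(inherits(inter, "smirn_inter"))
  if (!is.null(inter$assignment)) return(as.integer(inter$assignment(word)))
  if (is.null(inter$letter_map)) {
    stop("no assignment rule available; supply bins or an assignment function")
  }
  first <- substr(word, 1L, 1L)
  r <- unname(inter$letter_map[first])
  if (is.na(r)) stop(sprintf("no region bin covers first letter '%s'", first))
  r
}

#' @export
memorize_word.smirn_inter <- function(net, word, ...) {
  r <- assign_region(net, word)
  res <- memorize_word(net$nets[[r]], word)
  invisible(c(res, list(region = r)))
}

#' @export
retrieve_word.smirn_inter <- function(net, word, ...) {
  retrieve_word(net$nets[[assign_region(net, word)]], word, ...)
}

#' Inter-modular search length between two regions
#'
#' Counts super nodes visited, source and destination inclusive. The ring is
#' traversed unidirectionally in ascending region order (worst case `R`, the
#' reading under which a 90-region ring costs 90); the complete graph costs 2
#' for any two distinct regions; custom topologies cost the number of nodes
#' on a breadth-first shortest path. A region searched within itself costs 1.
#'
#' @param inter a `smirn_inter` network.
#' @param src,dst region indices.
#' @return positive integer.
#' @export
inter_search_length <- function(inter, src, dst) {
  stopifnot(inherits(inter, "smirn_inter"))
  src <- as.integer(src); dst <- as.integer(dst)
  R <- inter$regions
  if (length(src) != 1L || length(dst) != 1L || is.na(src) || is.na(dst) ||
      src < 1L || src > R || dst < 1L || dst > R) {
    stop("unknown region")
  }
  if (src == dst) return(1L)
  switch(inter$topology,
         ring = ((dst - src) %% R) + 1L,
         complete = 2L,
         custom = {
           g <- as_igraph(inter)
           as.integer(igraph::distances(g, v = as.character(src),
                                        to = as.character(dst))[1, 1]) + 1L
         })
}

#' Total retrieval cost through the bi-modular network
#'
#' The cost of retrieving a word entering at region `entry` is the
#' inter-modular search length from the entry region to the word's region
#' (cost over super nodes) plus the intra-modular comparisons of
#' [retrieve_word()] inside that region; the intra-modular strengthening side
#' effect is performed.
#'
#' @param inter a `smirn_inter` network.
#' @param word word string.
#' @param entry entry region; defaults to the network's configured entry.
#' @return a list with `total` (`NA` when the intra-modular search fails),
#'   `inter`, `intra`, `region` and `status`.
#' @export
total_cost <- function(inter, word, entry = inter$entry) {
  stopifnot(inherits(inter, "smirn_inter"))
  r <- assign_region(inter, word)
  sn_cost <- inter_search_length(inter, entry, r)
  res <- retrieve_word(inter$nets[[r]], word)
  list(total = if (identical(res$status, "failure")) NA_integer_
               else sn_cost + res$comparisons,
       inter = sn_cost, intra = res$comparisons,
       region = r, status = res$status)
}

#' @export
print.smirn_inter <- function(x, ...) {
  cat(sprintf("<smirn inter-modular network: %d region(s), %s topology, %d word(s)>\n",
              x$regions, x$topology,
              sum(vapply(x$nets, function(n) length(n$word_order), integer(1)))))
  invisible(x)
}
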