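.asl_curve <- function(comparisons, word, pass, mode, algorithm) {
  asl <- if (identical(mode, "running_mean")) {
    cumsum(comparisons) / seq_along(comparisons)
  } else {
    as.numeric(comparisons)
  }
  structure(data.frame(step = seq_along(comparisons), word = word,
                       pass = pass, comparisons = comparisons, asl = asl,
                       stringsAsFactors = FALSE),
            mode = mode, algorithm = algorithm,
            class = c("smirn_asl", "data.frame"))
}

#' Average search length experiment
#'
#' Memorizes the corpus token by token (repeated tokens strengthen their
#' paths), then retrieves every stored word round-robin for the given number
#' of passes, recording the comparison count of each retrieval step. On an
#' inter-modular network tokens are first routed to their regions and each
#' step's cost is the [total_cost()] (inter plus intra). The schedule is
#' fully deterministic for a fixed corpus.
#'
#' @param net a fresh `smirn_intra` or `smirn_inter` network.
#' @param corpus character vector of word tokens (non-empty).
#' @param passes number of retrieval passes, `>= 1`.
#' @param mode `"running_mean"` (cumulative mean over completed retrievals,
#'   the smooth convergence curve) or `"instantaneous"` (per-step
#'   comparisons, used for exact limit checks).
#' @param ... unused.
#' @return a data frame of class `smirn_asl` with columns `step`, `word`,
#'   `pass`, `comparisons` and `asl`, and an attribute `log` holding the full
#'   operation log (memorization included) with columns `step`, `op`, `word`,
#'   `status`, `comparisons` and `rewired`.
#' @examples
#' asl_experiment(intra_network(), c("net", "network"), passes = 2,
#'                mode = "instantaneous")
#' @export
asl_experiment <- function(net, corpus, passes = 1L,
                           mode = c("running_mean", "instantaneous"), ...) {
  UseMethod("asl_experiment")
}

.check_schedule <- function(corpus, passes) {
  corpus <- corpus[nzchar(corpus)]
  if (!length(corpus)) stop("corpus must be non-empty")
  passes <- as.integer(passes)
  if (is.na(passes) || passes < 1L) stop("passes must be >= 1")
  list(corpus = corpus, passes = passes)
}

#' @export
asl_experiment.smirn_intra <- function(net, corpus, passes = 1L,
                                       mode = c("running_mean", "instantaneous"),
                                       ...) {
  mode <- match.arg(mode)
  sched <- .check_schedule(corpus, passes)
  log <- list()
  for (tok in sched$corpus) {
    m <- memorize_word(net, tok)
    log[[length(log) + 1L]] <- data.frame(
      op = "memorize", word = tok, status = "success",
      comparisons = NA_integer_, rewired = m$rewired, stringsAsFactors = FALSE)
  }
  words <- registered_words(net)
  comparisons <- integer(0); word_col <- character(0); pass_col <- integer(0)
  for (p in seq_len(sched$passes)) {
    for (w in words) {
      res <- retrieve_word(net, w)
      comparisons <- c(comparisons, res$comparisons)
      word_col <- c(word_col, w)
      pass_col <- c(pass_col, p)
      log[[length(log) + 1L]] <- data.frame(
        op = "retrieve", word = w, status = res$status,
        comparisons = res$comparisons, rewired = length(res$rewired),
        stringsAsFactors = FALSE)
    }
  }
  curve <- .asl_curve(comparisons, word_col, pass_col, mode, algorithm = "smirn")
  log <- do.call(rbind, log)
  log$step <- seq_len(nrow(log))
  attr(curve, "log") <- log[, c("step", "op", "word", "status", "comparisons",
                                "rewired")]
  curve
}

#' @export
asl_experiment.smirn_inter <- function(net, corpus, passes = 1L,
                                       mode = c("running_mean", "instantaneous"),
                                       ...) {
  mode <- match.arg(mode)
  sched <- .check_schedule(corpus, passes)
  log <- list()
  for (tok in sched$corpus) {
    m <- memorize_word(net, tok)
    log[[length(log) + 1L]] <- data.frame(
      op = "memorize", word = tok, status = "success",
      comparisons = NA_integer_, rewired = m$rewired, stringsAsFactors = FALSE)
  }
  words <- unique(sched$corpus)
  comparisons <- integer(0); word_col <- character(0); pass_col <- integer(0)
  for (p in seq_len(sched$passes)) {
    for (w in words) {
      res <- total_cost(net, w)
      comparisons <- c(comparisons, res$total)
      word_col <- c(word_col, w)
      pass_col <- c(pass_col, p)
      log[[length(log) + 1L]] <- data.frame(
        op = "retrieve", word = w, status = res$status,
        comparisons = res$total, rewired = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  curve <- .asl_curve(comparisons, word_col, pass_col, mode, algorithm = "smirn")
  log <- do.call(rbind, log)
  log$step <- seq_len(nrow(log))
  attr(curve, "log") <- log[, c("step", "op", "word", "status", "comparisons",
                                "rewired")]
  curve
}

#' @export
plot.smirn_asl <- function(x, ...) {
  plot(x$step, x$asl, type = "l", xlab = "retrieval step",
       ylab = sprintf("ASL (%s)", attr(x, "mode")), ...)
  graphics::abline(h = 2, lty = 3)
  invisible(x)
}

#' Convert a memory network to an igraph graph
#'
#' Intra-modular networks become the undirected tree over the root and all
#' live letter nodes (virtual decay placeholders are dropped); inter-modular
#' networks become the undirected region graph, with vertices named by region
#' index.
#'
#' @param x a `smirn_intra`, `smirn_inter`, or an igraph object (returned
#'   unchanged).
#' @param ... unused.
#' @return an igraph graph.
#' @export
as_igraph <- function(x, ...) UseMethod("as_igraph")

#' @export
as_igraph.igraph <- function(x, ...) x

#' @export
as_igraph.smirn_intra <- function(x, ...) {
  ids <- node_ids(x)
  parents <- vapply(ids, function(i) .node(x, i)$parent, character(1),
                    USE.NAMES = FALSE)
  igraph::graph_from_data_frame(
    data.frame(from = parents, to = ids, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = c("sn", ids), stringsAsFactors = FALSE))
}

#' @export
as_igraph.smirn_inter <- function(x, ...) {
  R <- x$regions
  g <- switch(x$topology,
              ring = if (R == 1L) igraph::make_ring(1L, circular = FALSE)
                     else igraph::make_ring(R),
              complete = igraph::make_full_graph(R),
              custom = igraph::graph_from_data_frame(
                data.frame(from = x$edges[, 1], to = x$edges[, 2]),
                directed = FALSE,
                vertices = data.frame(name = seq_len(R))))
  igraph::set_vertex_attr(g, "name", value = as.character(seq_len(R)))
}

#' Average path length
#'
#' Mean geodesic (edge-count) distance over all unordered node pairs of the
#' undirected network, root included. With `root_only = TRUE` only distances
#' from the root to the letter nodes are averaged (the variant under which a
#' fully strengthened network scores exactly 1).
#'
#' A fully strengthened intra-modular network with `m` letter nodes is a star,
#' so its APL is `2 m / (m + 1)` — approaching 2 from below.
#'
#' @param net a `smirn_intra`, `smirn_inter` or igraph object.
#' @param root_only average root-to-node distances only (intra networks).
#' @return a real number; networks with a single node return `NaN`.
#' @export
apl <- function(net, root_only = FALSE) {
  g <- as_igraph(net)
  if (!igraph::is_connected(g)) stop("network is disconnected; APL undefined")
  if (isTRUE(root_only)) {
    d <- igraph::distances(g, v = "sn")
    return(mean(d[1, colnames(d) != "sn"]))
  }
  igraph::mean_distance(g, directed = FALSE)
}

#' Clustering coefficient
#'
#' Mean of the standard local (Watts-Strogatz) clustering coefficient over
#' all nodes; nodes of degree below 2 contribute 0. Any tree — including
#' every intra-modular memory network — scores 0.
#'
#' @param net a `smirn_intra`, `smirn_inter` or igraph object.
#' @return real in `[0, 1]`.
#' @export
clustering_coefficient <- function(net) {
  g <- as_igraph(net)
  if (igraph::vcount(g) == 0L) return(0)
  val <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  if (is.nan(val)) 0 else val
}

#' Degree histogram
#'
#' Undirected degree counts of the network, as a named integer vector
#' (degree value to node count). A fully strengthened intra-modular network
#' with `m` letter nodes is the star histogram: one node of degree `m`, `m`
#' nodes of degree 1.
#'
#' @param net a `smirn_intra`, `smirn_inter` or igraph object.
#' @return named integer vector; names are degree values in increasing order.
#' @export
degree_histogram <- function(net) {
  g <- as_igraph(net)
  tab <- table(igraph::degree(g))
  setNames(as.integer(tab), names(tab))
}

#' Topological summary of a network
#'
#' @param net a `smirn_intra`, `smirn_inter` or igraph object.
#' @return a list of class `smirn_summary` with `node_count`, `edge_count`,
#'   `apl`, `clustering` and `degree_histogram`.
#' @export
network_summary <- function(net) {
  g <- as_igraph(net)
  structure(list(node_count = igraph::vcount(g),
                 edge_count = igraph::ecount(g),
                 apl = if (igraph::vcount(g) >= 2L && igraph::is_connected(g))
                         igraph::mean_distance(g, directed = FALSE)
                       else NA_real_,
                 clustering = clustering_coefficient(g),
                 degree_histogram = degree_histogram(g)),
            class = "smirn_summary")
}

#' @export
print.smirn_summary <- function(x, ...) {
  cat(sprintf("nodes: %d  edges: %d  APL: %s  clustering: %.3f\n",
              x$node_count, x$edge_count,
              if (is.na(x$apl)) "NA" else sprintf("%.3f", x$apl),
              x$clustering))
  cat("degree histogram:",
      paste(sprintf("%s:%d", names(x$degree_histogram), x$degree_histogram),
            collapse = "  "), "\n")
  invisible(x)
}
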