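#' Create a merge-find set of singletons
#'
#' The merge-find set (disjoint-set forest with union by size and path
#' compression) is the classical data structure whose find cost the memory
#' network's retrieval algorithm is benchmarked against. Elements are the
#' integers `1:n`; every element starts as its own root.
#'
#' @param n element count, `n >= 1`.
#' @return an object of class `smirn_mfset` (an environment; mutated in
#'   place).
#' @export
mfset_initial <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) stop("need at least one element")
  s <- new.env(parent = emptyenv())
  s$parent <- seq_len(n)
  s$size <- rep(1L, n)
  s$find_log <- integer()
  class(s) <- "smirn_mfset"
  s
}

.mf_check <- function(s, x) {
  x <- as.integer(x)
  if (length(x) != 1L || is.na(x) || x < 1L || x > length(s$parent)) {
    stop("unknown element")
  }
  x
}

## root lookup without compression (used by merge and by tests that probe the
## pre-compression shape)
.mf_root <- function(s, x) {
  while (s$parent[x] != x) x <- s$parent[x]
  x
}

#' Merge the sets containing two elements
#'
#' Union by size: the root of the smaller tree becomes a child of the root of
#' the larger; on equal sizes the second argument's root attaches under the
#' first's. Merging elements already in one set is a no-op.
#'
#' @param s a `smirn_mfset`.
#' @param a,b elements.
#' @return the set, invisibly (mutated in place).
#' @export
mfset_merge <- function(s, a, b) {
  stopifnot(inherits(s, "smirn_mfset"))
  ra <- .mf_root(s, .mf_check(s, a))
  rb <- .mf_root(s, .mf_check(s, b))
  if (ra == rb) return(invisible(s))
  if (s$size[ra] < s$size[rb]) {
    s$parent[ra] <- rb
    s$size[rb] <- s$size[rb] + s$size[ra]
  } else {
    s$parent[rb] <- ra
    s$size[ra] <- s$size[ra] + s$size[rb]
  }
  invisible(s)
}

#' Find with path compression, counting comparisons
#'
#' Walks from the element up to its root, counting every node visited
#' (element and root inclusive — the same endpoints-inclusive convention the
#' memory network's retrieval uses), then re-parents every node on the walked
#' path directly onto the root. The comparison count is appended to the set's
#' `find_log`.
#'
#' @param s a `smirn_mfset`.
#' @param x element.
#' @return a list with `root` and `comparisons`.
#' @export
mfset_find <- function(s, x) {
  stopifnot(inherits(s, "smirn_mfset"))
  x <- .mf_check(s, x)
  path <- x
  while (s$parent[x] != x) {
    x <- s$parent[x]
    path <- c(path, x)
  }
  comparisons <- length(path)
  if (comparisons > 2L) s$parent[path[seq_len(comparisons - 1L)]] <- x
  s$find_log <- c(s$find_log, comparisons)
  list(root = x, comparisons = comparisons)
}

#' Build a merge-find set from explicit parent pointers
#'
#' Intended for constructing specific tree shapes (e.g. a chain isomorphic to
#' a freshly memorized word) when benchmarking against the retrieval
#' algorithm. Roots are encoded as self-parents; the forest must be acyclic.
#'
#' @param parents integer vector; `parents[i]` is the parent of `i`, with
#'   `parents[i] == i` for roots.
#' @return a `smirn_mfset`.
#' @export
mfset_from_parents <- function(parents) {
  parents <- as.integer(parents)
  n <- length(parents)
  stopifnot(n >= 1L, !anyNA(parents), all(parents >= 1L), all(parents <= n))
  for (i in seq_len(n)) {
    x <- i; steps <- 0L
    while (parents[x] != x) {
      x <- parents[x]; steps <- steps + 1L
      if (steps > n) stop("parent pointers contain a cycle")
    }
  }
  s <- mfset_initial(n)
  s$parent <- parents
  roots <- vapply(seq_len(n), function(i) { x <- i
    while (parents[x] != x) x <- parents[x]; x }, integer(1))
  s$size <- vapply(seq_len(n), function(i) sum(roots == i), integer(1))
  s
}

#' @export
print.smirn_mfset <- function(x, ...) {
  cat(sprintf("<merge-find set: %d element(s), %d set(s), %d find(s) logged>\n",
              length(x$parent), sum(x$parent == seq_along(x$parent)),
              length(x$find_log)))
  invisible(x)
}

#' Enumerate trie positions of a word list
#'
#' Maps every distinct prefix of every distinct word to an integer element,
#' in first-occurrence order. This is the encoding that makes a merge-find
#' set structurally comparable to the letter trie built from the same corpus:
#' one element per trie position, one set per word's path.
#'
#' @param words character vector of words (duplicates ignored).
#' @return a list with `n` (position count), `index` (named integer vector,
#'   prefix string to element), `paths` (per distinct word, its positions in
#'   symbol order) and `terminals` (named integer vector, word to terminal
#'   element).
#' @export
trie_positions <- function(words) {
  words <- unique(words[nzchar(words)])
  idx <- new.env(parent = emptyenv())
  count <- 0L
  paths <- vector("list", length(words))
  names(paths) <- words
  for (w in words) {
    len <- nchar(w)
    pos <- integer(len)
    for (i in seq_len(len)) {
      p <- substr(w, 1L, i)
      if (!exists(p, envir = idx, inherits = FALSE)) {
        count <- count + 1L
        assign(p, count, envir = idx)
      }
      pos[i] <- get(p, envir = idx, inherits = FALSE)
    }
    paths[[w]] <- pos
  }
  prefixes <- ls(idx)
  index <- setNames(vapply(prefixes, get, integer(1), envir = idx), prefixes)
  list(n = count, index = index, paths = paths,
       terminals = vapply(paths, function(p) p[length(p)], integer(1)))
}

#' Baseline average search length curve of the merge-find set
#'
#' Re-runs the retrieval schedule of [asl_experiment()] against the
#' merge-find set: the corpus's trie positions become the elements, each
#' distinct word's successive positions are merged into one set once, and
#' then every distinct word's terminal element is found (with compression)
#' round-robin for the given number of passes.
#'
#' @param corpus character vector of word tokens (non-empty).
#' @param passes number of round-robin passes over the distinct words;
#'   `passes = 0` yields an empty curve.
#' @param mode `"running_mean"` (cumulative mean of comparisons, the smooth
#'   convergence curve) or `"instantaneous"` (per-step comparisons).
#' @return a data frame of class `smirn_asl` with columns `step`, `word`,
#'   `pass`, `comparisons` and `asl`.
#' @export
mfset_asl_curve <- function(corpus, passes = 1L,
                            mode = c("running_mean", "instantaneous")) {
  mode <- match.arg(mode)
  corpus <- corpus[nzchar(corpus)]
  if (!length(corpus)) stop("corpus must be non-empty")
  passes <- as.integer(passes)
  stopifnot(passes >= 0L)
  tp <- trie_positions(corpus)
  s <- mfset_initial(tp$n)
  for (pos in tp$paths) {
    if (length(pos) >= 2L) {
      for (i in 2:length(pos)) mfset_merge(s, pos[i - 1L], pos[i])
    }
  }
  words <- names(tp$paths)
  comparisons <- integer(0)
  word_col <- character(0)
  pass_col <- integer(0)
  for (p in seq_len(passes)) {
    for (w in words) {
      comparisons <- c(comparisons, mfset_find(s, tp$terminals[[w]])$comparisons)
      word_col <- c(word_col, w)
      pass_col <- c(pass_col, p)
    }
  }
  .asl_curve(comparisons, word_col, pass_col, mode, algorithm = "mfset")
}
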