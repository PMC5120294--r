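#' Specification for a synthetic word corpus
#'
#' The generator emulates the study condition the bundled paragraph
#' represents: a stream of a few hundred word tokens over a modest vocabulary
#' with natural-language-like repetition. Defaults mirror that scale — 100
#' distinct words of 2 to 10 lowercase letters, 160 tokens, Zipf rank
#' exponent 1 (the classical value for natural text).
#'
#' @param vocab_size number of distinct words, `>= 1`.
#' @param word_length either a single fixed length or a `c(min, max)` range
#'   sampled uniformly.
#' @param alphabet symbol set words are drawn from.
#' @param zipf_s Zipf repetition skew `s >= 0`; rank `r` is sampled with
#'   probability proportional to `r^-s` (`s = 0` is uniform).
#' @param n_tokens length of the emitted token stream.
#' @param seed integer seed; identical `(spec, seed)` yield identical
#'   corpora.
#' @return a list of class `smirn_corpus_spec`.
#' @export
corpus_spec <- function(vocab_size = 100L, word_length = c(2L, 10L),
                        alphabet = letters, zipf_s = 1, n_tokens = 160L,
                        seed = 1L) {
  vocab_size <- as.integer(vocab_size)
  n_tokens <- as.integer(n_tokens)
  word_length <- as.integer(word_length)
  if (length(word_length) == 1L) word_length <- rep(word_length, 2L)
  stopifnot(vocab_size >= 1L, n_tokens >= 0L, length(word_length) == 2L,
            word_length[1] >= 1L, word_length[2] >= word_length[1],
            is.numeric(zipf_s), zipf_s >= 0, length(alphabet) >= 1L)
  possible <- 0
  for (L in word_length[1]:word_length[2]) {
    possible <- possible + length(alphabet)^L
    if (possible >= vocab_size) break
  }
  if (possible < vocab_size) {
    stop(sprintf("vocab_size %d exceeds the %g distinct words possible for this alphabet and length range",
                 vocab_size, possible))
  }
  structure(list(vocab_size = vocab_size, word_length = word_length,
                 alphabet = alphabet, zipf_s = zipf_s, n_tokens = n_tokens,
                 seed = as.integer(seed)),
            class = "smirn_corpus_spec")
}

## run `expr` under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic word corpus
#'
#' Draws `vocab_size` distinct words (without replacement) with uniformly
#' sampled lengths and symbols, then emits `n_tokens` tokens whose vocabulary
#' ranks follow a Zipf law with exponent `zipf_s`. Fully reproducible from
#' `(spec, seed)`.
#'
#' @param spec a [corpus_spec()].
#' @return character vector of tokens, with the vocabulary (in rank order)
#'   attached as attribute `"vocab"`.
#' @export
generate_corpus <- function(spec = corpus_spec()) {
  stopifnot(inherits(spec, "smirn_corpus_spec"))
  .with_seed(spec$seed, {
    vocab <- character(0)
    tries <- 0L
    while (length(vocab) < spec$vocab_size) {
      tries <- tries + 1L
      if (tries > 1000L) stop("could not draw enough distinct words")
      need <- spec$vocab_size - length(vocab)
      lens <- sample(seq(spec$word_length[1], spec$word_length[2]),
                     2L * need, replace = TRUE)
      batch <- vapply(lens, function(L) {
        paste(sample(spec$alphabet, L, replace = TRUE), collapse = "")
      }, character(1))
      vocab <- unique(c(vocab, batch))
    }
    vocab <- vocab[seq_len(spec$vocab_size)]
    prob <- seq_len(spec$vocab_size)^(-spec$zipf_s)
    ranks <- sample.int(spec$vocab_size, spec$n_tokens, replace = TRUE,
                        prob = prob / sum(prob))
    structure(vocab[ranks], vocab = vocab)
  })
}

#' The bundled example paragraph
#'
#' A ~150-word public-domain English paragraph (the closing passage of
#' Darwin's *On the Origin of Species*) shipped as the default memory task.
#' Any paragraph of comparable size reproduces the same qualitative curves
#' and the exact limiting values.
#'
#' @return a single string.
#' @export
smirn_example_paragraph <- function() {
  path <- system.file("extdata", "entangled_bank.txt", package = "smirn")
  paste(readLines(path, warn = FALSE), collapse = " ")
}
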