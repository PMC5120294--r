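#' Run the full memory-network experiment suite
#'
#' One invocation reproduces the three convergence runs plus the baseline on
#' a single corpus and schedule:
#' * `SMIRN(1)` — a single intra-modular trie;
#' * `SMIRN(1b)` — the bi-modular network with one region (every retrieval
#'   pays one extra super-node visit);
#' * `SMIRN(4)` — four regions on a ring with first-letter word assignment;
#' * `MFset` — the merge-find-set baseline on the same trie positions and
#'   retrieval schedule.
#'
#' Artifacts written to `out_dir`: `network.json` and `edges.tsv` (the
#' `SMIRN(1)` network after the run), `curves.csv`
#' (`step,asl,mode,run_id`, both running-mean and instantaneous granularity),
#' `summary.json` (network statistics plus final ASL per run) and `log.csv`
#' (every memorize/retrieve operation). Everything is deterministic given
#' `(config, seed)`.
#'
#' @param config a named list, or path to a JSON file holding one. Fields
#'   (all optional): `corpus` (path to a plain-text file to tokenize),
#'   `corpus_spec` (arguments for [corpus_spec()], used when `corpus` is
#'   absent instead of the bundled paragraph), `passes` (default 20),
#'   `regions` (default 4), `seed` (default 1).
#' @param out_dir output directory, created if needed.
#' @return (invisibly) a list with `tokens`, `curves` (named list of
#'   `smirn_asl`), `summary`, and `paths` to the artifacts.
#' @export
run_experiment <- function(config = list(), out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  passes <- as.integer(config[["passes"]] %||% 20L)
  regions <- as.integer(config[["regions"]] %||% 4L)
  seed <- as.integer(config[["seed"]] %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  tokens <- if (!is.null(config[["corpus"]])) {
    if (!file.exists(config[["corpus"]])) {
      stop(sprintf("corpus file not found: %s", config[["corpus"]]))
    }
    tokenize(readLines(config[["corpus"]], warn = FALSE))
  } else if (!is.null(config[["corpus_spec"]])) {
    spec <- do.call(corpus_spec, c(config[["corpus_spec"]], list(seed = seed)))
    generate_corpus(spec)
  } else {
    tokenize(smirn_example_paragraph())
  }
  if (!length(tokens)) stop("corpus is empty after tokenization")

  .with_seed(seed, {
    net1 <- intra_network()
    curves <- list(
      "SMIRN(1)"  = asl_experiment(net1, tokens, passes),
      "SMIRN(1b)" = asl_experiment(inter_network(1L, "ring"), tokens, passes),
      "SMIRN(4)"  = asl_experiment(inter_network(regions, "ring"), tokens, passes),
      "MFset"     = mfset_asl_curve(tokens, passes))

    csv <- do.call(rbind, lapply(names(curves), function(id) {
      cv <- curves[[id]]
      rbind(data.frame(step = cv$step, asl = cv$asl, mode = "running_mean",
                       run_id = id, stringsAsFactors = FALSE),
            data.frame(step = cv$step, asl = as.numeric(cv$comparisons),
                       mode = "instantaneous", run_id = id,
                       stringsAsFactors = FALSE))
    }))
    paths <- list(
      network = file.path(out_dir, "network.json"),
      edges = file.path(out_dir, "edges.tsv"),
      curves = file.path(out_dir, "curves.csv"),
      summary = file.path(out_dir, "summary.json"),
      log = file.path(out_dir, "log.csv"))
    write_network_json(net1, paths$network)
    write_edge_tsv(net1, paths$edges)
    utils::write.csv(csv, paths$curves, row.names = FALSE, quote = FALSE)
    utils::write.csv(attr(curves[["SMIRN(1)"]], "log"), paths$log,
                     row.names = FALSE, quote = FALSE)
    summ <- network_summary(net1)
    summary <- list(
      corpus_tokens = length(tokens),
      distinct_words = length(unique(tokens)),
      passes = passes,
      seed = seed,
      network = list(node_count = summ$node_count,
                     edge_count = summ$edge_count,
                     apl = summ$apl, clustering = summ$clustering,
                     degree_histogram = as.list(summ$degree_histogram)),
      final_asl = lapply(curves, function(cv) {
        list(running_mean = cv$asl[nrow(cv)],
             instantaneous = cv$comparisons[nrow(cv)])
      }))
    jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(list(tokens = tokens, curves = curves, summary = summary,
                   paths = paths))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
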