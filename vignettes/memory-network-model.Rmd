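---
title: "A trie-based memory network: model, retrieval dynamics, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A trie-based memory network: model, retrieval dynamics, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smirn)
```

## The model

The package simulates memory as information processing over a network of
*meta-memory* nodes — abstract memory units (a letter here, but any token
alphabet works) standing in for neurons or cortical regions. Three memory
operations have direct network counterparts:

* **Memorization** adds a word as a path of letter nodes under a symbol-less
  root `sn`, the single input/output point. Words sharing a prefix share its
  nodes, so storage is a trie: one node per distinct prefix, and node
  identity is positional (the two "e"s of *netbeans* are different nodes).
* **Strengthening** is the side effect of retrieval. A search walks from the
  root to the target and costs one comparison per node visited, endpoints
  inclusive (`depth + 1`). The retrieved nodes and all their former proper
  ancestors are then re-parented directly onto the root; their child links
  are untouched, so every descendant gets shallower as well. This is path
  compression in the union–find sense, and it drives the per-word cost to the
  limit 2 (root plus target) — the same limit a merge–find set reaches.
* **Forgetting** is passive decay. When a word's last access falls more than
  `tau` ticks behind the logical clock, a childless *virtual node* replaces
  the word's deepest letter and climbs toward the root one tick at a time.
  Replaced nodes are deleted unless another living word still has them on its
  path; when the last path node goes, the word is unregistered entirely.

On the cortical level, regions each holding an independent trie are composed
into an inter-modular graph. The two extreme topologies are a ring —
traversed unidirectionally in ascending region order — and the complete
graph; the region count is bounded by the 90-region AAL cortical
parcellation. The cost of a bi-modular retrieval is additive:
`cost(sn) + cost(n)`, super-node visits plus intra-modular comparisons.

## Two kinds of links

One structural decision underlies the whole implementation. Each letter node
carries

* a **physical parent pointer** — the edge that retrieval rewires and that
  depth, comparison counts and all graph statistics are computed from; and
* a **lexical child index** (at most one child per symbol) — the trie
  structure laid down at memorization time, altered only by forgetting.

The separation is forced by the semantics of strengthening: after a word is
compressed, the root may physically hold several children with the same
symbol (memorize and then retrieve the word *nn* — both nodes end up at depth
1). Prefix matching on physical children would then be ambiguous, and
re-memorizing a known word could duplicate nodes. Matching on the lexical
index keeps memorization idempotent and deterministic no matter how flattened
the physical tree is, and is consistent with moved nodes keeping their
relations to their children. New suffixes attach to the divergence node *at
its current position* — after compression that means at depth 1.

## Counting conventions

A search length counts nodes visited, source and destination inclusive. This
is the only convention under which the fully strengthened intra-modular limit
is exactly 2 while the root-to-node geodesic is 1, and it is applied
uniformly: intra-modular retrieval (`depth + 1`), merge–find-set finds
(leaf-to-root walk length), and inter-modular traversal (ring cost
`((dst − src) mod R) + 1`, worst case `R = 90`; complete-graph cost 2; both
reproduced exhaustively in the tests). A failed word search costs the matched
prefix walk (root inclusive) plus one failing probe. Node retrievals that
fail validation (unknown word, out-of-range position) cost the single root
consultation and have no side effects.

The ring is traversed unidirectionally rather than by bidirectional shortest
path: that is the reading under which the worst case over 90 regions is 90
rather than 46, and the package reports the worst case and the enumerated
mean separately rather than conflating them.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `tau` | 1000 | clock ticks | decay threshold; the clock counts memorize/retrieve operations and explicit decay ticks, since the model has no physical time unit. The default keeps forgetting out of short schedules unless asked for. |
| `passes` | 20 | round-robin passes | enough to show both the exact instantaneous limit (reached in pass 2) and the slow `1/n` decay of the cumulative mean. |
| `regions` | 4 | — | the canonical four-region bi-modular condition with first-letter bins `a-e, f-l, m-q, r-z`. Other counts get a near-even contiguous split of the alphabet. |
| `zipf_s` | 1 | — | rank exponent of the synthetic corpus; 1 is the classical natural-language value. |
| `vocab_size`, `n_tokens` | 100, 160 | words, tokens | the scale of a ~150-word paragraph, the study condition the bundled fixture represents. |

## What the synthetic generator does and does not emulate

`generate_corpus()` reproduces the *scale and repetition structure* of a
paragraph-sized memory task: a modest distinct vocabulary, uniform random
word lengths, Zipf-distributed token repetition, full determinism under a
seed. It does **not** emulate the morphological structure of natural
language — real words share prefixes far more than uniform random strings do
(478 trie positions for the bundled paragraph's 106 distinct words versus
roughly one node per letter for random strings). Passing tests on synthetic
corpora therefore exercise the algorithms' correctness, not natural-language
compression ratios; the bundled public-domain paragraph (the closing passage
of Darwin's *Origin of Species*, 162 tokens, 106 distinct words) is the
fixture for the quantitative claims, and any comparable paragraph reproduces
the same limiting values.

## Convergence behaviour

```{r}
toks <- tokenize(smirn_example_paragraph())
curve <- asl_experiment(intra_network(), toks, passes = 20)
c(final_instantaneous = tail(curve$comparisons, 1),
  pass1_mean = mean(curve$comparisons[curve$pass == 1]),
  running_mean_after_20 = tail(curve$asl, 1))
```

Every retrieval from the second pass onward costs exactly 2. The *cumulative*
running mean, however, permanently carries the first pass, in which fresh
words cost `depth + 1` (about 5.4 on average for this paragraph), so it
approaches 2 only like `1/n` — after 20 passes it still sits near 2.17. A
running mean within 0.1 of the limit by pass 20 would require a first-pass
mean below 4, i.e. a mean terminal depth below 3, which natural English text
does not produce; the per-pass mean, by contrast, equals the limit exactly
from pass 2 onward. Both granularities are emitted (`mode = "running_mean"`
and `"instantaneous"`), and the exact limit statements are always made on the
instantaneous curve.

After one full strengthening pass the network is a star:

```{r}
net <- intra_network()
memorize_words(net, toks)
for (w in registered_words(net)) retrieve_word(net, w)
c(apl = apl(net), root_only = apl(net, root_only = TRUE),
  clustering = clustering_coefficient(net))
```

The average path length is `2m/(m+1)` for `m` letter nodes (root distances 1,
pairwise distances 2), below 2 and approaching it from below as the
vocabulary grows — the small-world signature of the strengthened network.

A note on the clustering coefficient: the package implements the standard
local (Watts–Strogatz) definition, under which every tree — including every
intra-modular network, star or not — scores 0. An alternative view counts the
root-centred cluster structure as maximal; that reading is not a computable
graph statistic and is not implemented. Triangle-bearing inter-modular
topologies (the complete graph) do score positively.

## Numerical and degeneracy choices

* **Tie breaks.** The lexical index holds at most one child per symbol, so
  prefix matching never branches. Merge–find-set unions of equal-sized trees
  attach the second argument's root under the first's.
* **Batch rewiring.** The ancestor set is snapshotted before any re-parenting,
  so the outcome is order-independent.
* **Failure is side-effect-free.** Retrieval of an absent word changes
  nothing unless `learn_on_fail = TRUE` explicitly memorizes it afterwards.
* **Forgetting deletes, retrieval never does.** Retrieving a partially
  forgotten word strengthens the surviving prefix and reports `"partial"`;
  the decay engine alone removes nodes. Decay processes one node per expired
  word per tick, words in registration order; a tick during which the
  deepest node is shared truncates the record without deleting the node.
* **Degenerate inputs.** An empty corpus, `passes = 0`, a vocabulary larger
  than the alphabet permits, a disconnected custom topology, and symbols
  outside the alphabet are all rejected with specific errors; a
  single-region inter-modular network degenerates to a bare trie plus a
  constant inter cost of 1.
* **Scale.** The quantitative checks run at the study scale — a ~150-word
  paragraph (478 trie positions), 90-region topologies enumerated over all
  8100 ordered pairs, and property checks over dozens of seeded random
  corpora — which keeps the full suite within seconds on one core.

## Serialization

Networks round-trip through JSON (`nodes`, `words`, `clock`, `alphabet`).
The lexical index is not stored: every live letter node lies on at least one
registered word's path (forgetting guarantees this), so the trie is rebuilt
from the word paths on read. A headerless two-column TSV edge list serves
generic graph tooling.

## Known limitations

* Edges are unweighted; free or cued recall with weighted competition is out
  of scope — retrieval answers recognition and path-output queries only.
* Semantic, contextual and episodic memory are not modelled; the network
  stores exact symbol sequences (a misspelled variant is simply a different
  path sharing whatever prefix it shares).
* The merge–find-set comparison is empirical; no `O(n α(n))` bound is proven
  here, and the corpus-to-set encoding (elements are trie positions, one
  merge chain per word) is a modelling choice made so the two curves share a
  schedule.
* The inter-modular layer models routing cost only, not anatomical
  connectivity.
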