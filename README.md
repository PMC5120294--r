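# smirn

Simulator for a simplified memory information retrieval network: a
computational model of word memory in which **memorization**, **strengthening**
and **forgetting** are realized as operations on a rooted letter trie, and
memory efficiency is measured with the tools of complex-network analysis.

The package is aimed at computational cognitive-science work that treats
memory as information processing: it lets you memorize word corpora, replay
retrieval schedules, watch the network reorganize itself, and compare its
search cost against the classical merge-find set.

## The model

**Intra-modular network.** Every letter is a meta-memory node; a word is a
path of letter nodes anchored at a symbol-less root `sn`, the sole
input/output point. Words sharing a prefix share the prefix's nodes, so the
vocabulary forms a trie: the letter-node count equals the number of distinct
word prefixes.

**Strengthening retrieval.** Retrieving a stored item costs one comparison per
node visited from the root to the target, endpoints inclusive
(`cost = depth + 1`). Afterwards the retrieved nodes *and all of their former
ancestors* are re-parented directly onto the root — path compression, with
child links preserved. Repeated retrieval therefore drives every stored word
toward the limiting cost

```
ASL  →  2        (root + target)
```

and the whole network toward a star, whose average path length is
`2m/(m+1) < 2` for `m` letter nodes: root-to-node geodesics are 1,
node-to-node geodesics are 2.

**Forgetting.** A word untouched for more than `tau` clock ticks decays: a
childless *virtual node* replaces its deepest letter and climbs toward the
root one tick at a time, deleting nodes that no other living word still uses.
Re-learning a partially forgotten word rebuilds the lost suffix and removes
the virtual node.

**Inter-modular network.** Up to 90 regions (the AAL cortical parcellation
bound), each owning its own trie, are wired as a unidirectional ring (worst
case cost `R`, i.e. 90), a complete graph (cost 2 between any two regions) or
a custom connected topology. Words are routed to regions by first letter
(canonically `a-e | f-l | m-q | r-z` for four regions), and the total
retrieval cost is the inter-modular visit count plus the intra-modular
comparisons.

**Baseline.** An instrumented merge-find set (union by size, path
compression, `O(n α(n))` finds) is run on the same trie positions and
retrieval schedule for efficiency comparison.

## Worked example

```r
library(smirn)

net <- intra_network()
memorize_word(net, "netbeans")
memorize_word(net, "network")      # shares the n-e-t prefix
node_count(net)
#> [1] 12

retrieve_word(net, "netbeans")$comparisons   # depth 8 + root
#> [1] 9
retrieve_word(net, "netbeans")$comparisons   # fully strengthened
#> [1] 2

# the bundled ~150-word paragraph, 20 retrieval passes
toks  <- tokenize(smirn_example_paragraph())
curve <- asl_experiment(intra_network(), toks, passes = 20)
tail(curve$comparisons, 1)    # instantaneous ASL at the final step
#> [1] 2
tail(curve$asl, 1)            # cumulative running mean after 20 passes
#> [1] 2.171698

# fully strengthened geodesics
net2 <- intra_network()
memorize_words(net2, toks)
for (w in registered_words(net2)) retrieve_word(net2, w)
apl(net2)                     # 2m/(m+1), just below 2
#> [1] 1.995825
```

The final retrieval costs exactly 2 comparisons; the cumulative mean still
carries the expensive first pass (fresh words cost `depth + 1`) and decays
toward 2 like `1/n`. After one full strengthening pass the 478-node trie is a
star: every root-to-node distance is 1, every node-to-node distance is 2.

A full experiment — the intra-modular run, the one-region and four-region
bi-modular runs, and the merge-find-set baseline, with all artifacts
(network JSON, edge TSV, curve CSV, summary JSON, operation log) — is one
call:

```r
run_experiment(list(passes = 20, seed = 1), out_dir = "out")
```

or, from a shell, `Rscript inst/cli/smirn.R simulate --out out`.

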