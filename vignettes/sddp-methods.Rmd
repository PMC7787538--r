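---
title: "Methods: from literature-mined markers to a pathway-based risk indicator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from literature-mined markers to a pathway-based risk indicator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sddp)
```

# Overview

`sddp` estimates an individual's degree of future susceptibility to a
disease from four chained models:

1. **Information extraction.** Marker–disease associations are mined from
   abstracts with strict clause-level linguistic rules and filtered by a
   co-occurrence z-score and a document-support threshold.
2. **Pathway modelling.** A molecular interaction network is transformed
   into per-marker *characteristic trees* (single-parent shortest-path
   spanning trees), and pathways are joined into a hierarchy network
   through their shared molecules.
3. **Logic inference.** The hierarchy is compiled into propositional
   specification rules; forward chaining derives every pathway atom
   classically entailed by the individual's detected pathways, with a
   replayable proof trace.
4. **Risk ranking.** Pathway combinations are scored by pairwise dominance
   over per-publication co-occurrence weights; the individual's combination
   is read off as a competition rank — the risk indicator.

This vignette documents the modelling assumptions, the tunable parameters,
the numerical conventions adopted where the design was genuinely open, and
what the synthetic generators do and do not emulate.

# Information extraction

## Sentence model

Each sentence is an ordered rooted tree of constituents (independent
clauses, adverbial clauses, conjoint clauses, compound units, units,
groups; leaves are tokens). The package *consumes* parses rather than
producing them: `post_parse()` reads Penn-style bracketed parses (labels
are collapsed onto the constituent scheme, unmappable ones onto `unit`),
and `sentence_post()` provides a deliberately coarse heuristic fallback
that splits clauses at the coordinator lexicon and at comma-preceded
relative pronouns. Decoupling parsing keeps every test deterministic and
lets users plug in any constituency parser.

Two strict rules are built in:

- **Pronoun antecedents.** Each pronoun (`whom`, `which`, `it`, `who`,
  `that`; configurable) is annotated with the *closest* dictionary terms of
  the nearest preceding independent clause (closest = smallest token
  distance to the term's end). Equidistant antecedents are all kept — a
  recall-favouring choice, logged for audit. A pronoun with no preceding
  clause stays unannotated (logged, not fatal).
- **Preposition-modifier exclusion.** Mentions in two distinct independent
  clauses joined by a coordinator (`whereas`, `while`, `but`; configurable)
  are judged unrelated. All other co-occurrences are related.

Further exclusion rules can be registered as predicates over a mention pair
and the tree (`extra_rules` in `related_pairs()`), so an extended rule
catalogue can be supplied without touching the package.

## Association significance

The unit of co-occurrence is the **sentence** (configurable in spirit: all
counting happens in one place, `corpus_pair_stats()`). For a pair with
sentence marginals $n_a, n_b$ out of $N$ corpus sentences, the null
probability of a joint related occurrence is $p = (n_a/N)(n_b/N)$, the
expectation $E = pN$, and the reported statistic is the one-sample binomial
z-score

$$ z = \frac{n_{rel} - E}{\sqrt{E(1-p)}}, $$

with $z = 0$ when $E = 0$. This is the standard co-occurrence significance
test against independence; the defaults `z_min = 1.96` (one-sided 2.5%)
and `min_docs = 3` (at least three distinct publications with a related
co-occurrence) implement the two strictness filters — significance *within*
texts and support *across* texts. Both are configurable.

# Pathway modelling

## Characteristic trees

`build_mct()` removes multiple parentage from the interaction network by
breadth-first search from the marker root: every node keeps exactly one
edge to a neighbour on a shortest path to the root. When several such
neighbours exist one is chosen uniformly at random from the supplied seed;
`deterministic = TRUE` substitutes the lexicographically smallest parent
for bit-exact runs. Depths are therefore exactly the BFS distances — a
property the test-suite checks against `igraph::distances()` as an
independent oracle. Trees are built over the subnetwork induced by the
pathway's molecules; molecules unreachable from every marker are excluded
and logged.

## Hierarchy network

Two pathways are linked iff their molecule sets intersect. The hierarchical
levels of a shared molecule are its minimum depths across each pathway's
forest. Where the notion of the *lowest common molecule* was left open, the
package adopts: pick the shared molecule minimising the **sum** of its two
levels (closest to both marker roots), breaking ties by smallest molecule
id; levels count from 0 at the roots. The arrow then runs from the pathway
in which the molecule sits deeper (the more general one) to the pathway in
which it sits shallower (the more specific one); equal levels leave the
edge undirected, and a shared molecule reachable in neither forest leaves
an undirected edge with no recorded levels. These are documented package
conventions, deterministic and symmetric, not claims about any external
system's behaviour.

# Logic inference

## Rule generation

The MPIN-to-rules mapping is policy-controlled because either implication
direction is defensible:

- `generalize` (default): arrow general → specific emits
  `specific -> general` — a deficiency in a specific pathway implies one in
  its more general relative, since the shared molecule belongs to both.
- `specialize`: the reverse implication.
- `conjunctive`: additionally, a pathway with incoming arrows from
  $y_1 \dots y_k$ receives $(y_1 \wedge \dots \wedge y_k) \to x$.

Rules can also be authored directly in a small DSL (`Ri: EXPR -> EXPR`
with `& | !`, parentheses, `#` comments; `∧ ∨ ¬ →` accepted as aliases),
parsed at standard precedence (`!` > `&` > `|`) with line-and-caret error
reporting.

## Semantics and termination

The semantic contract is **classical propositional entailment**: an atom is
inferred iff it is true in every model of rules plus detected atoms.
Entailment is decided by clause-level resolution saturation with implicit
factoring and forward subsumption. Because every resolvent lives in the
finite clause space over the atom universe, the breadth-first saturation
terminates; by the prime-implicate completeness of resolution it derives
the unit clause of every entailed atom, and the empty clause exactly when
the base is contradictory. A contradictory base is flagged, every atom is
reported, and a warning is raised. Detected atoms absent from the rule base
are carried through unchanged (logged).

The proof trace is a presentation layer on top of this contract. Definite
chains are narrated with the classical named rules — modus ponens,
conjunction, simplification, addition (addition is used only during trace
construction, never to enlarge the saturation space) — and anything beyond
definite reasoning is shown as resolution steps over clausal restatements
of the rules. `verify_trace()` replays every step mechanically from its
supports, and `explain()` extracts the minimal renumbered sub-derivation of
one atom. Completeness relative to naive rule iteration is guaranteed (and
tested) on definite-clause bases; on arbitrary bases the engine is tested
against a truth-table model-enumeration oracle.

# Risk ranking

Combination weights count, per publication and combination, the sentences
in which at least one marker term of *every* member pathway occurs with all
selected mentions pairwise related — the same sentence semantics as the
extractor, so the worked weight matrix is a direct fixture
(`sddp_example("table2")`). A precomputed matrix can always be supplied
instead. Since the full power set of pathways is exponential, combinations
are enumerated up to `max_size` (default 3) or given explicitly.

Combination $c_i$ beats $c_j$ if it out-weighs $c_j$ in more publications
than the reverse; only strict `>` comparisons are used, so any strictly
increasing per-publication reweighting leaves all outcomes invariant. The
score is beats minus losses (a Copeland-style score, zero-sum by
construction) and the risk indicator is the competition rank
$r_i = 1 + \#\{j : s_j > s_i\}$ — tied scores share a rank and the
following ranks are skipped, the only scheme consistent with the worked
example's tie pattern.

# Synthetic data

`gen_corpus()` emulates what the extractor needs from real literature:
planted single-clause marker–disease sentences, cross-clause coordinator
decoys (true negatives for the strict rules), relative-pronoun sentences,
and background noise in which terms co-occur under independence — which
makes the z-score null exact. Every sentence is emitted with its bracketed
parse, so no external parser is needed anywhere in the tests. The defaults
define the reference study conditions: 200 abstracts of 4–8 sentences, a
vocabulary of 20 markers and 2 diseases, 10 planted pairs each appearing in
an abstract with probability 0.15, 20% of planted sentences expressed as
coordinator decoys and 15% through pronouns, and per-sentence noise
mention rates of 0.08. `gen_network_and_pathways()` adds an Erdős–Rényi
interaction network (30 molecules, edge probability 0.2) and pathway sets
with fixed pairwise overlaps.

What the generators do **not** emulate: real lexical variation and
ambiguity (surface forms are unambiguous tokens), parser errors, abbreviation
and coreference phenomena beyond the single pronoun rule, citation-level
correlation between abstracts, and the topology of curated interaction
databases. Passing the recovery tests therefore demonstrates that the
pipeline implements its own rules faithfully and separates planted signal
from independence-level noise — not that it attains any particular accuracy
on real corpora.

# Problem sizes and numerical choices

The shipped test-suite exercises: the worked ten-combination ranking
example (exact integer reproduction), 100 random graphs ($n = 30$,
$p = 0.2$) against the BFS oracle, 200 random rule bases on up to 12 atoms
against truth-table enumeration (plus 100 definite bases against the naive
fixpoint), and one 200-abstract generated corpus for extractor recovery
at the default thresholds (precision and recall at least 0.9 — a package
test policy for the reference conditions, not an external claim). These
sizes keep a full run in the order of a minute on one CPU while still
covering every code path; all stochastic tests run under fixed seeds.

Remaining conventions worth knowing: tokenisation splits on whitespace and
peels leading/trailing punctuation only, so hyphenated identifiers stay
intact; dictionary lookup is case-insensitive longest-match and
non-overlapping; TSV files are tab-separated UTF-8 with `#` comments and no
quoting, so golden files are bit-exact; and all randomness flows through
explicit seeds recorded in the run manifest.

# Limitations

- Only the two strict linguistic rules described above are built in; richer
  catalogues must be registered through the plugin interface.
- The heuristic sentence splitter is intentionally minimal; for real text a
  proper constituency parser should feed `post_parse()`.
- Dominance ranking is reported without uncertainty; no calibration of
  indicators to clinical time-to-onset is attempted.
- The resolution engine targets the desk scale of pathway rule bases
  (tens of atoms); it is not an industrial SAT solver.
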