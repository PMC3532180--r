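---
title: "Querying KiSAO and finding substitute simulation algorithms"
author: "kisaoquery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Querying KiSAO and finding substitute simulation algorithms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kisaoquery)
```

## The problem

A SED-ML simulation description names its algorithm by a KiSAO identifier,
e.g. `KISAO:0000039` for the tau-leaping method. A simulation tool reading
such a description faces two recurring tasks:

1. **resolution** — map the opaque identifier to a name, definition,
   synonyms and literature links, in any of the four identifier forms in
   circulation (short id, OWL IRI, MIRIAM URN, identifiers.org URL);
2. **substitution** — when the named algorithm is not implemented, find an
   implemented algorithm that will produce comparable results for the same
   simulation set-up.

KiSAO encodes the knowledge needed for both: a subclass hierarchy of
simulation algorithms, a hierarchy of algorithm *characteristics* (e.g.
*stochastic system behaviour*, *discrete variable*), a hierarchy of
algorithm *parameters*, and existential restrictions (`has characteristic`,
`has parameter`, `is hybrid of`, `has type`) linking them. kisaoquery loads
an OWL 2 RDF/XML release of such an ontology and answers both the
taxonomy-level and the application-level queries over it.

## The model

### Structural reasoning, not DL reasoning

KiSAO-shaped files use a small, regular fragment of OWL 2: named classes,
`rdfs:subClassOf` between named classes, and anonymous
`owl:someValuesFrom` restrictions over a handful of properties. The package
therefore implements a *structural* reasoner: the subclass axioms form a
directed acyclic graph (multiple parents are allowed), and everything else
is computed as graph closure. No tableau reasoning is attempted —
universal restrictions, property chains and disjointness are out of scope,
and a restriction over an unconfigured property is logged with its subject
IRI, recorded in `skippedConstructs()`, and skipped rather than treated as
fatal, so files from newer ontology releases still load.

Three derived structures drive every query; all are computed eagerly when
the ontology loads (for ontologies of KiSAO's size — hundreds of classes —
this costs milliseconds) and cached on the graph object:

* **closure** — transitive ancestor and descendant sets of every term;
* **branch assignment** — a term belongs to the algorithm, characteristic
  or parameter branch iff it is, or descends from, that branch's configured
  root; terms under no root are `"other"`, and a term under two roots is a
  format error;
* **inferred links** — an algorithm *possesses* every characteristic
  asserted on it **or on any subclass ancestor** (existential restrictions
  are inherited down the hierarchy), and this set is then closed **upward
  within the characteristic branch**: an algorithm with *stochastic system
  behaviour* also possesses *type of system behaviour*, because
  the subclass axiom between the two characteristics entails the weaker
  restriction. Parameters and hybrid links are inherited down the algorithm
  hierarchy the same way, but are *not* generalized upward — using
  *tau-leaping epsilon* does not entail using every other parameter.

### Hierarchy distance

Substitute ranking needs a notion of how far apart two algorithms sit.
The package defines the distance between algorithms $a$ and $b$ as the
length of the shortest **undirected** path between them in the subclass
graph, restricted to the algorithm branch (root included):

$$d(a, b) = \min_{c \,\in\, \mathrm{anc}^*(a)\cap\mathrm{anc}^*(b)}
  \big[\mathrm{up}(a, c) + \mathrm{up}(b, c)\big]$$

where $\mathrm{anc}^*(x)$ is $x$ plus its ancestors and
$\mathrm{up}(x, c)$ the minimal number of subclass steps from $x$ up to
$c$. Equivalently: breadth-first-search distance after forgetting edge
direction. This makes a parent distance 1 and a sibling distance 2, which
matches the intuitive ranking — the generic method directly above a
variant is a closer substitute than a sister variant. The hierarchy is
treated as a DAG: with multiple parents the minimum over all paths is
used. Two design points were genuinely open and are fixed as follows:

* paths may pass through any algorithm-branch class, including the branch
  root, but never through characteristic- or parameter-branch classes;
* `NA` (unreachable) is returned when the two algorithms sit in different
  connected components; such candidates sort after all reachable ones.

The distance is a true metric on each connected component (symmetry, zero
iff equal, triangle inequality) — the test suite verifies this on every
random fixture.

### Substitute search

`nMostSimilar(graph, a, n, types)` composes three pieces:

1. **candidates** — the non-deprecated algorithms whose inferred
   characteristic profile, *restricted to the requested characteristic
   types*, is set-equal to the query's
   (`algorithmsWithSameCharacteristics()`). A type filter keeps a
   characteristic iff it is one of the filter classes or their
   descendants. Set *equality* (not subset) is used: a substitute should
   have exactly the same behaviour within the filtered types, neither more
   nor less specific. Subset-style matching remains available separately
   through `algorithmsByCharacteristics()`.
2. **ranking** — ascending hierarchy distance to the query; ties broken by
   ascending numeric id. The tie-break is a deliberate, documented
   convention: within a distance stratum the candidates are scientifically
   interchangeable, and a deterministic order makes pipelines
   reproducible.
3. **truncation** — the first `n`; the query algorithm itself is never
   returned, and fewer than `n` rows are returned when fewer candidates
   exist.

On the worked-example fixture, the query for the Poisson tau-leaping
method, filtering on *type of system behaviour* and *type of variable*,
returns the tau-leaping method at distance 1 and the multinomial, binomial
and implicit variants at distance 2 — LSODE is excluded because its
filtered profile (deterministic behaviour, continuous variables) differs:

```{r worked-example}
owl <- generateExampleFixture(tempfile(fileext = ".owl"))
g <- loadOntology(owl)
k <- EXAMPLE_FIXTURE_IDS
nMostSimilar(g, k[["poisson_tau_leaping"]], 4,
             types = k[c("type_of_system_behaviour", "type_of_variable")])
```

### Closed-world negation

`algorithmsByCharacteristics(..., mode = "lack")` and `NOT` in
`algorithmsByQuery()` treat a characteristic as *absent* whenever it is not
inferable — closed-world negation. Open-world OWL negation would require
full DL reasoning and would rarely conclude anything from a KiSAO-shaped
file; for the actual use case — matching what a simulation tool can do —
the closed-world reading is the correct one. A direct consequence, kept as
a tested invariant: for any characteristic set, the possess- and
lack-results are disjoint and jointly cover all non-deprecated algorithms.

Deprecated terms stay resolvable by id and name (legacy SED-ML files must
still map to information), participate in closures, but are excluded from
every application-level candidate or result set: a substitute must be a
live term.

### The query grammar

`algorithmsByQuery()` accepts infix boolean expressions —
`AND`/`OR`/`NOT`, parentheses, case-insensitive keywords,
whitespace-insensitive. An atom names one term, by any identifier form or
by quoted label; the named term's branch decides the test (characteristic
atoms test possession, parameter atoms test use). This keeps the grammar
minimal while covering both atom kinds, at the cost that an atom whose
label is shared by several terms must be disambiguated by id.

## Identifiers

The canonical identifier is a string of exactly seven decimal digits.
`normalizeKisaoId()` accepts the four circulating renderings (plus the
underscore and bare-digit forms) case-insensitively in the prefix, and
`renderKisaoId()` reproduces each form exactly. Digit count is strict:
an eight-digit form — a typo pattern that occurs in the wild — is rejected
rather than truncated, because silent truncation can alias two distinct
terms.

## Configuration

Which IRIs carry the annotations and relations is a property of the
release, not of OWL. All of them are configurable
(`defaultOntologyConfig()`, `readOntologyConfig()`, one YAML file — an
annotated example ships in `inst/extdata/kisao-config.yaml`). The defaults
are the OBO-in-OWL annotation properties, readable relation IRIs in the
KiSAO namespace, and the KiSAO branch roots `kisao:0000000` (algorithms),
`kisao:0000097` (characteristics), `kisao:0000201` (parameters). Loading
from a URL is supported but never implicit; everything in the package's
tests runs from generated local files.

## What the fixture generators emulate

`exampleFixtureManifest()` encodes the worked example exactly: the
tau-leaping family (with the `tauL` exact synonym on kisao:0000039),
LSODE (kisao:0000071), the two characteristic types with their
stochastic/deterministic and discrete/continuous values, and the
*tau-leaping epsilon* parameter typed `double`. Terms without an
established id use synthetic ids in the reserved 9000000+ range, recorded
in `EXAMPLE_FIXTURE_IDS`.

`generateRandomOntology()` emits seeded random ontologies: each branch is
a rooted DAG grown by attaching every new term to 1–`maxParents` earlier
terms of its branch, links are sampled independently per
algorithm–characteristic and algorithm–parameter pair with probability
`linkDensity` (default 0.15), a `hybridFraction` of algorithms carry two
`is_hybrid_of` targets, 80% of parameters are typed, and 10% of terms are
deprecated by default. The same seed yields a byte-identical OWL file, and
the returned manifest is the ground truth the test suite's brute-force
oracles evaluate against (naive edge-expansion reachability, literal
fixpoint inference, igraph BFS distances, truth-table query evaluation).

What the random fixtures do **not** emulate: the topology statistics of a
real curated ontology (depth distribution, label conventions, annotation
richness), multilingual annotations, or constructs outside the supported
fragment. Tests passing on these fixtures demonstrate that the queries
implement their definitions exactly on arbitrary KiSAO-shaped DAGs; they
do not certify behaviour on OWL constructs the structural reasoner
deliberately skips.

The oracle sweep in the test suite uses 50 seeded fixtures with branch
sizes up to 200 algorithms, 60 characteristics and 40 parameters — large
enough to cover multi-parent DAGs, disconnected algorithm components and
deprecated-term handling, and comparable to a real release's branch sizes,
while keeping the whole suite under a couple of minutes on one CPU.

## Numerical and degenerate-input choices

* Ties at equal hierarchy distance: ascending numeric id, always.
* `n = 0` similar-algorithm queries return an empty result, not an error;
  negative `n` is a usage error.
* An empty characteristic list is a vacuous conjunction:
  `hasCharacteristic(g, a, character())` is `TRUE`, and every algorithm
  "possesses" the empty set.
* A zero-length (but non-`NULL`) type filter keeps no characteristics.
* A parameter without a declared `has_type` yields `NA`, not an error.
* Classes referenced by an axiom but never declared become unlabelled stub
  terms, so every edge and link endpoint always resolves.
* A cyclic subclass graph, and a term reachable from two branch roots, are
  format errors: both break the definitions the queries rest on.

## Known limitations

* Only the RDF/XML serialization is parsed (the form KiSAO ships in);
  Turtle or functional syntax would need conversion first.
* Characteristics are equally weighted in similarity ranking; weighted or
  prioritized characteristics are out of scope.
* Name search is exact or substring, case-insensitive; no fuzzy matching.
* Closed-world negation is an explicit modelling choice, not OWL
  semantics; results of `lack`/`NOT` queries are relative to what the
  loaded release asserts.
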