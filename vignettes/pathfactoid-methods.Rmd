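---
title: "Models and methods behind pathfactoid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pathfactoid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathfactoid)
```

# The problem

Author-driven pathway curation asks the scientists who discovered a molecular
interaction to record it themselves, in a structured form that databases and
inference tools can consume. The computational substrate for that workflow has
four parts, and `pathfactoid` implements each of them:

1. a **document model** — typed molecular entities (protein, RNA, DNA,
   chemical), labelled complexes, signed and mechanism-tagged pairwise
   interactions, and free-text context terms, all hanging off an article
   reference;
2. an **entity-grounding search** that maps the free-text label an author
   typed to a database record (NCBI Gene for genes and their products, ChEBI
   for small molecules), using ranked synonym similarity with organism
   prioritization;
3. **exporters** to the community standards used downstream: canonical JSON
   (the native round-trip format), SIF, SBGN-ML Process Description, and a
   minimal BioPAX Level 3;
4. **network-integration queries** over SIF graphs — merging networks from
   several sources, enumerating bounded-length regulatory paths, and
   measuring whether newly curated edges bridge previously disconnected
   pathway components.

# The document model

A `pathway_document` is an immutable value: every `add_*` operation returns
an updated copy, and the identifier of the new element is retrieved with
`last_id()`. Identifiers are opaque (`e1`, `x1`, `i1`, ...) and insertion
order is recorded on every element, because grounding uses it (see below)
and validation orders its findings by it.

Three structural rules are enforced at creation time, as classed errors:
participants of an interaction must differ (`self-interaction`) and must
resolve in the document (`unknown-element`); binding is the undirected
relation and cannot carry an activation or inhibition sign
(`sign-mechanism-conflict`); and complexes do not nest
(`nested-complex-unsupported`). Flat complexes match how curated drawings
depict them — a box enclosing plain entities — and refusing nesting loudly is
safer than silently flattening. Interactions are strictly pairwise; n-ary
reactions and stoichiometry are outside the model, as are modification sites
and mutations. Both plain entities and complexes may participate in
interactions.

Everything else is deferred to submission-time validation, which never
raises: `validate_document()` returns a table of issues ordered by severity
then insertion order. Five codes are defined: `empty-document` and
`unlabelled-node` are errors (a submittable document must name its nodes);
`ungrounded-entity`, `isolated-entity` and `mixed-organisms` are warnings.
Mixed organisms is deliberately a warning, not an error: cross-organism
documents are legitimate (host–pathogen work, humanized models), so the
check flags likely slips without blocking them.

The supported organism table (`pf_organisms()`) covers human plus eight
model organisms, keyed by NCBI taxon, with human first in the default
priority order; it accepts extensions (e.g. viral taxa) as plain named
entries rather than code changes.

# Entity grounding

## Normalization and similarity

Labels and record names are compared after a deterministic normalization:
Greek glyphs are spelled out (`α` → `alpha`), the string is case-folded, and
every non-alphanumeric run becomes a token boundary, so `NF-κB`, `NFKB` and
`nf kappab` collide the way a curator expects. The similarity between a
query and a record is the maximum over the record's canonical name and
synonyms of

$$ s(q, n) = 1 - \frac{d(q, n)}{\max(|q|, |n|)} $$

where $d$ is Levenshtein distance on the normalized strings, with an exact
normalized match pinned to $s = 1$. The measure is symmetric and bounded in
$[0, 1]$. No similarity measure is canonical for this task; an edit-ratio
over a synonym set was chosen because the dominant real input is a known
symbol or a close typographic variant of one, which this handles without any
training data.

## Ranking and organism priority

`search_records()` scores **every** record in the namespace implied by the
entity class (protein, RNA and DNA all search the gene namespace — the
product type is annotation, not a filter) and sorts by:

1. similarity score, descending;
2. organism priority: records whose organism appears earlier in the
   caller's organism context win, then the default order (human first, then
   the model organisms); chemicals carry no organism and skip this key;
3. shorter matched name (prefers primary symbols over long descriptive
   synonyms);
4. lexicographic record identifier (a final, total tie-break).

The ranking is thus fully deterministic, and the synonym index is an
optimization only — the contract is brute-force score-all-and-sort, and the
test suite holds the implementation to that contract with an independently
coded oracle.

The organism context is where document state feeds back into search:
`ground_document()` processes entities in insertion order and passes
`organism_history()` — the organisms of previously grounded genes, most
recent first — so that grounding a mouse gene steers the next ambiguous
symbol (`p53`) to its mouse record. Entities whose best hit scores below
`min_score` (default 0.5) stay ungrounded; a floor prevents absurd
assignments for junk labels, and 0.5 corresponds to allowing roughly half
the characters of a short symbol to disagree, which is already generous.

## The synthetic benchmark

No public gold standard exists for the author-typed-label task, so the
package generates its own dictionary and benchmark
(`generate_dictionary()`, `generate_benchmark()`), and the headline
accuracies are computed on that stand-in. The standard conditions are fixed
once in `benchmark_spec()`: 500 records over two organisms, 1000 queries,
and a perturbation mix of exact labels (55%), case changes (15%),
punctuation variants (12%), Greek-glyph/spelled-name swaps (5%),
truncations of multi-token names (8%) and distractors (5%).

Two dictionary features make the benchmark non-trivial. **Homolog
collisions** (30% of gene records) plant the same symbol under two
organisms, so a bare symbol is genuinely ambiguous and only organism
priority can resolve it; queries carry a context naming the truth's organism
90% of the time, emulating a curator who has already added same-organism
genes. **Near-miss pairs** (10%) plant symbols at edit distance 1 of each
other; the distractor perturbation applies a one-character edit to a truth
name, so for those records the query sits within two edits of a *different*
record's name and the ranker must weigh two nearly equal candidates. A
distractor built with no relation to its truth record would make the truth
unreachable at any cutoff and silently cap top-10 accuracy at 95%, which is
why the perturbation is anchored to the truth's own name.

What passing the accuracy thresholds on this benchmark shows is that the
normalization, similarity and priority machinery behaves as designed under
realistic name noise; it does **not** estimate accuracy on real articles,
whose label distribution (novel aliases, fusions, embedded species hints) is
richer than the generator's.

# Exporters

The native format is canonical JSON: fixed key order, element order by
insertion, UTF-8, with each element's insertion order serialized so that a
round-trip reproduces the document exactly — including the output of
`validate_document()`. `from_json()` validates while parsing and reports
`malformed-document` with the offending path, or `unknown-element` for
dangling references.

SIF export uses the Pathway Commons vocabulary so that exported edges merge
cleanly with Pathway Commons downloads: directed interactions map to
`controls-state-change-of` (or `controls-expression-of` for
transcription/translation), binding and other unsigned interactions to
`interacts-with`, and an *n*-member complex expands to its
$\binom{n}{2}$ `in-complex-with` pairs. Plain SIF cannot express signs; an
optional fourth column carries them, off by default. Node names prefer the
grounded canonical name, then the raw label, then the identifier — an
unlabelled, ungrounded node still serializes.

SBGN-ML (Process Description) renders each entity as its glyph class, each
complex as a container glyph with nested member glyphs, and each interaction
as a process (or association, for binding) with stimulation/inhibition,
consumption and production arcs. Coordinates come from a deterministic grid:
the data carry no layout, and a reproducible placeholder beats a
non-deterministic algorithm for an exchange artifact.

BioPAX Level 3 output is a minimal faithful mapping: physical-entity
subclasses with `UnificationXref`s, `Complex` with components, `Control`
over a `BiochemicalReaction` for directed state changes,
`TemplateReactionRegulation` over a `TemplateReaction` for expression
control, `ComplexAssembly` for binding, and `MolecularInteraction` for
unsigned associations — the one case the source model leaves open, mapped to
the least-committal BioPAX class. Context terms become comments on the
enclosing `Pathway`. No site-level modification detail is synthesized,
because the document model does not capture it.

# Network queries

`read_sif()` parses the three-column tab-separated dialect; unknown relation
tokens are kept verbatim and treated as undirected, `controls-*` relations
as directed. Undirected edges are stored with lexicographic endpoints and
duplicate triples collapse, accumulating per-source provenance tags —
which makes `merge_networks()` idempotent, commutative and associative.

`paths_between()` enumerates simple paths (no repeated node) with at most
`limit` edges. "Separation" is counted in edges, and by default only
directed `controls-*` edges are traversed — the regulatory-route reading —
with a flag to admit undirected edges in either orientation. Paths are
ordered by length then lexicographic node sequence, so output is
reproducible. Querying a node against itself returns the single zero-length
path rather than an error.

`connectivity_delta()` works on the undirected skeleton: it counts connected
components before and after adding a set of new edges and reports as
*bridging* those new edges whose endpoints lay in different pre-existing
components. The packaged schematic fixtures (`schematic_networks()`)
reproduce the shape of the published integration example — two disconnected
pathway components joined into one by two curated interactions, and a
three-edge SENP1-to-SOD2 regulatory chain — using only the handful of gene
symbols that anchor that example, not real pathway content.

# Numerical and design choices

* **Tie-breaking is total** everywhere results are ordered (search hits,
  SIF edges, paths, validation issues), so equal inputs give byte-identical
  outputs; several tests assert this literally.
* **Degenerate inputs**: empty labels normalize to an empty token sequence
  and are never grounded; empty queries return empty hit lists; empty
  documents export to valid (empty) JSON/XML; zero-edge networks merge and
  query without special cases.
* **Problem sizes** used by the shipped checks were chosen to exercise the
  contracts well inside interactive runtimes: the standard benchmark is
  500 records × 1000 queries (seconds to evaluate), ranking equivalence is
  checked on 100 random dictionaries of up to 200 records with 50 queries
  each, path-enumeration equivalence on 200 random graphs of up to 10
  nodes, and round-trip identity on 500 generated documents.
* **Generated documents** default to fully grounded, single-organism,
  fully connected output, so generator output validates with zero issues;
  ungrounded or sparse variants are explicit options, not defaults.
* **Seeds**: all generators are pure functions of spec + seed; the CLI
  refuses to simulate without an explicit `--seed`.

# Limitations

The grounding accuracy figures are properties of the synthetic stand-in
benchmark, not measurements on published articles. The similarity measure is
character-level; it has no notion of token importance, so a long descriptive
synonym can outscore a symbol for badly garbled queries. The BioPAX and
SBGN-ML mappings are one-way exports — there is no importer and no claim of
equivalence with any other tool's serialization of the same content. Path
enumeration is exhaustive and exponential in the worst case; it is intended
for the small `limit` values (≤ 3) regulatory-route queries use, not as a
general graph-mining primitive.
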