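---
title: "Mapping relational query results onto attributed networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping relational query results onto attributed networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relnet)
```

# The problem and the model

Interaction data in systems biology live in relational databases whose
schemas vary from lab to lab, so no fixed import tool covers them. relnet
treats SQL itself as the import language: any read-only `SELECT` can be
executed against a connected database, and its result table is mapped onto
an attributed directed multigraph by a user-supplied column role map.

The network model is deliberately small. A node is a text identifier plus
an attribute map; an edge is identified by the triple *(source, target,
type)* — rendered `"source (type) target"` — so parallel edges of
different types coexist while re-importing the same relationship converges
onto one edge. Attribute values are integer, real, text or boolean
scalars, or homogeneous vectors of those (list attributes). Edges are
stored directed, source → target as written by the role map; consumers
that want an undirected reading apply it downstream. Endpoints of an edge
always exist (auto-created empty if necessary) and removing a node removes
its incident edges, so the structure can never dangle.

Two assumptions matter in practice: node identifiers are compared as exact
case-sensitive text (no identifier normalization — joining databases with
inconsistent accession spellings is the user's responsibility), and
identifiers and edge types must not contain tab or newline characters,
which the line-oriented output formats could not represent.

# The four modes of operation

**Create network.** Each result row contributes its `source_id` value as a
node; if a `target_id` column is present and non-NULL, a target node and
an edge are added, typed by the `edge_type` column value or the constant
`"interaction"`. Attribute columns attach to source, target or edge after
automatic type conversion. A NULL id skips the whole row with a warning; a
NULL attribute value sets nothing — in particular it never clears an
attribute set earlier, so repeated enrichment cannot erase information.

**Load node / edge attributes.** These modes require at least one `?`
placeholder and launch the query once per processed element — the
selection, or every node/edge when the selection is empty. Placeholders
are instantiated from element fields: `ID` or an attribute name for nodes;
`SOURCE`, `TARGET`, `TYPE`, an edge attribute, or an endpoint attribute
for edges. When a bare attribute name exists on both an edge and its
endpoints, the edge attribute wins, then the *source* endpoint; the
explicit prefixes `SOURCE.x` / `TARGET.x` address an endpoint
unambiguously. An element missing a referenced attribute is skipped with a
warning rather than aborting the batch.

A per-element result with one row yields scalar attributes; with several
rows, each column becomes a list attribute in row order. The alternative —
keeping only the last row — would be silently lossy, so it was rejected.
Zero rows leave the element untouched. Columns whose every value merely
echoes back one of the bind values (the id column selected for the join)
are recognized by value comparison and dropped, since they would duplicate
the element key as an attribute; `keepEcho = TRUE` restores them.

**Expand network.** Also bind-driven, once per seed node. The role map
names the *neighbor* column as `source_id`; the seed is the implicit other
endpoint. New edges are written seed → neighbor by default (every new edge
is therefore incident to a seed), and `seedAsSource = FALSE` flips the
direction. Because node and edge insertion are merges, expanding twice
with the same seeds is a no-op — idempotence is the designed behavior, not
an accident. Note that an *empty* selection seeds all current nodes, so
repeating an empty-selection expansion can legitimately grow the frontier;
idempotence is stated for a fixed seed set.

Per-element execution is the semantic contract (one query per element,
observable through `queryCount()`); no batched rewrite is performed.

# Query validation and safety

Validation is lexical, not a full SQL parse: a state machine masks string
literals (`'…'` with `''` escapes), quoted identifiers (`"…"`, backticks)
and comments (`--`, `/* */`), then checks that the leading keyword is
`SELECT` — or `WITH`, since common-table-expression queries are SELECTs in
practice — and that no unquoted `;` is followed by further content. The
same masking yields the placeholder count, so a `?` inside a literal is
never mistaken for a bind position. This keeps validation portable across
engine dialects at the cost of not catching vendor-specific write
constructs hiding behind a `SELECT` keyword (none exist in the supported
engines' read statements). Bind values are passed as typed positional
database parameters, never interpolated into the text.

# Connection profiles and the query archive

A profile stores the access coordinates of one database under a short
name; a YAML store file holds many, enabling rapid switching within a
session. The embedded-file SQLite engine is the reference engine; the
profile abstraction does not leak engine syntax to callers. Secrets are
never persisted: a profile carries only the *name* of an environment
variable (`passwordRef`), so stores can be committed to version control.
The query history is most-recent-first with a default bound of 50 entries
(an interactive-scale choice; configurable), deduplicating immediate
repeats; favorites are named, editable, and exportable as a plain
`name<TAB>query` text document.

# Serialization choices

*SIF* is written tab-delimited, one edge per line plus bare-id lines for
isolated nodes; multi-target lines and the classic whitespace dialect are
accepted on read, and a two-field line is a hard parse error with its line
number. *GraphML* is the full-fidelity format: every attribute gets a
typed `<key>`; list attributes serialize as `|`-delimited strings (escape
`\|`, literal backslash `\\`, NA as the reserved token `\N`) with the
element type and delimiter declared in the key's `<desc>`. *Attribute
tables* are TSV keyed by `ID` (nodes) or `SOURCE`/`TYPE`/`TARGET` columns
(edges; a composite `KEY` column is accepted on read), with the type
declared in each header as `name:type`; an empty cell means "attribute
absent", which makes an empty text string unrepresentable in this format —
use GraphML when that distinction matters. Reading a table attaches
attributes to existing elements only and reports the count of unmatched
keys.

All writers emit nodes sorted bytewise by id and edges by composite key,
and doubles are rendered with `%.17g` (round-trip exact for IEEE doubles),
so identical networks always produce byte-identical files — determinism
that downstream pipelines can checksum.

# The synthetic fixtures

The fixture builders create real SQLite files and return the exact rows
they inserted (`GroundTruth`), so every assertion about mapper output is
computed from the inserted rows alone, never by re-querying the database
under test. One seeded generator drives all draws: equal specs give equal
databases and equal query answers.

The toy database defaults — 20 proteins, 40 interactions with half
confirmed, per-protein mass (5–150 kDa) and isoelectric point (3–12), 30
scored predictions — are the documented tutorial conditions for the four
example queries. Self-interactions (~5%) and duplicate pairs are allowed
deliberately: they exercise the mapper's merge path. Half of the
predictions reuse known interaction pairs (so edge enrichment finds
matches) and half are fresh pairs (so expansion adds neighbors). The three
case builders are miniatures of common deployments: a protein–domain
membership schema whose three-table join maps to a typed bipartite
network; a molecule–reaction participation schema with a shared
description table enriched through one query; and an ontology-term schema
of `nOntologies` disjoint complete `branching`-ary trees, so the mapped
parent-link network has exactly `nOntologies` weakly connected acyclic
components.

What the fixtures do *not* emulate: realistic biological identifiers or
value distributions, schema irregularities (mixed-case column names,
composite keys, views), multi-user or concurrent access, and server-engine
dialect differences — the embedded engine stands in for all engines.
Passing tests therefore demonstrate the mapping semantics, not robustness
against every production schema.

# Problem sizes and numerical notes

The test suite and the acceptance script run the toy fixture at its
default size, serialization round-trips on 100 randomized networks of up
to 6 nodes and 8 edge draws with mixed scalar/list attributes, a
placeholder corpus of 200 generated queries, and the term fixture at 3
ontologies × 15 terms — sizes chosen so the whole suite completes in
seconds while covering every degenerate case we identified: empty
networks and results, empty files, limit-exceeds-result previews,
zero-match enrichments, seeds without neighbors, NULL ids and values, and
duplicate edge keys. There are no numerical tolerances anywhere:
comparisons are exact by construction (typed values, `%.17g` doubles).

# Known limitations

Only the embedded SQLite engine can actually be opened in this build;
MySQL/PostgreSQL profiles are stored and validated but connecting requires
a driver this installation does not ship. List attributes bind into `?`
placeholders by their first element. Attribute-table columns assume one
type per attribute name across elements (true of mapper output, where
types come from the database schema). Edge composite keys cannot represent
identifiers containing `" ("`; use the three-column form there. None of
these touch the core mapping semantics.
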