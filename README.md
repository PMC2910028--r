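# relnet — attributed networks from relational database queries

Molecular interaction data — protein–protein interactions, pathway
memberships, ontology term relations — are overwhelmingly stored in
relational databases, each with its own schema. Importing them into a graph
analysis or visualization workflow usually means exporting tables to text
and re-importing them by hand, repeated every time the database changes.
relnet removes that loop: it executes read-only SQL `SELECT` statements
directly against any reachable database and maps the result sets onto an
attributed directed multigraph, headlessly and scriptably. It is written
for bioinformaticians who know their schema and a bit of SQL.

## The model

The central object is a directed multigraph `G = (V, E)` where nodes are
keyed by a text identifier and edges by the triple *(source, target,
type)*, each element carrying a map of typed attributes (integer, real,
text, boolean scalars, or homogeneous lists). A query result is a table
`R` of rows × typed columns; a **column role map** assigns each column one
of the roles *source id*, *target id*, *source/target/edge attribute*,
*edge type* or *ignore*. Four modes of operation map `R` onto `G`:

1. **Create network** — each row of one `SELECT` contributes a source node,
   optionally a target node and a typed edge, plus converted attribute
   values. Database field types convert automatically to attribute types;
   NULLs set nothing.
2. **Load node attributes** — a query with `?` bind variables is launched
   once per node (selected nodes, or all), the placeholders instantiated
   from that node's fields; returned columns become node attributes
   (single row → scalars, several rows → list attributes in row order).
3. **Load edge attributes** — the same, once per edge; bind references may
   use `SOURCE`, `TARGET`, `TYPE`, edge attributes, or endpoint node
   attributes (`SOURCE.x` / `TARGET.x`).
4. **Expand network** — once per seed node; each returned row adds a
   neighbor node and an edge incident to the seed.

Bind values are always passed to the database as typed positional
parameters, never spliced into the SQL text, and only single `SELECT`
(or `WITH … SELECT`) statements pass validation, so the engine is
read-only by construction. Networks are exchanged as SIF, GraphML (full
typed-attribute round-trip) and tab-separated attribute tables; named
connection profiles, a bounded query history and editable favorites make
multi-database sessions scriptable.

## Worked example

```r
library(relnet)

spec <- fixtureSpec(seed = 1)                 # 20 proteins, 40 interactions,
gt   <- buildToyDb(spec, "toy.db")            # half confirmed, 30 predictions
conn <- openConnection(connectionProfile("toy", "sqlite", "toy.db"))

q <- validateSelect(
  "SELECT protn1, protn2, intType, confirmed FROM interactions WHERE confirmed = 'Y'")
previewQuery(conn, q, limit = 3)
#> ResultTable: 3 row(s)
#>   protn1 <text>  protn2 <text>  intType <text>  confirmed <text>
#>   protn1 protn2 intType confirmed
#> 1     P4    P19 genetic         Y
#> 2     P7    P10      pp         Y
#> 3     P1     P6      pd         Y

net <- createNetwork(executeQuery(conn, q),
                     columnRoleMap(c("source", "target", "edgetype", "edgeattr")))
net
#> Network: 20 nodes, 20 edges
#>   attribute values: 20
#>   edge types: genetic, pd, pp
```

The 20 confirmed interaction rows of this fixture involve 20 distinct
proteins and 20 distinct (source, target, type) triples; each edge carries
its `confirmed = "Y"` flag as an attribute and its `intType` value as the
edge type. Enrichment then issues exactly one parameterized query per
node:

```r
net <- loadNodeAttributes(conn,
  validateSelect("SELECT protein, mass, pI FROM features WHERE protein = ?"),
  binds = "ID", net)
str(nodeAttrs(net, "P1"))
#> List of 2
#>  $ mass: num 140272
#>  $ pI  : num 3.98

writeSIF(net, "confirmed.sif")
writeGraphML(net, "confirmed.graphml")
```

`P1`'s mass (140272.4 Da) and isoelectric point (3.98) are exactly the
values the fixture generator inserted into the `features` table — the
ground truth every test asserts against. The same run is available
non-interactively through a YAML manifest (`runManifest()`) or the
`inst/scripts/relnet` command line (`profiles`, `preview`, `run`,
`fixtures` subcommands).

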