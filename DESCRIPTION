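Package: relnet
Title: Attributed Networks from Relational Database Queries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A headless engine that maps the result sets of SQL SELECT
    statements onto attributed directed multigraphs. Supports named database
    connection profiles, read-only query validation with positional bind
    variables, and four modes of operation: create a network from a result
    table, load node attributes, load edge attributes, and expand a network
    around selected seed nodes. Networks are exchanged as SIF, GraphML and
    tab-separated attribute tables. Includes deterministic synthetic database
    builders used as ground truth in tests, and a scriptable manifest runner.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    DBI,
    RSQLite,
    xml2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
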