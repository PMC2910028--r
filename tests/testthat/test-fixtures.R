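test_that("the toy builder honours its spec counts and determinism", {
  spec <- fixtureSpec(seed = 1, nProteins = 20, nInteractions = 40,
                      confirmedFraction = 0.5, nPredictions = 30)
  p1 <- withr::local_tempfile(fileext = ".db")
  p2 <- withr::local_tempfile(fileext = ".db")
  gt1 <- buildToyDb(spec, p1)
  gt2 <- buildToyDb(spec, p2)
  expect_identical(nrow(gt1$tables$interactions), 40L)
  expect_identical(nrow(gt1$tables$features), 20L)
  expect_identical(nrow(gt1$tables$predictedInteractions), 30L)
  expect_identical(sum(gt1$tables$interactions$confirmed == "Y"), 20L)
  expect_identical(gt1$tables, gt2$tables)
  # equal specs yield byte-identical database files
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))

  # identical specs give identical query answers
  for (sql in c("SELECT * FROM interactions", "SELECT * FROM features")) {
    c1 <- openConnection(connectionProfile("a", "sqlite", p1))
    c2 <- openConnection(connectionProfile("b", "sqlite", p2))
    expect_identical(resultRows(executeQuery(c1, validateSelect(sql))),
                     resultRows(executeQuery(c2, validateSelect(sql))))
    closeConnection(c1); closeConnection(c2)
  }
  expect_error(buildToyDb(spec, p1), "overwrite", class = "relnet_io_error")
})

test_that("querying the built database returns exactly the GroundTruth rows", {
  fx <- localToyDb(seed = 11)
  conn <- localConn(fx)
  for (tab in names(fx$gt$tables)) {
    got <- resultRows(executeQuery(conn, validateSelect(
      sprintf("SELECT * FROM %s", tab))))
    expect_identical(got, fx$gt$tables[[tab]], label = tab)
  }
})

test_that("all four documented example queries run against the toy fixture", {
  fx <- localToyDb(seed = 1)
  conn <- localConn(fx)
  for (nm in names(toyExampleQueries())) {
    q <- validateSelect(toyExampleQueries()[[nm]])
    binds <- as.list(rep("P1", placeholderCount(q)))
    expect_s4_class(executeQuery(conn, q, binds), "ResultTable")
  }
})

test_that("a degenerate confirmed fraction returns every interaction row", {
  path <- withr::local_tempfile(fileext = ".db")
  gt <- buildToyDb(fixtureSpec(seed = 2, confirmedFraction = 1.0), path)
  conn <- openConnection(connectionProfile("all", "sqlite", path))
  withr::defer(closeConnection(conn))
  res <- executeQuery(conn, validateSelect(toyExampleQueries()[["create"]]))
  expect_identical(resultRowCount(res), gt$spec$nInteractions)
})

test_that("the protein-domain fixture maps to a typed bipartite network", {
  path <- withr::local_tempfile(fileext = ".db")
  gt <- buildProteinDomainDb(fixtureSpec(seed = 4, nProteins = 10, nDomains = 5,
                                         membershipsPerProtein = 2), path)
  conn <- openConnection(connectionProfile("pd", "sqlite", path))
  withr::defer(closeConnection(conn))
  res <- executeQuery(conn, validateSelect(
    "SELECT m.protein, p.nodeType, m.domain, d.nodeType AS domType
     FROM membership m
     JOIN proteins p ON p.protein = m.protein
     JOIN domains d ON d.domain = m.domain"))
  net <- suppressWarnings(createNetwork(res, columnRoleMap(
    c("source", "sourceattr", "target", "targetattr"),
    c("", "nodeType", "", "nodeType"))))
  expect_identical(edgeCount(net), nrow(unique(gt$tables$membership)))
  types <- vapply(nodeIds(net), function(id) nodeAttrs(net, id)$nodeType,
                  character(1))
  expect_setequal(unique(types), c("protein", "domain"))
  # bipartite: every edge joins a protein to a domain
  for (key in edgeKeys(net)) {
    e <- parseEdgeKey(key)
    expect_identical(types[[e$source]], "protein")
    expect_identical(types[[e$target]], "domain")
  }
})

test_that("the reaction fixture supports creation plus description enrichment", {
  path <- withr::local_tempfile(fileext = ".db")
  gt <- buildReactionDb(fixtureSpec(seed = 5), path)
  conn <- openConnection(connectionProfile("rxn", "sqlite", path))
  withr::defer(closeConnection(conn))
  net <- suppressWarnings(createNetwork(
    executeQuery(conn, validateSelect(
      "SELECT molecule, reaction, role FROM participation")),
    columnRoleMap(c("source", "target", "edgetype"))))
  expect_identical(edgeCount(net),
                   nrow(unique(gt$tables$participation)))
  net <- loadNodeAttributes(conn, validateSelect(
    "SELECT id, description FROM descriptions WHERE id = ?"), "ID", net)
  descOracle <- stats::setNames(gt$tables$descriptions$description,
                                gt$tables$descriptions$id)
  for (id in nodeIds(net))
    expect_identical(nodeAttrs(net, id)$description, unname(descOracle[id]))
})

test_that("the term fixture forms one acyclic hierarchy per ontology", {
  skip_if_not_installed("igraph")
  path <- withr::local_tempfile(fileext = ".db")
  spec <- fixtureSpec(seed = 6, nOntologies = 4, nTermsPerOntology = 12,
                      branching = 3)
  gt <- buildTermDb(spec, path)
  conn <- openConnection(connectionProfile("terms", "sqlite", path))
  withr::defer(closeConnection(conn))
  net <- createNetwork(executeQuery(conn, validateSelect(
    "SELECT child, parent, relType FROM termRelations")),
    columnRoleMap(c("source", "target", "edgetype")))
  # independent graph oracle: igraph component and cycle analysis
  edges <- t(vapply(edgeKeys(net), function(k) {
    e <- parseEdgeKey(k); c(e$source, e$target)
  }, character(2)))
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  lone <- setdiff(nodeIds(net), igraph::V(g)$name)
  if (length(lone)) g <- g + igraph::vertices(lone)
  expect_identical(as.integer(igraph::count_components(g, mode = "weak")),
                   spec$nOntologies)
  expect_true(igraph::is_dag(g))
  expect_identical(nodeCount(net), spec$nOntologies * spec$nTermsPerOntology)
})
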