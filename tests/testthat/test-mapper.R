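# The four modes of operation, asserted against the fixture GroundTruth.

test_that("Mode 1 reproduces the confirmed-interaction network exactly", {
  fx <- localToyDb(seed = 1)
  conn <- localConn(fx)
  res <- executeQuery(conn, validateSelect(toyExampleQueries()[["create"]]))
  net <- suppressWarnings(createNetwork(res, toyRoles()))
  oracle <- mode1Oracle(fx$gt)
  expect_setequal(nodeIds(net), oracle$nodes)
  expect_setequal(edgeKeys(net), unique(oracle$edges))
  # every edge carries the confirmed flag and its own interaction type
  for (key in edgeKeys(net))
    expect_identical(edgeAttrs(net, key)$confirmed, "Y")
})

test_that("Mode 1 handles empty results, NULL ids and role violations", {
  fx <- localToyDb(seed = 1)
  conn <- localConn(fx)
  empty <- executeQuery(conn, validateSelect(
    "SELECT protn1, protn2 FROM interactions WHERE confirmed = 'neither'"))
  net <- createNetwork(empty, columnRoleMap(c("source", "target")))
  expect_identical(nodeCount(net), 0L)

  nullRow <- executeQuery(conn, validateSelect(
    "SELECT NULL AS s, 'X' AS t UNION ALL SELECT 'A', 'B'"))
  expect_warning(net2 <- createNetwork(nullRow, columnRoleMap(c("source", "target"))),
                 "NULL id")
  expect_setequal(nodeIds(net2), c("A", "B"))

  one <- executeQuery(conn, validateSelect("SELECT 'A' AS a, 'B' AS b"))
  expect_error(createNetwork(one, columnRoleMap(c("ignore", "ignore"))),
               "source_id", class = "relnet_mapping_error")
  expect_error(createNetwork(one, columnRoleMap(c("source", "edgeattr"))),
               "target_id", class = "relnet_mapping_error")
  expect_error(createNetwork(one, columnRoleMap("source")),
               "columns", class = "relnet_mapping_error")
  expect_error(columnRoleMap(c("source", "sauce")), class = "relnet_mapping_error")
})

test_that("Mode 2 equals an in-memory feature join, one query per node", {
  fx <- localToyDb(seed = 1)
  conn <- localConn(fx)
  net <- suppressWarnings(createNetwork(
    executeQuery(conn, validateSelect(toyExampleQueries()[["create"]])),
    toyRoles()))
  q <- validateSelect(toyExampleQueries()[["node_attrs"]])
  resetQueryCount(conn)
  net2 <- loadNodeAttributes(conn, q, "ID", net)
  expect_identical(queryCount(conn), nodeCount(net))

  oracle <- featureJoinOracle(fx$gt, nodeIds(net2))
  for (id in nodeIds(net2)) {
    expect_identical(nodeAttrs(net2, id)$mass, oracle[[id]]$mass, label = id)
    expect_identical(nodeAttrs(net2, id)$pI, oracle[[id]]$pI, label = id)
    # the echoed id column is not stored as an attribute
    expect_null(nodeAttrs(net2, id)$protein)
  }

  # an explicit selection processes exactly those nodes
  sel <- nodeIds(net)[1:3]
  resetQueryCount(conn)
  net3 <- loadNodeAttributes(conn, q, "ID", net, selection = sel)
  expect_identical(queryCount(conn), 3L)
  enriched <- vapply(nodeIds(net3),
                     function(id) !is.null(nodeAttrs(net3, id)$mass), logical(1))
  expect_setequal(nodeIds(net3)[enriched], sel)

  expect_error(loadNodeAttributes(conn, q, "ID", net, selection = "NOPE"),
               class = "relnet_mapping_error")
  expect_error(loadNodeAttributes(conn, q, "SOURCE", net),
               class = "relnet_mapping_error")
  # a query matching nothing leaves the network attribute-identical
  net4 <- loadNodeAttributes(conn, validateSelect(
    "SELECT mass FROM features WHERE protein = ? AND mass < 0"), "ID", net)
  expect_true(sameNetwork(net, net4))
})

test_that("Mode 2 keeps echoes on request and builds list attributes in row order", {
  fx <- localToyDb(seed = 1)
  conn <- localConn(fx)
  net <- addNode(emptyNetwork(), "P3")
  q <- validateSelect(toyExampleQueries()[["node_attrs"]])
  withEcho <- loadNodeAttributes(conn, q, "ID", net, keepEcho = TRUE)
  expect_identical(nodeAttrs(withEcho, "P3")$protein, "P3")

  ints <- fx$gt$tables$interactions
  pick <- names(which(table(ints$protn1) > 1))[1]
  multi <- loadNodeAttributes(conn, validateSelect(
    "SELECT intType FROM interactions WHERE protn1 = ?"), "ID",
    addNode(emptyNetwork(), pick))
  expect_identical(nodeAttrs(multi, pick)$intType,
                   ints$intType[ints$protn1 == pick])
})

test_that("Mode 3 loads predicted type and score onto matching edges", {
  fx <- localToyDb(seed = 1)
  conn <- localConn(fx)
  net <- suppressWarnings(createNetwork(
    executeQuery(conn, validateSelect(toyExampleQueries()[["create"]])),
    toyRoles()))
  q <- validateSelect(toyExampleQueries()[["edge_attrs"]])
  resetQueryCount(conn)
  net2 <- suppressWarnings(loadEdgeAttributes(conn, q, c("SOURCE", "TARGET"), net))
  expect_identical(queryCount(conn), edgeCount(net))

  preds <- fx$gt$tables$predictedInteractions
  for (key in edgeKeys(net2)) {
    e <- parseEdgeKey(key)
    hit <- preds[preds$protn1 == e$source & preds$protn2 == e$target, ]
    got <- edgeAttrs(net2, key)$score
    if (nrow(hit) == 0L) expect_null(got)
    else expect_identical(got, hit$score, label = key)
  }
  # at least one edge of this fixture has a prediction
  expect_true(any(vapply(edgeKeys(net2),
                         function(k) !is.null(edgeAttrs(net2, k)$score),
                         logical(1))))

  # empty selection on an edgeless network issues no query
  resetQueryCount(conn)
  lone <- addNode(emptyNetwork(), "A")
  expect_true(sameNetwork(lone, loadEdgeAttributes(conn, q, c("SOURCE", "TARGET"),
                                                   lone)))
  expect_identical(queryCount(conn), 0L)
})

test_that("Mode 4 expansion is local to its seeds and idempotent", {
  fx <- localToyDb(seed = 1)
  conn <- localConn(fx)
  net <- suppressWarnings(createNetwork(
    executeQuery(conn, validateSelect(toyExampleQueries()[["create"]])),
    toyRoles()))
  seeds <- nodeIds(net)[1:4]
  q <- validateSelect(toyExampleQueries()[["expand"]])
  roles <- columnRoleMap(c("source", "edgetype", "edgeattr"))
  before <- edgeKeys(net)
  resetQueryCount(conn)
  net2 <- expandNetwork(conn, q, "ID", roles, net, selection = seeds)
  expect_identical(queryCount(conn), length(seeds))

  newKeys <- setdiff(edgeKeys(net2), before)
  for (key in newKeys)
    expect_true(parseEdgeKey(key)$source %in% seeds, label = key)
  # expected neighbor set straight from the GroundTruth predictions
  preds <- fx$gt$tables$predictedInteractions
  wanted <- preds[preds$protn1 %in% seeds, ]
  expect_setequal(nodeIds(net2), union(nodeIds(net), wanted$protn2))
  expect_setequal(newKeys,
                  setdiff(edgeKey(wanted$protn1, wanted$protn2, wanted$intType),
                          before))

  net3 <- expandNetwork(conn, q, "ID", roles, net2, selection = seeds)
  expect_true(sameNetwork(net2, net3))

  # a seed with no predictions changes nothing
  noPred <- setdiff(paste0("P", 1:20), preds$protn1)
  if (length(noPred)) {
    quiet <- expandNetwork(conn, q, "ID", roles, net, selection = noPred[1])
    expect_true(sameNetwork(net, quiet))
  }

  # flipped direction: new edges point into the seed
  flipped <- expandNetwork(conn, q, "ID", roles, net, selection = seeds[1],
                           seedAsSource = FALSE)
  fkeys <- setdiff(edgeKeys(flipped), before)
  for (key in fkeys) expect_identical(parseEdgeKey(key)$target, seeds[1])
  expect_error(expandNetwork(conn, q, "ID",
                             columnRoleMap(c("source", "target", "edgeattr")),
                             net, selection = seeds),
               class = "relnet_mapping_error")
})

test_that("creating then enriching equals a single two-table join via Mode 1", {
  fx <- localToyDb(seed = 1)
  conn <- localConn(fx)
  looped <- loadNodeAttributes(
    conn, validateSelect(toyExampleQueries()[["node_attrs"]]), "ID",
    suppressWarnings(createNetwork(
      executeQuery(conn, validateSelect(toyExampleQueries()[["create"]])),
      toyRoles())))
  join <- suppressWarnings(createNetwork(
    executeQuery(conn, validateSelect(
      "SELECT i.protn1, i.protn2, i.intType, i.confirmed,
              f1.mass AS m1, f1.pI AS p1, f2.mass AS m2, f2.pI AS p2
       FROM interactions i
       JOIN features f1 ON f1.protein = i.protn1
       JOIN features f2 ON f2.protein = i.protn2
       WHERE i.confirmed = 'Y'")),
    columnRoleMap(
      c("source", "target", "edgetype", "edgeattr",
        "sourceattr", "sourceattr", "targetattr", "targetattr"),
      c("", "", "", "", "mass", "pI", "mass", "pI"))))
  expect_true(sameNetwork(looped, join))
})

test_that("enrichment modes demand bind variables and matching references", {
  fx <- localToyDb(seed = 1)
  conn <- localConn(fx)
  net <- addNode(emptyNetwork(), "P1")
  noBind <- validateSelect("SELECT mass FROM features")
  expect_error(loadNodeAttributes(conn, noBind, character(), net),
               "bind", class = "relnet_mapping_error")
  q <- validateSelect(toyExampleQueries()[["node_attrs"]])
  expect_error(loadNodeAttributes(conn, q, c("ID", "ID"), net),
               class = "relnet_usage_error")
  # node missing the referenced bind attribute is skipped with a warning
  resetQueryCount(conn)
  expect_warning(out <- loadNodeAttributes(conn, validateSelect(
    "SELECT mass FROM features WHERE protein = ?"), "alias", net), "skipped")
  expect_true(sameNetwork(net, out))
  expect_identical(queryCount(conn), 0L)
})
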