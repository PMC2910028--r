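test_that("SELECT validation accepts the documented queries and counts binds", {
  q1 <- validateSelect(
    "SELECT protn1, protn2, intType, confirmed FROM interactions WHERE confirmed = 'Y'")
  expect_identical(placeholderCount(q1), 0L)
  q3 <- validateSelect(
    "SELECT protn1, protn2, intType, score FROM predictedInteractions WHERE protn1 = ? AND protn2 = ?")
  expect_identical(placeholderCount(q3), 2L)
  # '?' inside a string literal is not a bind position
  expect_identical(placeholderCount(validateSelect(
    "SELECT x FROM t WHERE note = 'what?'")), 0L)
  # common-table-expression queries are read-only SELECTs
  expect_identical(placeholderCount(validateSelect(
    "WITH c AS (SELECT protn1 FROM interactions) SELECT * FROM c WHERE protn1 = ?")), 1L)
})

test_that("write statements and multi-statement input are rejected by name", {
  err <- expect_error(validateSelect("DROP TABLE interactions"),
                      class = "relnet_query_error")
  expect_match(conditionMessage(err), "DROP")
  expect_error(validateSelect("INSERT INTO t VALUES (1)"), "INSERT",
               class = "relnet_query_error")
  expect_error(validateSelect("UPDATE t SET a = 1"), "UPDATE")
  expect_error(validateSelect("SELECT 1; DROP TABLE t"), "multiple",
               class = "relnet_query_error")
  # a quoted semicolon or a trailing one is fine
  expect_s4_class(validateSelect("SELECT 1;"), "ValidatedQuery")
  expect_s4_class(validateSelect("SELECT * FROM t WHERE a = 'x;y'"),
                  "ValidatedQuery")
  expect_error(validateSelect("   "), class = "relnet_query_error")
})

test_that("placeholder counting agrees with the quote-stripping oracle", {
  for (sql in sqlCorpus(n = 80)) {
    expect_identical(countPlaceholders(sql), placeholderOracle(sql),
                     label = sql)
  }
})

test_that("execution returns typed rows, preserves NULLs and checks binds", {
  fx <- localToyDb(seed = 2)
  conn <- localConn(fx)
  q <- validateSelect("SELECT protein, mass, pI FROM features WHERE protein = ?")
  res <- executeQuery(conn, q, list("P7"))
  want <- fx$gt$tables$features[fx$gt$tables$features$protein == "P7", ]
  expect_identical(resultRows(res)$mass, want$mass)
  expect_identical(resultRows(res)$pI, want$pI)
  expect_identical(resultColumns(res), c("protein", "mass", "pI"))
  expect_identical(resultTypes(res), c("text", "real", "real"))

  empty <- executeQuery(conn, q, list("NOSUCH"))
  expect_identical(resultRowCount(empty), 0L)
  expect_identical(resultColumns(empty), c("protein", "mass", "pI"))

  nulls <- executeQuery(conn, validateSelect("SELECT NULL AS x, 1 AS y"))
  expect_true(is.na(resultRows(nulls)$x))

  before <- queryCount(conn)
  expect_error(executeQuery(conn, validateSelect(
    "SELECT * FROM predictedInteractions WHERE protn1 = ? AND protn2 = ?"),
    list("P1")), class = "relnet_usage_error")
  # the bind-count mismatch is caught before touching the database
  expect_identical(queryCount(conn), before)
  expect_error(executeQuery(conn, validateSelect("SELECT nope FROM interactions")),
               class = "relnet_query_error")
})

test_that("preview returns the head of the full result order", {
  fx <- localToyDb(seed = 2)
  conn <- localConn(fx)
  q <- validateSelect("SELECT protn1, protn2 FROM interactions")
  full <- resultRows(executeQuery(conn, q))
  prev <- previewQuery(conn, q, limit = 5)
  expect_identical(resultRowCount(prev), 5L)
  expect_identical(resultRows(prev), utils::head(full, 5))
  small <- previewQuery(conn, validateSelect(
    "SELECT protn1 FROM interactions LIMIT 3"), limit = 5)
  expect_identical(resultRowCount(small), 3L)
  expect_error(previewQuery(conn, q, limit = 0), class = "relnet_usage_error")
})

test_that("history is bounded, deduplicated and persisted; favorites are editable", {
  arc <- queryArchive(bound = 5L)
  arc <- recordQuery(arc, "SELECT 1")
  arc <- recordQuery(arc, "SELECT 1")  # consecutive repeat: one entry
  expect_identical(queryHistory(arc), "SELECT 1")
  for (i in 1:6) arc <- recordQuery(arc, sprintf("SELECT %d FROM t", i))
  expect_length(queryHistory(arc), 5L)
  expect_identical(queryHistory(arc)[1], "SELECT 6 FROM t")
  expect_false("SELECT 1" %in% queryHistory(arc))  # oldest evicted

  path <- withr::local_tempfile(fileext = ".yaml")
  arc2 <- queryArchive(path, bound = 5L)
  arc2 <- recordQuery(arc2, "SELECT a FROM b")
  arc2 <- saveFavorite(arc2, "enrich", "SELECT mass FROM features WHERE protein = ?")
  expect_named(listFavorites(arc2), "enrich")
  reloaded <- queryArchive(path)
  expect_identical(queryHistory(reloaded), queryHistory(arc2))
  expect_identical(listFavorites(reloaded), listFavorites(arc2))
  reloaded <- saveFavorite(reloaded, "enrich", "SELECT 2")  # editable
  expect_identical(unname(listFavorites(reloaded)["enrich"]), "SELECT 2")
  expect_error(deleteFavorite(reloaded, "nope"), "no favorite",
               class = "relnet_usage_error")
  reloaded <- deleteFavorite(reloaded, "enrich")
  expect_length(listFavorites(reloaded), 0L)

  favPath <- withr::local_tempfile(fileext = ".txt")
  arc2 <- saveFavorite(arc2, "count", "SELECT COUNT(*) FROM interactions")
  exportFavorites(arc2, favPath)
  arc3 <- importFavorites(queryArchive(bound = 5L), favPath)
  expect_identical(sort(names(listFavorites(arc3))),
                   sort(names(listFavorites(arc2))))
})

test_that("an engine session never changes any database table", {
  fx <- localToyDb(seed = 4)
  conn <- localConn(fx)
  before <- tableSnapshots(conn)
  net <- createNetwork(executeQuery(conn, validateSelect(
    toyExampleQueries()[["create"]])), toyRoles())
  net <- loadNodeAttributes(conn, validateSelect(toyExampleQueries()[["node_attrs"]]),
                            "ID", net)
  net <- suppressWarnings(loadEdgeAttributes(
    conn, validateSelect(toyExampleQueries()[["edge_attrs"]]),
    c("SOURCE", "TARGET"), net))
  net <- expandNetwork(conn, validateSelect(toyExampleQueries()[["expand"]]), "ID",
                       columnRoleMap(c("source", "edgetype", "edgeattr")), net)
  expect_identical(tableSnapshots(conn), before)
})
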