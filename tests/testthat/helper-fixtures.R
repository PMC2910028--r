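# Shared helpers: temporary fixture databases, a randomized network
# generator, and the independent oracles used against the implementation.

localToyDb <- function(seed = 1, ..., env = parent.frame()) {
  path <- tempfile(fileext = ".db")
  gt <- buildToyDb(fixtureSpec(seed = seed, ...), path)
  withr::defer(unlink(path), envir = env)
  list(path = path, gt = gt,
       profile = connectionProfile(paste0("toy", seed), "sqlite", path))
}

localConn <- function(fx, env = parent.frame()) {
  conn <- openConnection(fx$profile)
  withr::defer(closeConnection(conn), envir = env)
  conn
}

toyRoles <- function() columnRoleMap(c("source", "target", "edgetype", "edgeattr"))

# Independent Mode-1 oracle, computed from the GroundTruth rows alone.
mode1Oracle <- function(gt) {
  conf <- gt$tables$interactions[gt$tables$interactions$confirmed == "Y", ]
  list(nodes = union(conf$protn1, conf$protn2),
       edges = edgeKey(conf$protn1, conf$protn2, conf$intType))
}

# Independent placeholder-counting oracle: strip quoted regions and comments
# with regular expressions (a different mechanism than the engine's state
# machine), then count remaining '?' characters.
placeholderOracle <- function(sql) {
  s <- gsub("'([^']|'')*'", " ", sql)
  s <- gsub('"[^"]*"', " ", s)
  s <- gsub("`[^`]*`", " ", s)
  s <- gsub("/\\*([^*]|\\*[^/])*\\*/", " ", s)
  s <- gsub("--[^\n]*", " ", s)
  sum(strsplit(s, "", fixed = TRUE)[[1]] == "?")
}

# Generated corpus of SELECTs with '?' inside and outside literals/comments.
sqlCorpus <- function(n = 60, seed = 7) {
  set.seed(seed)
  frag <- c("a = ?", "b = 'x?'", "c = ?", "note = 'what?'", "d = \"q?\"",
            "e = ? -- really?\n", "f = 'it''s ok?'", "g = /* eh? */ ?",
            "h = `col?`", "i IN (?, ?)", "j = 'multi ?? marks'")
  vapply(seq_len(n), function(i) {
    k <- sample(1:4, 1)
    paste0("SELECT x FROM t WHERE ",
           paste(sample(frag, k, replace = TRUE), collapse = " AND "))
  }, character(1))
}

# Deterministic randomized attributed network; attribute names keep a fixed
# name -> type mapping so attribute-table columns are consistently typed.
randomNetwork <- function(seed) {
  set.seed(seed)
  pool <- list(
    mass = function() round(runif(1, 1, 100), 4),
    copies = function() sample.int(50L, 1),
    essential = function() sample(c(TRUE, FALSE), 1),
    note = function() paste0("txt", sample.int(99L, 1)),
    `half life` = function() runif(1),
    tags = function() paste0("tag|", sample(letters, sample(2:4, 1))),
    scores = function() round(runif(sample(2:4, 1)), 3),
    counts = function() sample.int(9L, sample(2:4, 1), replace = TRUE),
    flags = function() sample(c(TRUE, FALSE), sample(2:3, 1), replace = TRUE))
  randAttrs <- function() {
    nms <- sample(names(pool), sample(0:4, 1))
    stats::setNames(lapply(nms, function(nm) pool[[nm]]()), nms)
  }
  net <- emptyNetwork()
  nNodes <- sample(0:6, 1)
  ids <- sprintf("N%02d", seq_len(nNodes))
  for (id in ids) net <- addNode(net, id, randAttrs())
  if (nNodes >= 2) {
    for (k in seq_len(sample(0:8, 1))) {
      ends <- sample(ids, 2, replace = TRUE)
      net <- suppressWarnings(addEdge(net, ends[1], ends[2],
                                      sample(c("pp", "pd", "reg"), 1),
                                      randAttrs()))
    }
  }
  net
}

textFileWith <- function(...) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(...), path)
  path
}

# Canonical dump of every table of a database, for before/after comparisons.
tableSnapshots <- function(conn) {
  tabs <- sort(DBI::dbListTables(conn@db))
  stats::setNames(lapply(tabs, function(t) {
    df <- DBI::dbReadTable(conn@db, t)
    paste(capture.output(print(df)), collapse = "\n")
  }), tabs)
}

# Expected per-node attribute map from a GroundTruth features table,
# following the scalar/list rule (1 row -> scalars, >1 rows -> lists).
featureJoinOracle <- function(gt, ids) {
  feats <- gt$tables$features
  stats::setNames(lapply(ids, function(id) {
    rows <- feats[feats$protein == id, , drop = FALSE]
    if (nrow(rows) == 0L) return(list())
    if (nrow(rows) == 1L) list(mass = rows$mass, pI = rows$pI)
    else list(mass = rows$mass, pI = rows$pI)
  }), ids)
}

isScalarValue <- function(v) {
  is.atomic(v) && length(v) == 1L &&
    (is.integer(v) || is.double(v) || is.character(v) || is.logical(v))
}
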