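#' @import methods
NULL

SUPPORTED_ENGINES <- c("sqlite", "mysql", "postgres")

ROLE_LEVELS <- c("source_id", "target_id", "source_attr", "target_attr",
                 "edge_attr", "edge_type", "ignore")

DB_TYPE_LEVELS <- c("integer", "real", "text", "boolean", "unknown")

#' Named database connection profile
#'
#' A \code{ConnectionProfile} collects the access coordinates of one
#' relational database under a short unique name, so that a session can
#' switch rapidly between databases. The \code{sqlite} engine is the
#' embedded-file reference engine: \code{location} is a file path and
#' \code{database} must be empty. For server engines (\code{mysql},
#' \code{postgres}) \code{location} is \code{host} or \code{host:port}.
#' Secrets are never stored: \code{passwordRef} names an environment
#' variable that holds the password at connect time.
#'
#' @slot name short unique label.
#' @slot engine one of \code{"sqlite"}, \code{"mysql"}, \code{"postgres"}.
#' @slot location file path (sqlite) or host\[:port\] (server engines).
#' @slot database schema name; empty for sqlite.
#' @slot user account name, may be empty.
#' @slot passwordRef name of the environment variable holding the password.
#' @seealso [connectionProfile()], [openConnection()], [ProfileStore-class]
#' @exportClass ConnectionProfile
setClass("ConnectionProfile", representation(
  name = "character", engine = "character", location = "character",
  database = "character", user = "character", passwordRef = "character"
))

setValidity("ConnectionProfile", function(object) {
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    return("profile name must be a non-empty string")
  if (length(object@engine) != 1L || !object@engine %in% SUPPORTED_ENGINES)
    return(sprintf("engine must be one of: %s", paste(SUPPORTED_ENGINES, collapse = ", ")))
  if (object@engine == "sqlite") {
    if (!nzchar(object@location))
      return("sqlite profiles need a non-empty file path in 'location'")
    if (nzchar(object@database))
      return("sqlite profiles must have an empty 'database' (the file is the database)")
  }
  TRUE
})

#' Persistent store of connection profiles
#'
#' Keeps [ConnectionProfile-class] objects keyed by name and persists them
#' to a single human-editable YAML file. Loading a saved store reproduces
#' the same profile set field by field.
#'
#' @slot path config file location.
#' @slot profiles named list of [ConnectionProfile-class] objects.
#' @seealso [profileStore()], [saveProfile()], [loadProfileStore()]
#' @exportClass ProfileStore
setClass("ProfileStore", representation(path = "character", profiles = "list"))

setValidity("ProfileStore", function(object) {
  if (length(object@path) != 1L) return("path must be a single string")
  nms <- names(object@profiles)
  if (length(object@profiles) &&
      (is.null(nms) || anyDuplicated(nms) || any(!nzchar(nms))))
    return("profiles must be uniquely named")
  for (p in object@profiles) {
    if (!is(p, "ConnectionProfile")) return("profiles must be ConnectionProfile objects")
  }
  TRUE
})

#' Open handle on one database
#'
#' Wraps a live DBI connection together with the profile it came from and a
#' small statistics environment (number of statements executed), which tests
#' and the manifest runner use to verify the one-query-per-element contract
#' of the enrichment modes.
#'
#' @slot profile the [ConnectionProfile-class] that was opened.
#' @slot db the underlying DBI connection.
#' @slot stats environment with counter \code{queries}.
#' @seealso [openConnection()], [queryCount()]
#' @exportClass ConnectionHandle
setClass("ConnectionHandle",
         representation(profile = "ConnectionProfile", db = "ANY",
                        stats = "environment"))

#' A validated read-only SELECT statement
#'
#' Produced by [validateSelect()]: the text is guaranteed to be a single
#' SELECT (or WITH ... SELECT) statement, and \code{placeholderCount} is the
#' number of \code{?} bind positions outside string literals and comments.
#'
#' @slot text the SQL text.
#' @slot placeholderCount non-negative integer.
#' @exportClass ValidatedQuery
setClass("ValidatedQuery",
         representation(text = "character", placeholderCount = "integer"))

setValidity("ValidatedQuery", function(object) {
  if (length(object@text) != 1L || !nzchar(object@text)) return("empty query text")
  if (length(object@placeholderCount) != 1L || object@placeholderCount < 0L)
    return("placeholderCount must be a non-negative integer")
  TRUE
})

#' Tabular answer of one query execution
#'
#' Rows and columns exactly as returned by the database, in database order,
#' with one declared type per column (\code{integer}, \code{real},
#' \code{text}, \code{boolean} or \code{unknown}). \code{NA} entries are
#' database NULLs.
#'
#' @slot columnNames ordered column labels.
#' @slot columnTypes declared type per column.
#' @slot rows data.frame holding the records.
#' @seealso [executeQuery()], [previewQuery()]
#' @exportClass ResultTable
setClass("ResultTable", representation(
  columnNames = "character", columnTypes = "character", rows = "data.frame"
))

setValidity("ResultTable", function(object) {
  if (length(object@columnNames) != length(object@columnTypes))
    return("one declared type per column is required")
  if (ncol(object@rows) != length(object@columnNames))
    return("every row must have exactly one value slot per column")
  if (!all(object@columnTypes %in% DB_TYPE_LEVELS))
    return("unknown column type label")
  TRUE
})

#' Query history and favorites
#'
#' \code{history} is a most-recent-first list of executed query texts,
#' bounded at \code{bound} entries; an immediate repeat of the newest entry
#' is not appended twice. \code{favorites} is a named, editable list of
#' stored query texts. The archive persists to a YAML file next to the
#' profile store.
#'
#' @slot history character vector, newest first.
#' @slot favorites named character vector.
#' @slot bound maximum history length.
#' @slot path persistence location ("" for in-memory only).
#' @seealso [queryArchive()], [recordQuery()], [saveFavorite()]
#' @exportClass QueryArchive
setClass("QueryArchive", representation(
  history = "character", favorites = "character",
  bound = "integer", path = "character"
))

setValidity("QueryArchive", function(object) {
  if (length(object@bound) != 1L || object@bound < 1L)
    return("history bound must be a positive integer")
  if (length(object@history) > object@bound)
    return("history exceeds its bound")
  if (length(object@favorites) && is.null(names(object@favorites)))
    return("favorites must be named")
  TRUE
})

#' Column-to-network role assignment
#'
#' Tells the mapper what each result column means: the source node id, the
#' target node id, an attribute of the source/target/edge, the edge type, or
#' nothing. Attribute roles carry the attribute name to use, defaulting to
#' the column name.
#'
#' @slot roles one of \code{source_id}, \code{target_id}, \code{source_attr},
#'   \code{target_attr}, \code{edge_attr}, \code{edge_type}, \code{ignore}
#'   per column.
#' @slot attrNames attribute name per column ("" where not applicable).
#' @seealso [columnRoleMap()], [createNetwork()]
#' @exportClass ColumnRoleMap
setClass("ColumnRoleMap",
         representation(roles = "character", attrNames = "character"))

setValidity("ColumnRoleMap", function(object) {
  if (!all(object@roles %in% ROLE_LEVELS))
    return(sprintf("roles must be among: %s", paste(ROLE_LEVELS, collapse = ", ")))
  if (length(object@attrNames) != length(object@roles))
    return("one attribute name slot per role is required")
  if (sum(object@roles == "source_id") > 1L) return("at most one source_id column")
  if (sum(object@roles == "target_id") > 1L) return("at most one target_id column")
  if (sum(object@roles == "edge_type") > 1L) return("at most one edge_type column")
  TRUE
})

#' Attributed directed multigraph
#'
#' The in-memory network all four mapping modes read and write. Nodes are
#' keyed by a non-empty text identifier; edges are keyed by the triple
#' (source, target, type), so two edges between the same endpoints with
#' different types coexist. Every node and edge carries a map of typed
#' attributes (integer, real, text, boolean scalars, or homogeneous list
#' attributes represented as vectors of length > 1). Edges are directed
#' source to target; endpoints always exist (no dangling edges), and
#' removing a node removes its incident edges.
#'
#' Identifiers and edge types must not contain tab or newline characters
#' (they would be unrepresentable in the SIF and attribute-table formats).
#'
#' @slot nodes named list: id -> attribute map.
#' @slot edges named list: composite key "source (type) target" ->
#'   list(source, target, type, attrs).
#' @slot metadata free-form list (e.g. import bookkeeping).
#' @seealso [emptyNetwork()], [addNode()], [addEdge()], [createNetwork()]
#' @exportClass Network
setClass("Network", representation(
  nodes = "list", edges = "list", metadata = "list"
))

badIdChars <- function(x) grepl("[\t\n\r]", x)

setValidity("Network", function(object) {
  ids <- names(object@nodes)
  if (length(object@nodes)) {
    if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
      return("node ids must be unique non-empty strings")
    if (any(badIdChars(ids))) return("node ids must not contain tab/newline")
  }
  for (key in names(object@edges)) {
    e <- object@edges[[key]]
    if (!all(c("source", "target", "type") %in% names(e)))
      return("edge records need source, target and type")
    if (!e$source %in% ids || !e$target %in% ids)
      return(sprintf("dangling edge: %s", key))
    if (!identical(key, edgeKey(e$source, e$target, e$type)))
      return(sprintf("edge key mismatch for %s", key))
  }
  TRUE
})
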