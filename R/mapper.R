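# The four modes of operation: map query result tables onto the network,
# driving parameterized queries with per-element bind values.

#' Build a column role map
#'
#' Assigns one role per result column. Accepted role spellings (case
#' insensitive): \code{source}/\code{source_id}, \code{target}/
#' \code{target_id}, \code{sourceattr}/\code{source_attr},
#' \code{targetattr}/\code{target_attr}, \code{edgeattr}/\code{edge_attr},
#' \code{edgetype}/\code{edge_type}, \code{ignore}.
#'
#' @param roles character vector, one role per column.
#' @param attrNames optional attribute name per column; defaults to the
#'   result column name for attribute roles.
#' @return a [ColumnRoleMap-class].
#' @examples
#' columnRoleMap(c("source", "target", "edgetype", "edgeattr"))
#' @export
columnRoleMap <- function(roles, attrNames = NULL) {
  canon <- c(source = "source_id", source_id = "source_id",
             target = "target_id", target_id = "target_id",
             sourceattr = "source_attr", source_attr = "source_attr",
             targetattr = "target_attr", target_attr = "target_attr",
             edgeattr = "edge_attr", edge_attr = "edge_attr",
             edgetype = "edge_type", edge_type = "edge_type",
             ignore = "ignore")
  key <- gsub("[-. ]", "_", tolower(trimws(roles)))
  bad <- setdiff(key, names(canon))
  if (length(bad))
    mappingError(sprintf("unknown column role(s): %s", paste(bad, collapse = ", ")))
  roles <- unname(canon[key])
  if (is.null(attrNames)) attrNames <- rep("", length(roles))
  if (length(attrNames) != length(roles))
    mappingError("attrNames must have one entry per role")
  new("ColumnRoleMap", roles = roles, attrNames = attrNames)
}

setMethod("show", "ColumnRoleMap", function(object) {
  lab <- ifelse(nzchar(object@attrNames),
                paste0(object@roles, "(", object@attrNames, ")"), object@roles)
  cat("ColumnRoleMap:", paste(lab, collapse = ", "), "\n")
})

# Resolve the attribute name a column maps to.
roleAttrName <- function(roles, i, columnName) {
  if (nzchar(roles@attrNames[i])) roles@attrNames[i] else columnName
}

checkRolesAgainstResult <- function(roles, result, mode) {
  if (length(roles@roles) != length(result@columnNames))
    mappingError(sprintf("role map has %d entries but the result has %d columns",
                         length(roles@roles), ncol(result@rows)))
  if (sum(roles@roles == "source_id") != 1L)
    mappingError("exactly one source_id column is required")
  if (mode == "expand" && any(roles@roles %in% c("target_id", "target_attr")))
    mappingError("expand mode takes no target columns: the seed node is the implicit other endpoint")
  if (mode == "create" && !any(roles@roles == "target_id") &&
      any(roles@roles %in% c("target_attr", "edge_attr", "edge_type")))
    mappingError("target/edge roles require a target_id column in create mode")
  invisible(TRUE)
}

#' Mode 1: create a network from one result table
#'
#' Each row contributes network elements according to the role map: the
#' \code{source_id} value becomes (or updates) a node; if a \code{target_id}
#' column is present and non-NULL, a target node and a directed edge
#' (source, target, type) are created, the type taken from the
#' \code{edge_type} column value, else the constant \code{"interaction"}.
#' Attribute columns are converted via [convertDbValue()] and attached to
#' their element; NULL attribute values set nothing; rows with a NULL id
#' are skipped with a warning.
#'
#' @param result a [ResultTable-class].
#' @param roles a [ColumnRoleMap-class] with exactly one \code{source_id}.
#' @param net network to extend; defaults to an empty one.
#' @return a [Network-class].
#' @export
createNetwork <- function(result, roles, net = emptyNetwork()) {
  checkRolesAgainstResult(roles, result, "create")
  mapRows(result, roles, net, seed = NULL, seedAsSource = TRUE)
}

# Shared row walker for create (seed = NULL) and expand (seed = node id).
mapRows <- function(result, roles, net, seed, seedAsSource) {
  r <- roles@roles
  iSrc <- which(r == "source_id")
  iTgt <- which(r == "target_id")
  iTyp <- which(r == "edge_type")
  df <- result@rows
  types <- result@columnTypes
  for (row in seq_len(nrow(df))) {
    srcRaw <- df[[iSrc]][row]
    if (is.na(srcRaw)) {
      warning(sprintf("row %d skipped: NULL id", row), call. = FALSE)
      next
    }
    src <- as.character(srcRaw)
    tgt <- NULL
    if (length(iTgt)) {
      tgtRaw <- df[[iTgt]][row]
      if (!is.na(tgtRaw)) tgt <- as.character(tgtRaw)
    } else if (!is.null(seed)) {
      # expand mode: the seed is the implicit other endpoint
      tgt <- src
      src <- seed
      if (!seedAsSource) { tmp <- src; src <- tgt; tgt <- tmp }
    }
    sAttrs <- list(); tAttrs <- list(); eAttrs <- list()
    for (i in seq_along(r)) {
      if (!r[i] %in% c("source_attr", "target_attr", "edge_attr")) next
      val <- convertDbValue(df[[i]][row], types[i])
      if (is.null(val)) next
      nm <- roleAttrName(roles, i, result@columnNames[i])
      if (r[i] == "source_attr") sAttrs[[nm]] <- val
      else if (r[i] == "target_attr") tAttrs[[nm]] <- val
      else eAttrs[[nm]] <- val
    }
    # In expand mode attribute roles follow the NEW neighbor (the row's
    # source_id column), wherever the seed ended up.
    if (!is.null(seed)) {
      neighborIsSource <- !seedAsSource
      if (neighborIsSource) { } else { tAttrs <- sAttrs; sAttrs <- list() }
    }
    net <- addNode(net, src, sAttrs)
    if (!is.null(tgt)) {
      type <- "interaction"
      if (length(iTyp) && !is.na(df[[iTyp]][row]))
        type <- as.character(df[[iTyp]][row])
      net <- addNode(net, tgt, tAttrs)
      net <- suppressWarnings(addEdge(net, src, tgt, type, eAttrs))
    }
  }
  net
}

# ---- bind resolution ------------------------------------------------------

#' Resolve a bind specification for one node
#'
#' Each entry of \code{binds} is \code{"ID"} or a node attribute name.
#' Returns NULL if a referenced attribute is missing (caller skips the
#' element with a warning).
#' @keywords internal
resolveNodeBinds <- function(net, id, binds) {
  vals <- vector("list", length(binds))
  for (i in seq_along(binds)) {
    if (grepl("^(SOURCE|TARGET)(\\.|$)", binds[[i]]))
      mappingError("node enrichment binds may reference node fields only")
    v <- nodeField(net, id, binds[[i]])
    if (is.null(v)) return(NULL)
    vals[[i]] <- bindScalar(v)
  }
  vals
}

resolveEdgeBinds <- function(net, key, binds) {
  vals <- vector("list", length(binds))
  for (i in seq_along(binds)) {
    v <- edgeField(net, key, binds[[i]])
    if (is.null(v)) return(NULL)
    vals[[i]] <- bindScalar(v)
  }
  vals
}

# List attributes cannot instantiate a single '?': use their first value.
bindScalar <- function(v) if (length(v) > 1L) v[[1]] else v

# Columns whose every returned value equals one of the bind values that
# instantiated the query are join echoes (e.g. the id column selected back);
# they are not stored as attributes unless keepEcho = TRUE.
isEchoColumn <- function(column, bindVals) {
  if (length(bindVals) == 0L) return(FALSE)
  any(vapply(bindVals, function(b) {
    all(!is.na(column)) && all(as.character(column) == as.character(b))
  }, logical(1)))
}

# Convert the columns of a per-element result into an attribute map:
# one row -> scalars; several rows -> list attributes in row order.
resultToAttrs <- function(result, bindVals, keepEcho) {
  attrs <- list()
  df <- result@rows
  if (nrow(df) == 0L) return(attrs)
  for (i in seq_along(result@columnNames)) {
    col <- df[[i]]
    if (!keepEcho && isEchoColumn(col, bindVals)) next
    if (nrow(df) == 1L) {
      val <- convertDbValue(col[1], result@columnTypes[i])
      if (!is.null(val)) attrs[[result@columnNames[i]]] <- val
    } else {
      vals <- unlist(lapply(seq_len(nrow(df)), function(r) {
        v <- convertDbValue(col[r], result@columnTypes[i])
        if (is.null(v)) switch(result@columnTypes[i],
                               integer = NA_integer_, real = NA_real_,
                               boolean = NA, NA_character_) else v
      }))
      attrs[[result@columnNames[i]]] <- vals
    }
  }
  attrs
}

#' Mode 2: load node attributes from a parameterized query
#'
#' Launches the query once per node — for the selected nodes, or for all
#' nodes when the selection is empty — with the \code{?} placeholders
#' instantiated from that node's fields as named by \code{binds} (\code{"ID"}
#' or an attribute name). Every returned column becomes a node attribute: a
#' single-row result yields scalar attributes, a multi-row result yields
#' list attributes in row order, and a zero-row result leaves the node
#' unchanged. Columns that merely echo a bind value back are dropped unless
#' \code{keepEcho = TRUE}. Nodes missing a referenced bind attribute are
#' skipped with a warning.
#'
#' @param conn a [ConnectionHandle-class].
#' @param query a [ValidatedQuery-class] with at least one placeholder.
#' @param binds character vector of node field references, one per
#'   placeholder.
#' @param net a [Network-class].
#' @param selection node ids to process; empty means all nodes.
#' @param keepEcho keep echoed join columns as attributes.
#' @return the enriched network.
#' @export
loadNodeAttributes <- function(conn, query, binds, net,
                               selection = character(), keepEcho = FALSE) {
  binds <- as.character(binds)
  checkEnrichArgs(query, binds)
  ids <- if (length(selection)) selection else nodeIds(net)
  missing <- setdiff(ids, nodeIds(net))
  if (length(missing))
    mappingError(sprintf("selection references unknown node(s): %s",
                         paste(missing, collapse = ", ")))
  for (id in ids) {
    vals <- resolveNodeBinds(net, id, binds)
    if (is.null(vals)) {
      warning(sprintf("node '%s' skipped: missing bind attribute", id),
              call. = FALSE)
      next
    }
    res <- executeQuery(conn, query, vals)
    attrs <- resultToAttrs(res, vals, keepEcho)
    if (length(attrs)) net <- addNode(net, id, attrs)
  }
  net
}

#' Mode 3: load edge attributes from a parameterized query
#'
#' Mirrors [loadNodeAttributes()] with one execution per edge. Bind
#' references may name edge fields (\code{"SOURCE"}, \code{"TARGET"},
#' \code{"TYPE"}, or an edge attribute) and endpoint node fields: a bare
#' attribute name resolves to the edge attribute if present, else to the
#' source node's attribute; \code{"SOURCE.x"} / \code{"TARGET.x"} address an
#' endpoint explicitly.
#'
#' @inheritParams loadNodeAttributes
#' @param selection composite edge keys to process; empty means all edges.
#' @return the enriched network.
#' @export
loadEdgeAttributes <- function(conn, query, binds, net,
                               selection = character(), keepEcho = FALSE) {
  binds <- as.character(binds)
  checkEnrichArgs(query, binds)
  keys <- if (length(selection)) selection else edgeKeys(net)
  missing <- setdiff(keys, edgeKeys(net))
  if (length(missing))
    mappingError(sprintf("selection references unknown edge(s): %s",
                         paste(missing, collapse = ", ")))
  for (key in keys) {
    vals <- resolveEdgeBinds(net, key, binds)
    if (is.null(vals)) {
      warning(sprintf("edge '%s' skipped: missing bind attribute", key),
              call. = FALSE)
      next
    }
    res <- executeQuery(conn, query, vals)
    attrs <- resultToAttrs(res, vals, keepEcho)
    if (length(attrs)) {
      e <- net@edges[[key]]
      net <- suppressWarnings(addEdge(net, e$source, e$target, e$type, attrs))
    }
  }
  net
}

#' Mode 4: expand a network around seed nodes
#'
#' For each seed node (the selection, or all nodes when empty) the query is
#' launched once with the seed's fields bound; each returned row
#' creates/merges a new neighbor node — the row's \code{source_id} column
#' value — and an edge between seed and neighbor, typed by the
#' \code{edge_type} column value or \code{"interaction"}. \code{edge_attr}
#' columns land on that edge and \code{source_attr} columns on the neighbor.
#' By default the seed is the edge source (\code{seedAsSource = FALSE}
#' flips the direction), so every new edge is incident to a seed node.
#'
#' @inheritParams loadNodeAttributes
#' @param roles a [ColumnRoleMap-class]; exactly one \code{source_id}
#'   (the neighbor), no \code{target_id}.
#' @param selection seed node ids; empty means all current nodes.
#' @param seedAsSource direction of new edges (default seed -> neighbor).
#' @return the expanded network.
#' @export
expandNetwork <- function(conn, query, binds, roles, net,
                          selection = character(), seedAsSource = TRUE) {
  binds <- as.character(binds)
  checkEnrichArgs(query, binds)
  seeds <- if (length(selection)) selection else nodeIds(net)
  missing <- setdiff(seeds, nodeIds(net))
  if (length(missing))
    mappingError(sprintf("selection references unknown node(s): %s",
                         paste(missing, collapse = ", ")))
  for (seed in seeds) {
    vals <- resolveNodeBinds(net, seed, binds)
    if (is.null(vals)) {
      warning(sprintf("seed '%s' skipped: missing bind attribute", seed),
              call. = FALSE)
      next
    }
    res <- executeQuery(conn, query, vals)
    checkRolesAgainstResult(roles, res, "expand")
    net <- mapRows(res, roles, net, seed = seed, seedAsSource = seedAsSource)
  }
  net
}

checkEnrichArgs <- function(query, binds) {
  if (!is(query, "ValidatedQuery"))
    usageError("query must be a ValidatedQuery (see validateSelect)")
  if (query@placeholderCount < 1L)
    mappingError("this mode requires at least one bind variable")
  if (length(binds) != query@placeholderCount)
    usageError(sprintf("query has %d placeholder(s) but %d bind reference(s) supplied",
                       query@placeholderCount, length(binds)))
  invisible(TRUE)
}
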