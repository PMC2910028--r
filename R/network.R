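# The attributed directed multigraph and database-value conversion.

#' Compose the canonical edge key
#'
#' Edge identity is the triple (source, target, type), rendered in the
#' conventional \code{"source (type) target"} form. This is the key used in
#' edge selections and accepted in edge attribute tables.
#'
#' @param source,target node identifiers.
#' @param type edge type label.
#' @return character vector of composite keys.
#' @export
edgeKey <- function(source, target, type) {
  paste0(source, " (", type, ") ", target)
}

#' Parse a composite edge key
#'
#' Inverse of [edgeKey()]. The type is taken as the content of the first
#' parenthesised group, so identifiers containing \code{" ("} are not
#' representable in composite form (use separate columns instead).
#'
#' @param key composite key string.
#' @return list with \code{source}, \code{target}, \code{type}.
#' @export
parseEdgeKey <- function(key) {
  m <- regmatches(key, regexec("^(.*?) \\((.*?)\\) (.*)$", key))[[1]]
  if (length(m) != 4L)
    ioError(sprintf("cannot parse edge key '%s' (expected \"source (type) target\")", key))
  list(source = m[2], type = m[3], target = m[4])
}

#' Create an empty network
#'
#' @return a [Network-class] with no nodes and no edges.
#' @examples
#' net <- emptyNetwork()
#' nodeCount(net)
#' @export
emptyNetwork <- function() {
  new("Network", nodes = structure(list(), names = character()),
      edges = structure(list(), names = character()), metadata = list())
}

#' @describeIn emptyNetwork number of nodes.
#' @param net a [Network-class].
#' @export
nodeCount <- function(net) length(net@nodes)

#' @describeIn emptyNetwork number of edges.
#' @export
edgeCount <- function(net) length(net@edges)

#' Node identifiers of a network
#' @param net a [Network-class].
#' @return character vector of ids, in insertion order.
#' @export
nodeIds <- function(net) names(net@nodes)

#' Edge keys of a network
#' @param net a [Network-class].
#' @return character vector of composite keys, in insertion order.
#' @export
edgeKeys <- function(net) names(net@edges)

#' Attribute map of one node
#' @param net a [Network-class].
#' @param id node identifier.
#' @return named list of attribute values.
#' @export
nodeAttrs <- function(net, id) {
  if (!id %in% names(net@nodes)) mappingError(sprintf("no node '%s'", id))
  net@nodes[[id]]
}

#' Attribute map of one edge
#' @param net a [Network-class].
#' @param key composite edge key (see [edgeKey()]).
#' @return named list of attribute values.
#' @export
edgeAttrs <- function(net, key) {
  if (!key %in% names(net@edges)) mappingError(sprintf("no edge '%s'", key))
  net@edges[[key]]$attrs
}

#' Add or update a node
#'
#' If the node already exists, the supplied attributes are merged into it:
#' new values overwrite old ones, other attributes are preserved.
#'
#' @param net a [Network-class].
#' @param id non-empty node identifier.
#' @param attrs named list of attribute values (scalars or homogeneous
#'   vectors); \code{NULL}/\code{NA} scalar entries are dropped (a database
#'   NULL sets nothing and never clears an existing attribute).
#' @return the updated network.
#' @examples
#' net <- addNode(emptyNetwork(), "P1", list(mass = 10.2))
#' nodeAttrs(net, "P1")
#' @export
addNode <- function(net, id, attrs = list()) {
  mustBeString(id, "node id")
  if (!nzchar(id)) usageError("node id must be non-empty")
  if (badIdChars(id)) usageError("node id must not contain tab/newline")
  attrs <- cleanAttrs(attrs)
  old <- net@nodes[[id]]
  net@nodes[[id]] <- if (is.null(old)) attrs else mergeAttrs(old, attrs)
  net
}

#' Add or update an edge
#'
#' The edge key is (source, target, type); adding the same key again merges
#' attributes (overwrite, with a warning) rather than duplicating the edge.
#' Absent endpoints are auto-created with empty attributes.
#'
#' @param net a [Network-class].
#' @param source,target node identifiers (created if absent).
#' @param type edge type label; defaults to \code{"interaction"}.
#' @param attrs named list of attribute values, as in [addNode()].
#' @return the updated network.
#' @examples
#' net <- addEdge(emptyNetwork(), "A", "B", "pp", list(score = 0.9))
#' edgeKeys(net)
#' @export
addEdge <- function(net, source, target, type = "interaction", attrs = list()) {
  mustBeString(source, "edge source"); mustBeString(target, "edge target")
  mustBeString(type, "edge type")
  if (badIdChars(type)) usageError("edge type must not contain tab/newline")
  if (!source %in% names(net@nodes)) net <- addNode(net, source)
  if (!target %in% names(net@nodes)) net <- addNode(net, target)
  attrs <- cleanAttrs(attrs)
  key <- edgeKey(source, target, type)
  old <- net@edges[[key]]
  if (is.null(old)) {
    net@edges[[key]] <- list(source = source, target = target, type = type,
                             attrs = attrs)
  } else {
    if (length(attrs))
      warning(sprintf("edge '%s' already present; merging attributes", key),
              call. = FALSE)
    old$attrs <- mergeAttrs(old$attrs, attrs)
    net@edges[[key]] <- old
  }
  net
}

#' Remove a node and its incident edges
#'
#' @param net a [Network-class].
#' @param id node identifier; unknown ids are ignored.
#' @return the updated network, with no dangling edges.
#' @export
removeNode <- function(net, id) {
  if (!id %in% names(net@nodes)) return(net)
  keep <- vapply(net@edges, function(e) e$source != id && e$target != id,
                 logical(1))
  net@edges <- net@edges[keep]
  net@nodes[[id]] <- NULL
  net
}

# Drop NULL and scalar-NA entries, validate the rest.
cleanAttrs <- function(attrs) {
  if (length(attrs) == 0L) return(structure(list(), names = character()))
  if (is.null(names(attrs)) || any(!nzchar(names(attrs))))
    usageError("attributes must be named")
  keep <- !vapply(attrs, function(v) is.null(v) || (isScalar(v) && is.na(v)),
                  logical(1))
  attrs <- attrs[keep]
  for (nm in names(attrs)) checkAttrValue(attrs[[nm]], nm)
  attrs
}

#' Read a node field
#'
#' The reserved field \code{"ID"} returns the node identifier; any other
#' name returns the attribute of that name. A missing attribute returns
#' \code{NULL} (an absent marker, distinct from a stored text value).
#'
#' @param net a [Network-class].
#' @param id node identifier (must exist).
#' @param field \code{"ID"} or an attribute name.
#' @return the field value, or \code{NULL} if the attribute is absent.
#' @export
nodeField <- function(net, id, field) {
  if (!id %in% names(net@nodes)) mappingError(sprintf("no node '%s'", id))
  if (identical(field, "ID")) return(id)
  net@nodes[[id]][[field]]
}

#' Read an edge field
#'
#' Reserved fields: \code{"SOURCE"} and \code{"TARGET"} return the endpoint
#' ids, \code{"TYPE"} the edge type. \code{"SOURCE.x"} / \code{"TARGET.x"}
#' read attribute \code{x} of the corresponding endpoint node. A bare
#' attribute name reads the edge attribute if present, otherwise the source
#' node's attribute of that name (documented tie-break).
#'
#' @param net a [Network-class].
#' @param key composite edge key (must exist).
#' @param field field reference as above.
#' @return the field value, or \code{NULL} if absent.
#' @export
edgeField <- function(net, key, field) {
  if (!key %in% names(net@edges)) mappingError(sprintf("no edge '%s'", key))
  e <- net@edges[[key]]
  if (identical(field, "SOURCE")) return(e$source)
  if (identical(field, "TARGET")) return(e$target)
  if (identical(field, "TYPE"))   return(e$type)
  if (startsWith(field, "SOURCE."))
    return(nodeField(net, e$source, sub("^SOURCE\\.", "", field)))
  if (startsWith(field, "TARGET."))
    return(nodeField(net, e$target, sub("^TARGET\\.", "", field)))
  v <- e$attrs[[field]]
  if (!is.null(v)) return(v)
  nodeField(net, e$source, field)
}

#' Convert a database value to an attribute value
#'
#' Applies the automatic field-type conversion: integer-like columns become
#' integer attributes, real-like become double, text-like become character,
#' boolean-like become logical (accepting 0/1 and common textual spellings),
#' and unknown types degrade to their text rendering. Database NULL
#' (\code{NA}) converts to \code{NULL}: the caller sets no attribute.
#'
#' @param raw a scalar database value or \code{NA}.
#' @param declaredType one of \code{"integer"}, \code{"real"}, \code{"text"},
#'   \code{"boolean"}, \code{"unknown"}.
#' @return a scalar attribute value, or \code{NULL} for NULL input.
#' @examples
#' convertDbValue(42L, "integer")
#' convertDbValue("Y", "text")
#' @export
convertDbValue <- function(raw, declaredType) {
  if (is.null(raw) || (isScalar(raw) && is.na(raw))) return(NULL)
  switch(declaredType,
    integer = as.integer(raw),
    real    = as.double(raw),
    text    = as.character(raw),
    boolean = asBooleanValue(raw),
    as.character(raw)  # unknown: degrade to text rendering
  )
}

asBooleanValue <- function(raw) {
  if (is.logical(raw)) return(raw)
  if (is.numeric(raw)) return(raw != 0)
  v <- toupper(as.character(raw))
  if (v %in% c("TRUE", "T", "Y", "YES", "1")) return(TRUE)
  if (v %in% c("FALSE", "F", "N", "NO", "0")) return(FALSE)
  NA
}

# Map a database-declared type name onto the five type buckets.
normalizeDbType <- function(decl) {
  d <- tolower(decl)
  if (grepl("int", d)) return("integer")
  if (grepl("real|doub|floa|num|dec", d)) return("real")
  if (grepl("char|text|clob|date|time", d)) return("text")
  if (grepl("bool|logic", d)) return("boolean")
  "unknown"
}

# R storage type -> declared type bucket (used when fetching results).
rTypeToDbType <- function(x) {
  if (is.integer(x)) "integer"
  else if (is.double(x)) "real"
  else if (is.character(x)) "text"
  else if (is.logical(x)) "boolean"
  else "unknown"
}

#' Structural and attribute equality of two networks
#'
#' Compares node sets, edge sets and (optionally) all attribute maps,
#' ignoring insertion order. Used by the idempotence and round-trip checks.
#'
#' @param a,b [Network-class] objects.
#' @param attributes compare attributes too (default) or structure only.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
sameNetwork <- function(a, b, attributes = TRUE) {
  if (!setequal(nodeIds(a), nodeIds(b))) return(FALSE)
  if (!setequal(edgeKeys(a), edgeKeys(b))) return(FALSE)
  if (!attributes) return(TRUE)
  sameMap <- function(x, y) {
    if (!setequal(names(x), names(y))) return(FALSE)
    all(vapply(names(x), function(nm) identical(x[[nm]], y[[nm]]), logical(1)))
  }
  for (id in nodeIds(a))
    if (!sameMap(a@nodes[[id]], b@nodes[[id]])) return(FALSE)
  for (key in edgeKeys(a))
    if (!sameMap(a@edges[[key]]$attrs, b@edges[[key]]$attrs)) return(FALSE)
  TRUE
}

setMethod("show", "Network", function(object) {
  cat(sprintf("Network: %d nodes, %d edges\n",
              nodeCount(object), edgeCount(object)))
  nAttr <- sum(lengths(object@nodes)) +
    sum(vapply(object@edges, function(e) length(e$attrs), integer(1)))
  cat(sprintf("  attribute values: %d\n", nAttr))
  types <- unique(vapply(object@edges, `[[`, character(1), "type"))
  if (length(types))
    cat("  edge types:", paste(bsort(types), collapse = ", "), "\n")
})
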