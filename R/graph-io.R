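# Network serialization: SIF (structure), GraphML (structure + typed
# attributes) and tab-separated attribute tables. All writers emit elements
# in a stable byte order (nodes lexicographic by id, edges by composite
# key), so two writes of the same network are byte-identical.

# ---- value rendering ------------------------------------------------------

attrTypeLabel <- function(v) {
  base <- if (is.integer(v)) "integer" else if (is.double(v)) "real"
          else if (is.logical(v)) "boolean" else "text"
  if (length(v) > 1L) paste0("list_", base) else base
}

renderScalar <- function(v) {
  if (is.na(v)) return("\\N")
  if (is.double(v)) sprintf("%.17g", v)
  else if (is.logical(v)) if (v) "true" else "false"
  else as.character(v)
}

parseScalar <- function(s, type) {
  if (identical(s, "\\N")) {
    return(switch(type, integer = NA_integer_, real = NA_real_,
                  boolean = NA, NA_character_))
  }
  switch(type,
    integer = as.integer(s),
    real    = as.double(s),
    boolean = identical(tolower(s), "true"),
    s)
}

# List attributes serialize as "|"-delimited text; literal "\" and "|"
# inside tokens are escaped, and NA is the reserved token "\N".
escapeToken <- function(s) gsub("|", "\\|", gsub("\\", "\\\\", s, fixed = TRUE), fixed = TRUE)
unescapeToken <- function(s) gsub("\\\\", "\\", gsub("\\|", "|", s, fixed = TRUE), fixed = TRUE)

renderValue <- function(v) {
  if (length(v) == 1L) return(renderScalar(v))
  paste(vapply(seq_along(v), function(i) {
    s <- renderScalar(v[i])
    if (identical(s, "\\N")) s else escapeToken(s)
  }, character(1)), collapse = "|")
}

parseValue <- function(s, typeLabel) {
  if (startsWith(typeLabel, "list_")) {
    base <- sub("^list_", "", typeLabel)
    tokens <- strsplit(s, "(?<!\\\\)\\|", perl = TRUE)[[1]]
    if (length(tokens) == 0L) tokens <- ""
    vapply(tokens, function(t) {
      if (identical(t, "\\N")) parseScalar(t, base)
      else parseScalar(unescapeToken(t), base)
    }, vector(switch(base, integer = "integer", real = "double",
                     boolean = "logical", "character"), 1),
    USE.NAMES = FALSE)
  } else {
    parseScalar(s, typeLabel)
  }
}

# ---- SIF ------------------------------------------------------------------

#' Write a network as SIF
#'
#' One tab-delimited line \code{source<TAB>type<TAB>target} per edge, plus
#' one bare-id line per isolated node. SIF carries structure only;
#' attributes go through [writeGraphML()] or [writeAttributeTables()].
#'
#' @param net a [Network-class].
#' @param path output file.
#' @return invisibly the path.
#' @export
writeSIF <- function(net, path) {
  lines <- character()
  for (key in bsort(edgeKeys(net))) {
    e <- net@edges[[key]]
    lines <- c(lines, paste(e$source, e$type, e$target, sep = "\t"))
  }
  touched <- unique(unlist(lapply(net@edges, function(e) c(e$source, e$target))))
  isolated <- bsort(setdiff(nodeIds(net), touched))
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' Read a SIF file
#'
#' Accepts the tab-delimited dialect written by [writeSIF()] and, for files
#' containing no tab at all, the classic whitespace-delimited dialect.
#' Multi-target lines (\code{source type t1 t2 ...}) are accepted on read.
#' A two-field line is malformed and raises a parse error with its line
#' number.
#'
#' @param path SIF file.
#' @return a [Network-class] (structure only, no attributes).
#' @export
readSIF <- function(path) {
  if (!file.exists(path)) ioError(sprintf("no such file: %s", path))
  lines <- readLines(path)
  tabbed <- any(grepl("\t", lines, fixed = TRUE))
  net <- emptyNetwork()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    fields <- if (tabbed) strsplit(line, "\t", fixed = TRUE)[[1]]
              else strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (length(fields) == 1L) net <- addNode(net, fields[1])
    else if (length(fields) == 2L)
      ioError(sprintf("malformed SIF line %d: two fields", i))
    else for (t in fields[3:length(fields)])
      net <- suppressWarnings(addEdge(net, fields[1], t, fields[2]))
  }
  net
}

# ---- GraphML --------------------------------------------------------------

GRAPHML_NS <- "http://graphml.graphdrawing.org/xmlns"

graphmlType <- c(integer = "int", real = "double", text = "string",
                 boolean = "boolean")

#' Write a network as GraphML
#'
#' Full round-trip format: every node and edge attribute is emitted with a
#' typed \code{<key>} declaration. List attributes are serialized as
#' "|"-delimited strings, with the element type and delimiter declared in
#' the key's \code{<desc>}. The structural edge type is stored under the
#' reserved key \code{interaction}.
#'
#' @param net a [Network-class].
#' @param path output file.
#' @return invisibly the path.
#' @export
writeGraphML <- function(net, path) {
  # collect (domain, name, typeLabel) key descriptors
  descr <- list()
  collect <- function(domain, attrs) {
    for (nm in names(attrs)) {
      tl <- attrTypeLabel(attrs[[nm]])
      id <- paste0(domain, "\r", nm, "\r", tl)
      descr[[id]] <<- list(domain = domain, name = nm, type = tl)
    }
  }
  for (id in nodeIds(net)) collect("node", net@nodes[[id]])
  for (key in edgeKeys(net)) collect("edge", net@edges[[key]]$attrs)
  descr <- descr[bsort(names(descr))]
  keyId <- stats::setNames(paste0("k", seq_along(descr) - 1L), names(descr))

  doc <- xml2::xml_new_root("graphml", xmlns = GRAPHML_NS)
  for (i in seq_along(descr)) {
    d <- descr[[i]]
    listType <- startsWith(d$type, "list_")
    base <- sub("^list_", "", d$type)
    k <- xml2::xml_add_child(doc, "key", id = unname(keyId[i]),
                             "for" = d$domain, attr.name = d$name,
                             attr.type = if (listType) "string"
                                         else graphmlType[[base]])
    if (listType)
      xml2::xml_add_child(k, "desc", paste0("list:", base, ":|"))
  }
  xml2::xml_add_child(doc, "key", id = "etype", "for" = "edge",
                      attr.name = "interaction", attr.type = "string")
  g <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "directed")
  addData <- function(parent, domain, attrs) {
    for (nm in bsort(names(attrs))) {
      v <- attrs[[nm]]
      id <- keyId[[paste0(domain, "\r", nm, "\r", attrTypeLabel(v))]]
      xml2::xml_add_child(parent, "data", renderValue(v), key = id)
    }
  }
  for (id in bsort(nodeIds(net))) {
    n <- xml2::xml_add_child(g, "node", id = id)
    addData(n, "node", net@nodes[[id]])
  }
  for (key in bsort(edgeKeys(net))) {
    e <- net@edges[[key]]
    el <- xml2::xml_add_child(g, "edge", source = e$source, target = e$target)
    xml2::xml_add_child(el, "data", e$type, key = "etype")
    addData(el, "edge", e$attrs)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a GraphML file written by [writeGraphML()]
#'
#' Restores structure and typed attributes, including list attributes.
#' Attributes declared with an unknown type degrade to text with a warning.
#'
#' @param path GraphML file.
#' @return a [Network-class].
#' @export
readGraphML <- function(path) {
  if (!file.exists(path)) ioError(sprintf("no such file: %s", path))
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    ioError(sprintf("cannot parse GraphML: %s", conditionMessage(e))))
  xml2::xml_ns_strip(doc)
  revType <- stats::setNames(names(graphmlType), unname(graphmlType))
  keys <- list()
  for (k in xml2::xml_find_all(doc, "./key")) {
    id <- xml2::xml_attr(k, "id")
    atype <- xml2::xml_attr(k, "attr.type")
    desc <- xml2::xml_text(xml2::xml_find_first(k, "./desc"))
    tl <- if (!is.na(desc) && startsWith(desc, "list:")) {
      paste0("list_", strsplit(desc, ":", fixed = TRUE)[[1]][2])
    } else if (!is.na(atype) && atype %in% names(revType)) {
      revType[[atype]]
    } else {
      warning(sprintf("unknown attribute type '%s'; reading as text", atype),
              call. = FALSE)
      "text"
    }
    keys[[id]] <- list(name = xml2::xml_attr(k, "attr.name"), type = tl)
  }
  readData <- function(el) {
    attrs <- list()
    for (d in xml2::xml_find_all(el, "./data")) {
      kid <- xml2::xml_attr(d, "key")
      if (identical(kid, "etype")) next
      spec <- keys[[kid]]
      if (is.null(spec)) next
      attrs[[spec$name]] <- parseValue(xml2::xml_text(d), spec$type)
    }
    attrs
  }
  net <- emptyNetwork()
  g <- xml2::xml_find_first(doc, "./graph")
  for (n in xml2::xml_find_all(g, "./node"))
    net <- addNode(net, xml2::xml_attr(n, "id"), readData(n))
  for (el in xml2::xml_find_all(g, "./edge")) {
    tnode <- xml2::xml_find_first(el, "./data[@key='etype']")
    type <- if (inherits(tnode, "xml_missing")) "interaction"
            else xml2::xml_text(tnode)
    net <- suppressWarnings(addEdge(net, xml2::xml_attr(el, "source"),
                                    xml2::xml_attr(el, "target"), type,
                                    readData(el)))
  }
  net
}

# ---- attribute tables -----------------------------------------------------

tableHeaderToken <- function(name, type) paste0(name, ":", type)

splitHeaderToken <- function(token) {
  known <- c("integer", "real", "text", "boolean",
             paste0("list_", c("integer", "real", "text", "boolean")))
  pos <- regexpr(":[a-z_]+$", token)
  if (pos > 0L) {
    type <- substring(token, pos + 1L)
    if (type %in% known)
      return(list(name = substring(token, 1L, pos - 1L), type = type))
  }
  list(name = token, type = "text")
}

collectAttrColumns <- function(maps) {
  cols <- list()
  for (attrs in maps) for (nm in names(attrs)) {
    if (is.null(cols[[nm]])) cols[[nm]] <- attrTypeLabel(attrs[[nm]])
  }
  cols[bsort(names(cols))]
}

#' Write node and edge attribute tables
#'
#' Tab-separated tables: the node table is keyed by an \code{ID} column, the
#' edge table by \code{SOURCE}, \code{TYPE}, \code{TARGET} columns. Every
#' attribute becomes one column whose header declares its type as
#' \code{name:type}; empty cells mean "attribute absent on this element".
#'
#' @param net a [Network-class].
#' @param nodePath,edgePath output files; either may be \code{NULL} to skip.
#' @return invisibly \code{c(nodePath, edgePath)}.
#' @export
writeAttributeTables <- function(net, nodePath = NULL, edgePath = NULL) {
  renderCell <- function(attrs, nm) {
    v <- attrs[[nm]]
    if (is.null(v)) "" else renderValue(v)
  }
  if (!is.null(nodePath)) {
    cols <- collectAttrColumns(net@nodes)
    hdr <- c("ID", mapply(tableHeaderToken, names(cols), unlist(cols),
                          USE.NAMES = FALSE))
    lines <- vapply(bsort(nodeIds(net)), function(id) {
      paste(c(id, vapply(names(cols), renderCell, character(1),
                         attrs = net@nodes[[id]])), collapse = "\t")
    }, character(1))
    writeLines(c(paste(hdr, collapse = "\t"), lines), nodePath)
  }
  if (!is.null(edgePath)) {
    cols <- collectAttrColumns(lapply(net@edges, `[[`, "attrs"))
    hdr <- c("SOURCE", "TYPE", "TARGET",
             mapply(tableHeaderToken, names(cols), unlist(cols),
                    USE.NAMES = FALSE))
    lines <- vapply(bsort(edgeKeys(net)), function(key) {
      e <- net@edges[[key]]
      paste(c(e$source, e$type, e$target,
              vapply(names(cols), renderCell, character(1), attrs = e$attrs)),
            collapse = "\t")
    }, character(1))
    writeLines(c(paste(hdr, collapse = "\t"), lines), edgePath)
  }
  invisible(c(nodePath, edgePath))
}

#' Read an attribute table onto an existing network
#'
#' Detects the element kind from the key columns (\code{ID} for nodes;
#' \code{SOURCE}/\code{TYPE}/\code{TARGET}, or a single composite
#' \code{KEY} column \code{"source (type) target"}, for edges). Attributes
#' attach to matching existing elements only; rows whose key matches
#' nothing are skipped, and the skip count is reported via a message and in
#' \code{metadata(net)$skippedKeys}.
#'
#' @param path tab-separated table written by [writeAttributeTables()].
#' @param net a [Network-class] to annotate.
#' @return the annotated network.
#' @export
readAttributeTable <- function(path, net) {
  if (!file.exists(path)) ioError(sprintf("no such file: %s", path))
  lines <- readLines(path)
  if (length(lines) == 0L) ioError("attribute table has no header row")
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  kind <- if (identical(hdr[1], "ID")) "node"
          else if (length(hdr) >= 3L &&
                   identical(hdr[1:3], c("SOURCE", "TYPE", "TARGET"))) "edge"
          else if (identical(hdr[1], "KEY")) "edgekey"
          else ioError("missing key column: expected ID, SOURCE/TYPE/TARGET or KEY")
  nKey <- if (kind == "edge") 3L else 1L
  attrHdr <- lapply(hdr[-seq_len(nKey)], splitHeaderToken)
  skipped <- 0L
  for (i in seq_along(lines)[-1]) {
    if (!nzchar(lines[i])) next
    cells <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    length(cells) <- length(hdr)  # pad trailing empties
    cells[is.na(cells)] <- ""
    attrs <- list()
    for (j in seq_along(attrHdr)) {
      cell <- cells[nKey + j]
      if (!nzchar(cell)) next
      attrs[[attrHdr[[j]]$name]] <- parseValue(cell, attrHdr[[j]]$type)
    }
    if (kind == "node") {
      if (!cells[1] %in% nodeIds(net)) { skipped <- skipped + 1L; next }
      net <- addNode(net, cells[1], attrs)
    } else {
      key <- if (kind == "edge") edgeKey(cells[1], cells[3], cells[2])
             else cells[1]
      if (!key %in% edgeKeys(net)) { skipped <- skipped + 1L; next }
      e <- net@edges[[key]]
      net <- suppressWarnings(addEdge(net, e$source, e$target, e$type, attrs))
    }
  }
  if (skipped > 0L)
    message(sprintf("readAttributeTable: skipped %d row(s) with unmatched keys",
                    skipped))
  net@metadata$skippedKeys <- skipped
  net
}
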