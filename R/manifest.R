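# Query manifests: a versionable YAML document binding a profile, a query,
# a mode of operation, roles/binds, an optional selection and the output
# artifacts — the headless counterpart of an interactive query session.

MANIFEST_MODES <- c("create", "node-attrs", "edge-attrs", "expand")

#' Validate a query manifest
#'
#' Checks all mode-specific requirements before any database contact:
#' every manifest needs a profile (or a direct sqlite \code{database} path)
#' and a query; \code{create} and \code{expand} need column roles;
#' \code{node-attrs}, \code{edge-attrs} and \code{expand} need bind
#' references and an input network.
#'
#' @param manifest named list, or the path of a YAML manifest file.
#' @return the normalized manifest list.
#' @export
readManifest <- function(manifest) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) usageError(sprintf("no manifest at %s", manifest))
    manifest <- yaml::read_yaml(manifest)
  }
  if (!is.list(manifest)) usageError("manifest must be a list or a YAML file path")
  m <- manifest
  if (is.null(m$mode) || !m$mode %in% MANIFEST_MODES)
    usageError(sprintf("manifest mode must be one of: %s",
                       paste(MANIFEST_MODES, collapse = ", ")))
  if (is.null(m$database) && (is.null(m$profile) || is.null(m$store)))
    usageError("manifest needs either 'database' (sqlite path) or 'profile' + 'store'")
  if (is.null(m$query) && is.null(m$query_file))
    usageError("manifest needs 'query' text or a 'query_file'")
  if (!is.null(m$query_file)) {
    if (!file.exists(m$query_file))
      usageError(sprintf("query_file does not exist: %s", m$query_file))
    m$query <- paste(readLines(m$query_file), collapse = "\n")
  }
  if (m$mode %in% c("create", "expand") && is.null(m$roles))
    usageError(sprintf("mode '%s' requires column roles", m$mode))
  if (m$mode != "create") {
    if (is.null(m$binds) || length(m$binds) == 0L)
      usageError(sprintf("mode '%s' requires bind references", m$mode))
    if (is.null(m$input))
      usageError(sprintf("mode '%s' requires an input network", m$mode))
  }
  if (is.null(m$output) || length(m$output) == 0L)
    usageError("manifest needs at least one output path")
  m
}

manifestProfile <- function(m) {
  if (!is.null(m$database))
    connectionProfile("manifest", "sqlite", m$database)
  else getProfile(loadProfileStore(m$store), m$profile)
}

loadInputNetwork <- function(input) {
  net <- if (!is.null(input$graphml)) readGraphML(input$graphml)
         else if (!is.null(input$sif)) readSIF(input$sif)
         else usageError("input network needs 'sif' or 'graphml'")
  if (!is.null(input$node_attributes))
    net <- readAttributeTable(input$node_attributes, net)
  if (!is.null(input$edge_attributes))
    net <- readAttributeTable(input$edge_attributes, net)
  net
}

readSelection <- function(path) {
  if (is.null(path)) return(character())
  if (!file.exists(path)) usageError(sprintf("no selection file at %s", path))
  sel <- readLines(path)
  sel[nzchar(trimws(sel))]
}

#' Run a query manifest end to end
#'
#' Validates the manifest, opens the connection, executes the named mode,
#' writes every requested output artifact and logs element counts (nodes,
#' edges, queries issued) to standard error. Outputs are deterministic:
#' running the same manifest twice over the same database yields
#' byte-identical files.
#'
#' @param manifest named list or YAML manifest path (see [readManifest()]).
#' @param quiet suppress the log.
#' @return invisibly a list: \code{network}, \code{nodes}, \code{edges},
#'   \code{queriesIssued}, \code{outputs}.
#' @export
runManifest <- function(manifest, quiet = FALSE) {
  m <- readManifest(manifest)
  query <- validateSelect(m$query)
  net <- if (m$mode == "create") emptyNetwork() else loadInputNetwork(m$input)
  sel <- readSelection(m$selection_file)
  roles <- if (!is.null(m$roles))
    columnRoleMap(unlist(m$roles), if (!is.null(m$attr_names)) unlist(m$attr_names))
  conn <- openConnection(manifestProfile(m))
  on.exit(closeConnection(conn))
  binds <- as.character(unlist(m$binds))
  net <- switch(m$mode,
    "create" = {
      res <- executeQuery(conn, query,
                          binds = if (length(binds)) binds else list())
      createNetwork(res, roles)
    },
    "node-attrs" = loadNodeAttributes(conn, query, binds, net, sel),
    "edge-attrs" = loadEdgeAttributes(conn, query, binds, net, sel),
    "expand" = expandNetwork(conn, query, binds, roles, net, sel,
                             seedAsSource = !isTRUE(m$seed_as_target)))
  outputs <- character()
  out <- m$output
  if (!is.null(out$sif)) { writeSIF(net, out$sif); outputs <- c(outputs, out$sif) }
  if (!is.null(out$graphml)) { writeGraphML(net, out$graphml); outputs <- c(outputs, out$graphml) }
  if (!is.null(out$node_attributes) || !is.null(out$edge_attributes)) {
    writeAttributeTables(net, out$node_attributes, out$edge_attributes)
    outputs <- c(outputs, out$node_attributes, out$edge_attributes)
  }
  summary <- list(mode = m$mode, nodes = nodeCount(net), edges = edgeCount(net),
                  queriesIssued = queryCount(conn), outputs = outputs)
  if (!is.null(out$summary)) {
    jsonlite::write_json(summary, out$summary, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, out$summary)
  }
  if (!quiet)
    message(sprintf("[%s] nodes: %d, edges: %d, queries issued: %d -> %s",
                    m$mode, summary$nodes, summary$edges, summary$queriesIssued,
                    paste(outputs, collapse = ", ")))
  invisible(c(list(network = net), summary))
}

#' Preview a query on the console
#'
#' Opens the profile, fetches at most \code{limit} rows and prints the
#' result with its declared column types.
#'
#' @param profile a [ConnectionProfile-class].
#' @param sql SELECT text.
#' @param limit positive row cap (default 10).
#' @param binds optional bind values.
#' @return invisibly the [ResultTable-class].
#' @export
runPreview <- function(profile, sql, limit = 10L, binds = list()) {
  conn <- openConnection(profile)
  on.exit(closeConnection(conn))
  res <- previewQuery(conn, validateSelect(sql), binds, limit)
  show(res)
  invisible(res)
}
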