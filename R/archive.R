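# Query history and favorites: a bounded most-recent-first history plus a
# named, editable set of favorite queries, persisted as YAML alongside the
# connection profiles.

#' Create or load a query archive
#'
#' @param path persistence location; loaded if the file exists. Use
#'   \code{""} for an in-memory archive.
#' @param bound maximum history length (default 50).
#' @return a [QueryArchive-class].
#' @export
queryArchive <- function(path = "", bound = 50L) {
  if (nzchar(path) && file.exists(path)) return(loadArchive(path, bound))
  new("QueryArchive", history = character(),
      favorites = structure(character(), names = character()),
      bound = as.integer(bound), path = path)
}

#' Record an executed query in the history
#'
#' The history is most-recent-first and bounded: recording beyond the bound
#' evicts the oldest entry, and an immediate repeat of the newest entry is
#' not appended twice in a row.
#'
#' @param archive a [QueryArchive-class].
#' @param sql executed query text.
#' @return the updated archive (persisted if it has a path).
#' @export
recordQuery <- function(archive, sql) {
  mustBeString(sql, "sql")
  if (length(archive@history) == 0L || archive@history[1] != sql) {
    archive@history <- c(sql, archive@history)
    if (length(archive@history) > archive@bound)
      archive@history <- archive@history[seq_len(archive@bound)]
  }
  persistArchive(archive)
}

#' @describeIn recordQuery the history, newest first.
#' @export
queryHistory <- function(archive) archive@history

#' Save a named favorite query
#'
#' An existing favorite of the same name is replaced (favorites are
#' editable).
#'
#' @param archive a [QueryArchive-class].
#' @param name favorite name.
#' @param sql query text.
#' @return the updated archive.
#' @export
saveFavorite <- function(archive, name, sql) {
  mustBeString(name, "favorite name"); mustBeString(sql, "sql")
  archive@favorites[[name]] <- sql
  persistArchive(archive)
}

#' @describeIn saveFavorite named character vector of favorites.
#' @export
listFavorites <- function(archive) archive@favorites

#' @describeIn saveFavorite delete a favorite; unknown names raise a
#'   not-found error.
#' @export
deleteFavorite <- function(archive, name) {
  if (!name %in% names(archive@favorites))
    usageError(sprintf("no favorite named '%s'", name))
  archive@favorites <- archive@favorites[names(archive@favorites) != name]
  persistArchive(archive)
}

persistArchive <- function(archive) {
  if (nzchar(archive@path)) {
    doc <- list(bound = archive@bound,
                history = as.list(archive@history),
                favorites = as.list(archive@favorites))
    ok <- tryCatch({ yaml::write_yaml(doc, archive@path); TRUE },
                   error = function(e) FALSE)
    if (!ok) ioError(sprintf("cannot write query archive at %s", archive@path))
  }
  archive
}

loadArchive <- function(path, bound = 50L) {
  doc <- yaml::read_yaml(path)
  fav <- unlist(doc$favorites)
  if (is.null(fav)) fav <- structure(character(), names = character())
  new("QueryArchive",
      history = as.character(unlist(doc$history)),
      favorites = fav,
      bound = as.integer(doc$bound %||% bound), path = path)
}

#' Export favorites as a plain-text document
#'
#' One favorite per line: name, a tab, then the query text. The inverse
#' operation [importFavorites()] merges such a document into an archive.
#'
#' @param archive a [QueryArchive-class].
#' @param path output file.
#' @return invisibly the path.
#' @export
exportFavorites <- function(archive, path) {
  nms <- bsort(names(archive@favorites))
  writeLines(paste(nms, archive@favorites[nms], sep = "\t"), path)
  invisible(path)
}

#' @describeIn exportFavorites import a favorites document, replacing
#'   same-named entries.
#' @export
importFavorites <- function(archive, path) {
  for (line in readLines(path)) {
    if (!nzchar(line)) next
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L)
      ioError("favorites document lines must be 'name<TAB>query'")
    archive <- saveFavorite(archive, parts[1],
                            paste(parts[-1], collapse = "\t"))
  }
  archive
}

setMethod("show", "QueryArchive", function(object) {
  cat(sprintf("QueryArchive: %d history entr%s (bound %d), %d favorite(s)\n",
              length(object@history),
              if (length(object@history) == 1L) "y" else "ies",
              object@bound, length(object@favorites)))
})
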