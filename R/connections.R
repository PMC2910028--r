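# Connection profiles: define, persist, list and open named database
# coordinates, so one session can switch quickly between databases.

#' Create a connection profile
#'
#' @param name short unique label.
#' @param engine \code{"sqlite"} (embedded file; the reference engine),
#'   \code{"mysql"} or \code{"postgres"}.
#' @param location file path (sqlite) or host\[:port\].
#' @param database schema name; must stay empty for sqlite.
#' @param user account name.
#' @param passwordRef name of an environment variable holding the password;
#'   the secret itself is never written to the profile store.
#' @return a [ConnectionProfile-class].
#' @examples
#' connectionProfile("toy", "sqlite", "toy.db")
#' @export
connectionProfile <- function(name, engine = c("sqlite", "mysql", "postgres"),
                              location, database = "", user = "",
                              passwordRef = "") {
  engine <- match.arg(engine)
  new("ConnectionProfile", name = name, engine = engine, location = location,
      database = database, user = user, passwordRef = passwordRef)
}

setMethod("show", "ConnectionProfile", function(object) {
  cat(sprintf("ConnectionProfile '%s' (%s): %s%s%s\n", object@name,
              object@engine, object@location,
              if (nzchar(object@database)) paste0("/", object@database) else "",
              if (nzchar(object@user)) paste0(" as ", object@user) else ""))
})

#' Create or load a profile store
#'
#' @param path config file location; if the file exists it is loaded.
#' @return a [ProfileStore-class].
#' @export
profileStore <- function(path) {
  if (file.exists(path)) return(loadProfileStore(path))
  new("ProfileStore", path = path,
      profiles = structure(list(), names = character()))
}

#' Save a profile into a store
#'
#' An existing profile of the same name is replaced. The store is persisted
#' to its path immediately.
#'
#' @param store a [ProfileStore-class].
#' @param profile a valid [ConnectionProfile-class].
#' @return the updated store.
#' @export
saveProfile <- function(store, profile) {
  validObject(profile)
  store@profiles[[profile@name]] <- profile
  persistStore(store)
  store
}

#' Remove a profile from a store
#' @param store a [ProfileStore-class].
#' @param name profile name; unknown names raise a not-found error.
#' @return the updated store.
#' @export
removeProfile <- function(store, name) {
  if (!name %in% names(store@profiles))
    usageError(sprintf("no profile named '%s'", name))
  store@profiles[[name]] <- NULL
  persistStore(store)
  store
}

#' List profile names in a store
#' @param store a [ProfileStore-class].
#' @return character vector of names, sorted.
#' @export
listProfiles <- function(store) bsort(names(store@profiles))

#' Fetch one profile by name
#' @param store a [ProfileStore-class].
#' @param name profile name.
#' @return a [ConnectionProfile-class].
#' @export
getProfile <- function(store, name) {
  p <- store@profiles[[name]]
  if (is.null(p)) usageError(sprintf("no profile named '%s'", name))
  p
}

persistStore <- function(store) {
  dir <- dirname(store@path)
  if (!dir.exists(dir))
    ioError(sprintf("profile store directory does not exist: %s", dir))
  doc <- list(profiles = lapply(store@profiles, function(p) list(
    engine = p@engine, location = p@location, database = p@database,
    user = p@user, password_ref = p@passwordRef
  )))
  ok <- tryCatch({ yaml::write_yaml(doc, store@path); TRUE },
                 error = function(e) FALSE)
  if (!ok) ioError(sprintf("cannot write profile store at %s", store@path))
  invisible(store)
}

#' Load a profile store from disk
#'
#' Round-trips every field of every profile; secrets round-trip only as the
#' environment-variable reference they were stored as.
#'
#' @param path config file written by [saveProfile()].
#' @return a [ProfileStore-class].
#' @export
loadProfileStore <- function(path) {
  if (!file.exists(path)) ioError(sprintf("no profile store at %s", path))
  doc <- yaml::read_yaml(path)
  profs <- list()
  for (nm in names(doc$profiles)) {
    d <- doc$profiles[[nm]]
    profs[[nm]] <- connectionProfile(
      name = nm, engine = d$engine, location = d$location,
      database = d$database %||% "", user = d$user %||% "",
      passwordRef = d$password_ref %||% ""
    )
  }
  new("ProfileStore", path = path,
      profiles = structure(profs, names = names(profs)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Open a database connection for a profile
#'
#' Returns a [ConnectionHandle-class] able to execute read statements.
#' Handles for different profiles may coexist, enabling session-level
#' switching between databases. For the embedded sqlite engine a missing
#' database file is a connection error unless \code{create = TRUE}.
#'
#' @param profile a [ConnectionProfile-class].
#' @param create for sqlite: allow creating a new empty database file.
#' @return a [ConnectionHandle-class].
#' @export
openConnection <- function(profile, create = FALSE) {
  validObject(profile)
  if (profile@engine != "sqlite")
    connectionError(sprintf(
      "profile '%s': no driver for engine '%s' is available in this installation",
      profile@name, profile@engine))
  if (!create && !file.exists(profile@location))
    connectionError(sprintf("profile '%s': database file '%s' does not exist",
                            profile@name, profile@location))
  db <- tryCatch(DBI::dbConnect(RSQLite::SQLite(), profile@location),
                 error = function(e) connectionError(sprintf(
                   "profile '%s': %s", profile@name, conditionMessage(e))))
  stats <- new.env(parent = emptyenv())
  stats$queries <- 0L
  new("ConnectionHandle", profile = profile, db = db, stats = stats)
}

#' Close a connection handle
#' @param conn a [ConnectionHandle-class].
#' @return invisibly \code{TRUE}.
#' @export
closeConnection <- function(conn) {
  DBI::dbDisconnect(conn@db)
  invisible(TRUE)
}

#' Number of statements executed on a handle
#'
#' Every call of [executeQuery()] or [previewQuery()] increments the
#' counter; the enrichment modes issue exactly one query per processed
#' element, which this makes observable.
#'
#' @param conn a [ConnectionHandle-class].
#' @return integer count.
#' @export
queryCount <- function(conn) conn@stats$queries

#' Reset the statement counter of a handle
#' @param conn a [ConnectionHandle-class].
#' @return invisibly the previous count.
#' @export
resetQueryCount <- function(conn) {
  old <- conn@stats$queries
  conn@stats$queries <- 0L
  invisible(old)
}

setMethod("show", "ConnectionHandle", function(object) {
  cat(sprintf("ConnectionHandle on profile '%s' (%s), %d queries executed\n",
              object@profile@name, object@profile@engine,
              object@stats$queries))
})
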