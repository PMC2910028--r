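# Query engine: validate, parameterize, execute and preview SELECT
# statements; archive history and favorites.

# Quote- and comment-aware scan. Returns the SQL with every string literal,
# quoted identifier and comment masked by spaces, so that lexical checks
# (leading keyword, statement splitting, '?' counting) cannot be fooled by
# quoted content. Handles '' and "" escapes, backtick identifiers, -- line
# comments and /* */ block comments.
maskSqlLiterals <- function(sql) {
  ch <- strsplit(sql, "", fixed = TRUE)[[1]]
  n <- length(ch)
  out <- ch
  state <- "n"
  i <- 1L
  while (i <= n) {
    c0 <- ch[i]
    c1 <- if (i < n) ch[i + 1L] else ""
    if (state == "n") {
      if (c0 == "'") { state <- "sq"; out[i] <- " " }
      else if (c0 == '"') { state <- "dq"; out[i] <- " " }
      else if (c0 == "`") { state <- "bt"; out[i] <- " " }
      else if (c0 == "-" && c1 == "-") { state <- "lc"; out[i] <- " " }
      else if (c0 == "/" && c1 == "*") { state <- "bc"; out[i] <- " "; out[i + 1L] <- " "; i <- i + 1L }
    } else if (state == "sq") {
      if (c0 == "'" && c1 == "'") { out[i + 1L] <- " "; i <- i + 1L }
      else if (c0 == "'") state <- "n"
      out[i] <- " "
    } else if (state == "dq") {
      if (c0 == '"' && c1 == '"') { out[i] <- " "; out[i + 1L] <- " "; i <- i + 1L }
      else if (c0 == '"') state <- "n"
      out[i] <- " "
    } else if (state == "bt") {
      if (c0 == "`") state <- "n"
      out[i] <- " "
    } else if (state == "lc") {
      if (c0 == "\n") state <- "n" else out[i] <- " "
    } else if (state == "bc") {
      if (c0 == "*" && c1 == "/") { state <- "n"; out[i] <- " "; out[i + 1L] <- " "; i <- i + 1L }
      else out[i] <- " "
    }
    i <- i + 1L
  }
  paste(out, collapse = "")
}

#' Count bind placeholders in a SQL statement
#'
#' Counts \code{?} tokens outside string literals, quoted identifiers and
#' comments.
#'
#' @param sql SQL text.
#' @return non-negative integer.
#' @examples
#' countPlaceholders("SELECT x FROM t WHERE a = ? AND note = 'what?'")
#' @export
countPlaceholders <- function(sql) {
  masked <- maskSqlLiterals(sql)
  lengths(regmatches(masked, gregexpr("?", masked, fixed = TRUE)))
}

#' Validate a SQL statement as a single read-only SELECT
#'
#' Validation is lexical: the leading keyword (after comments) must be
#' \code{SELECT}, or \code{WITH} introducing a common-table-expression
#' query; an unquoted \code{;} followed by further content rejects the text
#' as multiple statements. Write statements (\code{INSERT}, \code{UPDATE},
#' \code{DELETE}, \code{DROP}, ...) are rejected before any database
#' contact, naming the offending keyword.
#'
#' @param sql non-empty SQL text.
#' @return a [ValidatedQuery-class] carrying the placeholder count.
#' @examples
#' q <- validateSelect(
#'   "SELECT protn1, protn2, intType, confirmed FROM interactions WHERE confirmed = 'Y'")
#' placeholderCount(q)
#' @export
validateSelect <- function(sql) {
  mustBeString(sql, "sql")
  if (!nzchar(trimws(sql))) queryError("empty SQL text")
  masked <- maskSqlLiterals(sql)
  kw <- regmatches(masked, regexpr("^\\s*([A-Za-z_]+)", masked))
  kw <- toupper(trimws(kw))
  if (length(kw) == 0L || !nzchar(kw))
    queryError("statement does not begin with a keyword")
  if (!kw %in% c("SELECT", "WITH"))
    queryError(sprintf("only SELECT statements are executed; got '%s'", kw))
  semis <- gregexpr(";", masked, fixed = TRUE)[[1]]
  if (semis[1] != -1L) {
    for (pos in semis) {
      rest <- substr(masked, pos + 1L, nchar(masked))
      if (grepl("[^[:space:];]", rest))
        queryError("multiple statements are not allowed")
    }
  }
  new("ValidatedQuery", text = sql,
      placeholderCount = countPlaceholders(sql))
}

#' @describeIn validateSelect number of '?' bind positions of a validated query.
#' @param query a [ValidatedQuery-class].
#' @export
placeholderCount <- function(query) query@placeholderCount

#' @describeIn validateSelect the SQL text of a validated query.
#' @export
queryText <- function(query) query@text

setMethod("show", "ValidatedQuery", function(object) {
  cat(sprintf("ValidatedQuery (%d bind variable%s):\n  %s\n",
              object@placeholderCount,
              if (object@placeholderCount == 1L) "" else "s", object@text))
})

#' Execute a validated query
#'
#' Runs the statement with positional bind values passed as typed database
#' parameters (never spliced into the text) and returns the full result.
#' NULLs are preserved as \code{NA}. Column types are the declared database
#' types, bucketed into integer/real/text/boolean/unknown.
#'
#' @param conn a [ConnectionHandle-class].
#' @param query a [ValidatedQuery-class].
#' @param binds ordered list (or vector) of bind values; its length must
#'   equal the query's placeholder count.
#' @param limit optional row cap (used by [previewQuery()]).
#' @return a [ResultTable-class].
#' @export
executeQuery <- function(conn, query, binds = list(), limit = Inf) {
  if (!is(query, "ValidatedQuery")) query <- validateSelect(query)
  binds <- as.list(binds)
  if (length(binds) != query@placeholderCount)
    usageError(sprintf("query has %d placeholder(s) but %d bind value(s) supplied",
                       query@placeholderCount, length(binds)))
  res <- tryCatch(DBI::dbSendQuery(conn@db, query@text),
                  error = function(e) queryError(conditionMessage(e)))
  on.exit(DBI::dbClearResult(res), add = TRUE)
  if (length(binds))
    tryCatch(DBI::dbBind(res, unname(binds)),
             error = function(e) queryError(conditionMessage(e)))
  df <- tryCatch(
    if (is.finite(limit)) DBI::dbFetch(res, n = limit) else DBI::dbFetch(res),
    error = function(e) queryError(conditionMessage(e)))
  conn@stats$queries <- conn@stats$queries + 1L
  resultTable(df)
}

#' Preview the head of a query's result
#'
#' Identical to [executeQuery()] but returns at most \code{limit} rows,
#' taken from the head of the full result order; columns are never
#' truncated.
#'
#' @inheritParams executeQuery
#' @param limit positive row cap.
#' @return a [ResultTable-class] with at most \code{limit} rows.
#' @export
previewQuery <- function(conn, query, binds = list(), limit = 10L) {
  if (!is.numeric(limit) || length(limit) != 1L || is.na(limit) || limit < 1)
    usageError("preview limit must be a positive integer")
  executeQuery(conn, query, binds, limit = as.integer(limit))
}

# Wrap a fetched data.frame as a ResultTable with bucketed column types.
resultTable <- function(df) {
  types <- vapply(df, rTypeToDbType, character(1))
  new("ResultTable", columnNames = names(df), columnTypes = unname(types),
      rows = df)
}

#' @describeIn executeQuery number of rows in a result.
#' @param result a [ResultTable-class].
#' @export
resultRowCount <- function(result) nrow(result@rows)

#' @describeIn executeQuery result rows as a data.frame.
#' @export
resultRows <- function(result) result@rows

#' @describeIn executeQuery ordered column names of a result.
#' @export
resultColumns <- function(result) result@columnNames

#' @describeIn executeQuery declared column types of a result.
#' @export
resultTypes <- function(result) result@columnTypes

setMethod("show", "ResultTable", function(object) {
  hdr <- paste(sprintf("%s <%s>", object@columnNames, object@columnTypes),
               collapse = "  ")
  cat(sprintf("ResultTable: %d row(s)\n  %s\n", nrow(object@rows), hdr))
  if (nrow(object@rows)) print(utils::head(object@rows, 10L))
})
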