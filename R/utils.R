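# Internal helpers shared across modules.

# Structured conditions: every user-facing failure carries a class that the
# command-line wrapper maps onto an exit code (usage=2, connection=3, query=4,
# mapping=5, io=6).
relnetStop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "relnet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

usageError      <- function(msg, ...) relnetStop("relnet_usage_error", msg, ...)
connectionError <- function(msg, ...) relnetStop("relnet_connection_error", msg, ...)
queryError      <- function(msg, ...) relnetStop("relnet_query_error", msg, ...)
mappingError    <- function(msg, ...) relnetStop("relnet_mapping_error", msg, ...)
ioError         <- function(msg, ...) relnetStop("relnet_io_error", msg, ...)

# Byte-wise (C locale) sort so writers are deterministic across platforms.
bsort <- function(x) {
  if (length(x) == 0L) return(character())
  sort(x, method = "radix")
}

isScalar <- function(x) is.atomic(x) && length(x) == 1L

# Attribute values are atomic vectors: length 1 is a scalar, length > 1 a
# list attribute (homogeneous by construction since R vectors are typed).
checkAttrValue <- function(value, name) {
  if (!is.atomic(value) || length(value) == 0L)
    usageError(sprintf("attribute '%s' must be a non-empty atomic vector", name))
  if (!(is.integer(value) || is.double(value) || is.character(value) || is.logical(value)))
    usageError(sprintf("attribute '%s' has unsupported type '%s'", name, typeof(value)))
  invisible(TRUE)
}

# Merge attribute maps: new values overwrite, others are preserved.
mergeAttrs <- function(old, new) {
  for (nm in names(new)) old[[nm]] <- new[[nm]]
  old
}

mustBeString <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    usageError(sprintf("%s must be a single character string", what))
  invisible(x)
}
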