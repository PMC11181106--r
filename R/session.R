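# Capture session lifecycle. One session may be active at a time; it owns
# the execution counter, the history of execution records, and the parsed
# source of the activated script.

#' Activate provenance capture
#'
#' Starts a capture session for the script whose statements are to be
#' tracked. The script source is hashed (SHA-256 over the file bytes) and
#' parsed with source references kept, so that individual statements can be
#' located by line when tracked calls are analyzed later. A fresh session
#' UUID identifies this execution.
#'
#' When `script_path` is `NULL` the path is detected from
#' `commandArgs()` (a script run through `Rscript`); interactive
#' sessions and tests should pass the path explicitly.
#'
#' @param script_path path to the script file being executed, or `NULL`
#'   to auto-detect.
#' @return the session state, invisibly.
#' @seealso [deactivate()], [save_provenance()]
#' @export
activate <- function(script_path = NULL) {
  if (session_active()) {
    stop("a capture session is already active; call deactivate() first",
         call. = FALSE)
  }
  if (is.null(script_path)) script_path <- detect_script_path()
  if (is.null(script_path) || !file.exists(script_path)) {
    stop("cannot activate: script source file not found (",
         if (is.null(script_path)) "undetectable" else script_path, ")",
         call. = FALSE)
  }
  settings <- settings_env()
  parsed <- tryCatch(parse(script_path, keep.source = TRUE),
                     error = function(e) NULL)
  session <- new.env(parent = emptyenv())
  session$session_id <- settings$id_source()
  session$script_path <- normalizePath(script_path, winslash = "/")
  session$script_file_hash <- digest::digest(file = script_path,
                                             algo = "sha256")
  session$authority <- settings$authority
  session$counter <- 0L
  session$history <- list()
  session$active <- TRUE
  session$parsed <- parsed
  session$functions <- list()   # dedup cache for FunctionInfo
  # the null singleton is shared per session: reset its cached UUID
  .provtrace$null_uuid <- NULL
  .provtrace$session <- session
  invisible(session)
}

detect_script_path <- function() {
  args <- commandArgs(trailingOnly = FALSE)
  file_arg <- grep("^--file=", args, value = TRUE)
  if (length(file_arg) > 0L) {
    return(sub("^--file=", "", file_arg[[1L]]))
  }
  NULL
}

#' Deactivate the current capture session
#'
#' Stops tracking. The session (with its history) is returned so it can
#' still be serialized with [provenance_document()] or
#' [write_provenance()].
#'
#' @return the finished session, invisibly; `NULL` if none was active.
#' @export
deactivate <- function() {
  session <- .provtrace$session
  if (!is.null(session)) session$active <- FALSE
  .provtrace$session <- NULL
  .provtrace$last_session <- session
  invisible(session)
}

#' @rdname deactivate
#' @export
session_active <- function() {
  !is.null(.provtrace$session) && isTRUE(.provtrace$session$active)
}

#' Current (or most recently finished) capture session
#'
#' @param finished if `TRUE`, fall back to the last deactivated session
#'   when none is active.
#' @return session state or `NULL`.
#' @export
current_session <- function(finished = TRUE) {
  s <- .provtrace$session
  if (is.null(s) && finished) s <- .provtrace$last_session
  s
}

#' Serialize the captured history to an RDF file
#'
#' Convenience wrapper building the provenance document for the current
#' session (everything recorded so far) and writing it to `path`.
#' Typically called once at the end of the script, producing the sidecar
#' file next to the script's result file.
#'
#' @param path destination file.
#' @param format RDF syntax, `"turtle"` (default) or `"ntriples"`.
#' @param session session state; defaults to the current one.
#' @return `path`, invisibly.
#' @export
save_provenance <- function(path, format = "turtle",
                            session = current_session()) {
  if (is.null(session)) {
    stop("no capture session: call activate() first", call. = FALSE)
  }
  doc <- provenance_document(session)
  write_provenance(doc, path, format = format)
  invisible(path)
}

# Locate the full source statement containing a tracked call, using the
# source reference attached to the call expression and the parsed script.
# Falls back to deparsing the call itself (multi-line statements collapse
# to one unit either way).
resolve_statement <- function(call_expr, session) {
  stmt <- NULL
  ref <- attr(call_expr, "srcref")
  if (!is.null(ref) && !is.null(session$parsed)) {
    line <- ref[[1L]]
    refs <- attr(session$parsed, "srcref")
    srcfile_call <- attr(ref, "srcfile")
    same_file <- !is.null(srcfile_call) &&
      identical(normalizePath(srcfile_call$filename, winslash = "/",
                              mustWork = FALSE),
                session$script_path)
    if (same_file && !is.null(refs)) {
      for (i in seq_along(refs)) {
        r <- refs[[i]]
        if (line >= r[[1L]] && line <= r[[3L]]) {
          stmt <- paste(as.character(r), collapse = "\n")
          break
        }
      }
    }
  }
  if (is.null(stmt)) {
    stmt <- paste(deparse(call_expr), collapse = " ")
  }
  stmt
}
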