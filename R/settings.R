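#' @keywords internal
default_settings <- function() {
  list(
    # Organizational identifier used as the authority component of all URNs.
    authority = "my-authority",
    # Packages whose objects are hashed with the fast identity-based method
    # instead of the content hash (see hash_object()).
    builtin_hash_packages = character(),
    # Registry: package name -> function(object) returning
    # list(annotations = <named list>, array_annotations = <named list>).
    metadata_plugins = list(),
    # Fallback registry mapping S3 class name -> package, for classes whose
    # defining package cannot be discovered from the object itself.
    # Pre-populated with the demo container model shipped in this package.
    class_packages = c(AnalogSignal = "provtrace", EventSeries = "provtrace",
                       Segment = "provtrace", Block = "provtrace",
                       Epoch = "provtrace", PSDFigure = "provtrace",
                       ResultBundle = "provtrace"),
    # Attribute / parameter snapshots are capped at this many characters.
    attribute_max_chars = 256L,
    # Injectable identifier and clock sources, so tests can produce
    # deterministic records. Defaults: random version-4 UUIDs and UTC now.
    id_source = function() uuid::UUIDgenerate(),
    clock = function() Sys.time()
  )
}

settings_env <- function() {
  if (is.null(.provtrace$settings)) .provtrace$settings <- default_settings()
  .provtrace$settings
}

#' Get or set global capture settings
#'
#' Settings operate globally and control how provenance is captured and
#' described. They may be changed before activating a capture session; the
#' `authority` is used in every URN generated afterwards.
#'
#' Recognized settings:
#' \describe{
#'   \item{authority}{non-empty string identifying the organization
#'     responsible for the records; first component of all URNs.}
#'   \item{builtin_hash_packages}{character vector of package names whose
#'     objects are hashed by the identity-based fallback rather than by
#'     content (useful for objects whose content hash is expensive or too
#'     sensitive to irrelevant state).}
#'   \item{metadata_plugins}{named list mapping a package name to a function
#'     that extracts annotation dictionaries from that package's objects.}
#'   \item{class_packages}{named character vector mapping S3 class names to
#'     the package implementing them (identity fallback for module paths).}
#'   \item{attribute_max_chars}{integer cap on stringified metadata values.}
#'   \item{id_source, clock}{zero-argument functions returning a fresh UUID
#'     string / a POSIXct timestamp; injectable for reproducible records.}
#' }
#'
#' @param ... named settings to update. With no arguments the current
#'   settings list is returned.
#' @return the full settings list, invisibly when updating.
#' @examples
#' provtrace_settings(authority = "my-lab")
#' provtrace_settings()$authority
#' @export
provtrace_settings <- function(...) {
  current <- settings_env()
  changes <- list(...)
  if (length(changes) == 0L) return(current)
  nm <- names(changes)
  if (is.null(nm) || any(nm == "")) {
    stop("all settings must be named", call. = FALSE)
  }
  unknown <- setdiff(nm, names(current))
  if (length(unknown) > 0L) {
    stop("unknown setting(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if ("authority" %in% nm) {
    auth <- changes$authority
    if (!is.character(auth) || length(auth) != 1L || !nzchar(auth)) {
      stop("'authority' must be a non-empty string", call. = FALSE)
    }
  }
  .provtrace$settings <- modifyList(current, changes)
  invisible(.provtrace$settings)
}

#' Register a metadata-extraction plugin
#'
#' Plugins extract annotation dictionaries from the data objects of a given
#' package. When [describe_object()] encounters an object whose class is
#' implemented in `package`, the plugin is called and its
#' `annotations` / `array_annotations` results are recorded on the
#' descriptor.
#'
#' @param package package name owning the object classes.
#' @param fun function of one argument returning
#'   `list(annotations = <named list>, array_annotations = <named list>)`
#'   (either element may be `NULL`).
#' @export
register_metadata_plugin <- function(package, fun) {
  stopifnot(is.character(package), length(package) == 1L, is.function(fun))
  plugins <- settings_env()$metadata_plugins
  plugins[[package]] <- fun
  provtrace_settings(metadata_plugins = plugins)
}
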