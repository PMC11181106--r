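# Object identity: content hashing and metadata snapshots.

# Runtime address of an object, used only as a session-local disambiguator
# (identity in the serialized records relies on the content hash alone).
obj_address <- function(x) {
  if (is.environment(x)) {
    txt <- format(x)
    m <- regmatches(txt, regexpr("0x[0-9a-f]+", txt))
    return(if (length(m) == 1L) m else "0x0")
  }
  out <- tryCatch({
    a <- tracemem(x)
    untracemem(x)
    gsub("[<>]", "", a)
  }, error = function(e) NA_character_)
  if (is.na(out)) "0x0" else out
}

# Package ("module") implementing an object's class. S4 classes carry their
# package; base types map to "base"; S3 classes are looked up in the
# class_packages registry, falling back to "R".
class_module_path <- function(obj, settings = settings_env()) {
  cls <- class(obj)[1L]
  pkg <- attr(class(obj), "package")
  if (!is.null(pkg) && !identical(pkg, ".GlobalEnv")) return(pkg)
  reg <- settings$class_packages
  if (cls %in% names(reg)) return(unname(reg[[cls]]))
  base_classes <- c("numeric", "integer", "double", "character", "logical",
                    "complex", "raw", "list", "matrix", "array", "factor",
                    "data.frame", "function", "NULL", "environment", "name",
                    "call", "Date", "POSIXct", "POSIXlt", "table")
  if (cls %in% base_classes) return("base")
  "R"
}

strip_capture_attrs <- function(obj) {
  # State used for content hashing: the object minus the annotation
  # dictionaries (metadata is recorded separately and must not perturb the
  # data identity when e.g. a label annotation is added downstream is NOT
  # desired -- annotations are part of the object state, so keep them).
  obj
}

#' Hash an object for identity
#'
#' Returns the digest and the hash method used, applying the dispatch rule:
#' `NULL` maps to a session-shared UUID (the null object is a shared
#' singleton, so one identifier avoids duplication); objects whose class is
#' implemented in one of `builtin_hash_packages` use the identity-based
#' builtin hash; everything else gets a deterministic SHA-1 content digest
#' over the class name and the serialized object state. A failing content
#' hash degrades to the builtin method with a warning, never an error.
#'
#' @param obj any R value.
#' @param settings capture settings (defaults to the global settings).
#' @return list with elements `digest` (hex string or UUID) and
#'   `method` (one of `"content_sha1"`, `"builtin_hash"`, `"uuid"`).
#' @export
hash_object <- function(obj, settings = settings_env()) {
  if (is.null(obj)) {
    if (is.null(.provtrace$null_uuid)) {
      .provtrace$null_uuid <- settings$id_source()
    }
    return(list(digest = .provtrace$null_uuid, method = "uuid"))
  }
  type_name <- class(obj)[1L]
  pkg <- class_module_path(obj, settings)
  # reference objects (environments and classes built on them) are hashed
  # by identity: their content is mutable, so a content hash would give
  # every state a different identity while the script sees one object
  if (is.environment(obj) || pkg %in% settings$builtin_hash_packages) {
    return(list(digest = builtin_hash(obj, type_name),
                method = "builtin_hash"))
  }
  dg <- tryCatch(
    digest::digest(list(type_name, strip_capture_attrs(obj)), algo = "sha1"),
    error = function(e) NULL)
  if (is.null(dg)) {
    warning("content hashing failed for <", type_name,
            ">; falling back to builtin hash", call. = FALSE)
    return(list(digest = builtin_hash(obj, type_name),
                method = "builtin_hash"))
  }
  list(digest = dg, method = "content_sha1")
}

builtin_hash <- function(obj, type_name) {
  digest::digest(list(type_name, obj_address(obj)), algo = "sha1")
}

# Attributes that electrophysiology-style data models expose and that are
# recorded whenever present, mirroring the metadata users need to interpret
# a recorded array (shape, physical units, timing).
SPECIAL_ATTRIBUTES <- c("units", "t_start", "t_stop", "sampling_rate",
                        "nix_name", "dimensionality", "id", "pid",
                        "create_time")

format_shape <- function(obj) {
  d <- dim(obj)
  if (is.null(d)) {
    if (is.atomic(obj)) d <- length(obj) else return(NULL)
  }
  if (length(d) == 1L) sprintf("(%d,)", d)
  else paste0("(", paste(d, collapse = ", "), ")")
}

#' Stringify a value for a metadata or parameter snapshot
#'
#' Scalars become their natural printed form; short vectors a
#' tuple-style listing; anything else a bounded deparse. The cap keeps bulk
#' data out of the provenance records.
#'
#' @param x value to format.
#' @param max_chars character cap for the snapshot.
#' @return length-1 character string.
#' @keywords internal
format_value <- function(x, max_chars = settings_env()$attribute_max_chars) {
  out <- tryCatch({
    if (is.null(x)) {
      "NULL"
    } else if (is.atomic(x) && length(x) == 1L && is.null(dim(x))) {
      if (is.character(x)) x else format(x, digits = 15L, trim = TRUE)
    } else if (is.atomic(x) && is.null(dim(x)) && length(x) <= 16L) {
      paste0("(", paste(format(x, digits = 15L, trim = TRUE),
                        collapse = ", "), ")")
    } else {
      paste(deparse(x, control = "niceNames"), collapse = " ")
    }
  }, error = function(e) paste0("<unrepresentable ", class(x)[1L], ">"))
  if (nchar(out) > max_chars) out <- substr(out, 1L, max_chars)
  out
}

# Literal snapshot keeping scalar types (for typed RDF literals); anything
# non-scalar falls back to the bounded string form.
snapshot_value <- function(x, settings = settings_env()) {
  if (is.atomic(x) && length(x) == 1L && is.null(dim(x)) &&
      (is.numeric(x) || is.logical(x) || is.character(x))) {
    if (is.character(x) && nchar(x) > settings$attribute_max_chars) {
      return(substr(x, 1L, settings$attribute_max_chars))
    }
    return(x)
  }
  format_value(x, settings$attribute_max_chars)
}

#' Describe an in-memory data object
#'
#' Builds the identity-plus-metadata snapshot of one object: class name,
#' implementing package, content hash (via [hash_object()]), runtime memory
#' address, a snapshot of the object's attributes (including the special
#' attributes `shape`, `dtype`, `units`, `t_start`, `t_stop`,
#' `sampling_rate`, `nix_name`, `dimensionality`, `id`, `pid`,
#' `create_time` when present) and its annotation dictionaries.
#' Annotations are taken from `annotations` / `array_annotations`
#' attributes, or from a registered metadata plugin for the implementing
#' package. Values that cannot be represented are stored as bounded string
#' placeholders; description never fails.
#'
#' @param obj any R value.
#' @param settings capture settings.
#' @return object of class `provtrace_object`.
#' @export
describe_object <- function(obj, settings = settings_env()) {
  h <- hash_object(obj, settings)
  type_name <- class(obj)[1L]
  module <- class_module_path(obj, settings)

  attrs <- list()
  shp <- format_shape(obj)
  if (!is.null(shp)) attrs$shape <- shp
  if (is.atomic(obj) && !is.null(obj)) attrs$dtype <- typeof(obj)

  raw_attrs <- attributes(obj)
  raw_attrs <- raw_attrs[setdiff(names(raw_attrs),
                                 c("class", "names", "dim", "dimnames",
                                   "annotations", "array_annotations"))]
  for (nm in names(raw_attrs)) {
    attrs[[nm]] <- snapshot_value(raw_attrs[[nm]], settings)
  }
  # ensure the enumerated special attributes appear under their own names
  for (nm in intersect(SPECIAL_ATTRIBUTES, names(raw_attrs))) {
    attrs[[nm]] <- snapshot_value(raw_attrs[[nm]], settings)
  }

  ann <- list()
  plugin <- settings$metadata_plugins[[module]]
  meta <- NULL
  if (!is.null(plugin)) {
    meta <- tryCatch(plugin(obj), error = function(e) NULL)
  }
  if (is.null(meta)) {
    meta <- list(annotations = attr(obj, "annotations"),
                 array_annotations = attr(obj, "array_annotations"))
  }
  for (dict in meta[c("annotations", "array_annotations")]) {
    if (is.list(dict) && !is.null(names(dict))) {
      for (nm in names(dict)) ann[[nm]] <- snapshot_value(dict[[nm]], settings)
    }
  }

  structure(
    list(type_name = type_name,
         module_path = module,
         content_hash = h$digest,
         hash_method = h$method,
         memory_address = obj_address(obj),
         attributes = attrs,
         annotations = ann),
    class = "provtrace_object")
}

#' Describe a file by content
#'
#' @param path path to an existing file; the SHA-256 digest of its bytes is
#'   computed at description time, so equal content yields an equal hash
#'   regardless of path.
#' @return object of class `provtrace_file` with fields `hash_type`
#'   (always `"sha256"`), `file_hash`, and the absolute `path`.
#' @export
describe_file <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("file not found: ", paste(format(path), collapse = " "),
         call. = FALSE)
  }
  structure(
    list(hash_type = "sha256",
         file_hash = digest::digest(file = path, algo = "sha256"),
         path = normalizePath(path, winslash = "/")),
    class = "provtrace_file")
}

#' @export
print.provtrace_object <- function(x, ...) {
  cat("<data object> ", x$module_path, ".", x$type_name,
      "  [", x$hash_method, ":", substr(x$content_hash, 1L, 10L), "...]\n",
      sep = "")
  if (length(x$attributes)) {
    cat("  attributes:", paste(names(x$attributes), collapse = ", "), "\n")
  }
  if (length(x$annotations)) {
    cat("  annotations:", paste(names(x$annotations), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.provtrace_file <- function(x, ...) {
  cat("<file> ", x$path, "\n  sha256:", x$file_hash, "\n", sep = "")
  invisible(x)
}
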