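# Mapping of the capture history onto the PROV-O extension ontology, and
# the RDF file interface (write / read / merge).
#
# Five node classes are produced: DataObjectEntity and FileEntity
# (prov:Entity subclasses), FunctionExecution (prov:Activity),
# ScriptAgent (prov:SoftwareAgent), Function, plus NameValuePair blank
# nodes carrying parameters, attributes, and annotations.

a_iri <- function(local) rdf_iri(paste0(ALPACA_NS, local))
p_iri <- function(local) paste0(ALPACA_NS, local)
prov_p <- function(local) paste0(PROV_NS, local)
rdf_type <- function() paste0(RDF_NS, "type")

# URN grammar. The language token and authority layout reproduce the
# published identifier scheme byte-for-byte so that records interoperate
# with tooling that consumes it; equal descriptor identity yields an equal
# URN across records, sessions, and processes.
urn_object <- function(authority, class_dotted, hash) {
  sprintf("urn:%s:alpaca:object:Python:%s:%s", authority, class_dotted, hash)
}
urn_file <- function(authority, hash_type, hash) {
  sprintf("urn:%s:alpaca:file:%s:%s", authority, hash_type, hash)
}
urn_execution <- function(authority, script_hash, session_id, fn_dotted,
                          execution_id) {
  sprintf("urn:%s:alpaca:function_execution:Python:%s:%s:%s#%s",
          authority, script_hash, session_id, fn_dotted, execution_id)
}
urn_function <- function(authority, fn_dotted) {
  sprintf("urn:%s:alpaca:function:Python:%s", authority, fn_dotted)
}
urn_script <- function(authority, script_name, script_hash, session_id) {
  sprintf("urn:%s:alpaca:script:Python:%s:%s#%s",
          authority, script_name, script_hash, session_id)
}

descriptor_urn <- function(d, authority) {
  if (inherits(d, "provtrace_file")) {
    urn_file(authority, d$hash_type, d$file_hash)
  } else {
    urn_object(authority, paste(d$module_path, d$type_name, sep = "."),
               d$content_hash)
  }
}

hash_source_literal <- function(method) {
  # fixed vocabulary of the published ontology, independent of the internal
  # hash implementation
  switch(method,
         content_sha1 = "joblib_SHA1",
         builtin_hash = "Python_hash",
         uuid = "UUID",
         "joblib_SHA1")
}

typed_literal <- function(value) {
  if (is.logical(value) && length(value) == 1L && !is.na(value)) {
    rdf_literal(tolower(as.character(value)), paste0(XSD, "boolean"))
  } else if (is.integer(value) && length(value) == 1L && !is.na(value)) {
    rdf_literal(as.character(value), paste0(XSD, "integer"))
  } else if (is.double(value) && length(value) == 1L && !is.na(value)) {
    rdf_literal(format(value, digits = 15L, trim = TRUE, scientific = FALSE),
                paste0(XSD, "double"))
  } else if (is.character(value) && length(value) == 1L) {
    rdf_literal(value)
  } else {
    rdf_literal(format_value(value))
  }
}

#' Build the RDF provenance document for a session
#'
#' Each execution record contributes one FunctionExecution activity node,
#' a deduplicated Function node, `prov:used` edges to the input
#' entities, `prov:wasGeneratedBy` edges from the output entities,
#' association/attribution to the session's ScriptAgent, NameValuePair
#' blank nodes for parameters and object metadata, and
#' `prov:hasMember` triples for container accesses (each element
#' carrying exactly one of `fromAttribute` / `containerIndex` /
#' `containerSlice`). An empty session yields a document with only the
#' namespace declarations.
#'
#' @param session a capture session (see [activate()], [deactivate()]).
#' @return a `provenance_document` (an RDF graph).
#' @export
provenance_document <- function(session = current_session()) {
  if (is.null(session)) stop("no capture session", call. = FALSE)
  authority <- session$authority
  g <- rdf_graph(c(alpaca = ALPACA_NS, prov = PROV_NS, rdf = RDF_NS,
                   rdfs = RDFS_NS, xsd = XSD))
  class(g) <- c("provenance_document", class(g))
  history <- session$history
  if (length(history) == 0L) return(g)

  agent <- rdf_iri(urn_script(authority, basename(session$script_path),
                              session$script_file_hash, session$session_id))
  rdf_add(g, agent, rdf_type(), a_iri("ScriptAgent"))
  rdf_add(g, agent, p_iri("scriptPath"), rdf_literal(session$script_path))

  emitted <- new.env(parent = emptyenv())
  nvp_count <- 0L
  nvp <- function(owner, property, name, value) {
    nvp_count <<- nvp_count + 1L
    b <- rdf_bnode(sprintf("nvp%05d", nvp_count))
    rdf_add(g, owner, property, b)
    rdf_add(g, b, rdf_type(), a_iri("NameValuePair"))
    rdf_add(g, b, p_iri("pairName"), rdf_literal(name))
    rdf_add(g, b, p_iri("pairValue"), typed_literal(value))
  }

  emit_entity <- function(d) {
    urn <- descriptor_urn(d, authority)
    node <- rdf_iri(urn)
    if (!is.null(emitted[[urn]])) return(node)
    emitted[[urn]] <- TRUE
    if (inherits(d, "provtrace_file")) {
      rdf_add(g, node, rdf_type(), a_iri("FileEntity"))
      rdf_add(g, node, p_iri("filePath"), rdf_literal(d$path))
    } else {
      rdf_add(g, node, rdf_type(), a_iri("DataObjectEntity"))
      rdf_add(g, node, p_iri("hashSource"),
              rdf_literal(hash_source_literal(d$hash_method)))
      for (nm in names(d$attributes)) {
        nvp(node, p_iri("hasAttribute"), nm, d$attributes[[nm]])
      }
      for (nm in names(d$annotations)) {
        nvp(node, p_iri("hasAnnotation"), nm, d$annotations[[nm]])
      }
    }
    node
  }

  for (record in history) {
    fn_dotted <- dotted_name(record$fun)
    fn_urn <- urn_function(authority, fn_dotted)
    fn_node <- rdf_iri(fn_urn)
    if (is.null(emitted[[fn_urn]])) {
      emitted[[fn_urn]] <- TRUE
      rdf_add(g, fn_node, rdf_type(), a_iri("Function"))
      rdf_add(g, fn_node, p_iri("functionName"),
              rdf_literal(record$fun$name))
      rdf_add(g, fn_node, p_iri("implementedIn"),
              rdf_literal(record$fun$module_path))
      rdf_add(g, fn_node, p_iri("functionVersion"),
              rdf_literal(record$fun$version))
    }

    exec <- rdf_iri(urn_execution(authority, session$script_file_hash,
                                  session$session_id, fn_dotted,
                                  record$execution_id))
    rdf_add(g, exec, rdf_type(), a_iri("FunctionExecution"))
    rdf_add(g, exec, prov_p("startedAtTime"),
            rdf_literal(record$time_start, paste0(XSD, "dateTime")))
    rdf_add(g, exec, prov_p("endedAtTime"),
            rdf_literal(record$time_end, paste0(XSD, "dateTime")))
    rdf_add(g, exec, p_iri("executionOrder"),
            rdf_literal(as.character(record$order), paste0(XSD, "int")))
    rdf_add(g, exec, p_iri("codeStatement"),
            rdf_literal(record$code_statement))
    rdf_add(g, exec, p_iri("usedFunction"), fn_node)
    rdf_add(g, exec, prov_p("wasAssociatedWith"), agent)

    for (nm in names(record$inputs)) {
      rdf_add(g, exec, prov_p("used"), emit_entity(record$inputs[[nm]]))
    }
    for (d in record$outputs) {
      out_node <- emit_entity(d)
      rdf_add(g, out_node, prov_p("wasGeneratedBy"), exec)
      rdf_add(g, out_node, prov_p("wasAttributedTo"), agent)
    }
    for (nm in names(record$parameters)) {
      nvp(exec, p_iri("hasParameter"), nm, record$parameters[[nm]])
    }
    for (mb in record$memberships) {
      container <- emit_entity(mb$container)
      element <- emit_entity(mb$element)
      rdf_add(g, container, prov_p("hasMember"), element)
      prop <- switch(mb$relation,
                     attribute = "fromAttribute",
                     index = "containerIndex",
                     slice = "containerSlice")
      rdf_add(g, element, p_iri(prop), rdf_literal(mb$accessor))
    }
  }
  g
}

normalize_rdf_format <- function(format) {
  fmt <- tolower(format)
  fmt <- switch(fmt, ttl = "turtle", turtle = "turtle",
                nt = "ntriples", ntriples = "ntriples",
                "n-triples" = "ntriples", fmt)
  if (!fmt %in% c("turtle", "ntriples")) {
    stop("unsupported RDF format '", format,
         "'; supported formats: turtle (ttl), ntriples (nt)", call. = FALSE)
  }
  fmt
}

#' Write a provenance document to an RDF file
#'
#' @param doc a `provenance_document` (or a session, which is built
#'   first).
#' @param path destination file.
#' @param format `"turtle"` (default) or `"ntriples"`.
#' @return `path`, invisibly. The written file parses back into an
#'   isomorphic graph.
#' @export
write_provenance <- function(doc, path, format = "turtle") {
  fmt <- normalize_rdf_format(format)
  if (!inherits(doc, "provenance_document") && !inherits(doc, "rdf_graph")) {
    doc <- provenance_document(doc)
  }
  text <- switch(fmt,
                 turtle = serialize_turtle(doc),
                 ntriples = serialize_ntriples(doc))
  writeLines(text, path, sep = "", useBytes = TRUE)
  invisible(path)
}

#' Read serialized provenance
#'
#' Parses one or more RDF files (Turtle or N-Triples) and unions them into
#' a single document. Entities with equal URNs unify automatically, which
#' is what connects records captured by separate runs.
#'
#' @param paths character vector of RDF file paths.
#' @return a `provenance_document`.
#' @export
read_provenance <- function(paths) {
  graphs <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("RDF file not found: ", p, call. = FALSE)
    tryCatch(parse_turtle(paste(readLines(p, warn = FALSE),
                                collapse = "\n")),
             error = function(e) {
               stop("failed to parse RDF file '", p, "': ",
                    conditionMessage(e), call. = FALSE)
             })
  })
  doc <- if (length(graphs) == 1L) graphs[[1L]] else merge_graphs(graphs)
  class(doc) <- unique(c("provenance_document", class(doc)))
  doc
}

#' Merge provenance documents
#'
#' Triple-set union; no rewriting logic is needed because identity is
#' carried by deterministic URNs.
#'
#' @param ... `provenance_document` objects (or a single list of them).
#' @return the merged `provenance_document`.
#' @export
merge_provenance <- function(...) {
  docs <- list(...)
  if (length(docs) == 1L && is.list(docs[[1L]]) &&
      !inherits(docs[[1L]], "rdf_graph")) {
    docs <- docs[[1L]]
  }
  out <- merge_graphs(docs)
  class(out) <- unique(c("provenance_document", class(out)))
  out
}
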