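# Projection of serialized provenance onto a property graph for
# inspection, simplification, SNAP-style aggregation, and export.
#
# Node attribute conventions follow the GEXF exports consumed by graph
# tools: every node has `type` (object / file / function), `label`
# (class name, function name, or "File"), `Python_name` (dotted
# implementation path, empty for files), and `Time Interval`
# ("<[start,end]>" built from execution order). Edges point in the
# direction of data flow: used-entity -> activity -> generated-entity.

split_urn <- function(urn) strsplit(urn, ":", fixed = TRUE)[[1L]]

urn_kind <- function(urn) {
  parts <- split_urn(urn)
  if (length(parts) >= 4L) parts[[4L]] else ""
}

object_class_from_urn <- function(urn) {
  parts <- split_urn(urn)
  if (length(parts) >= 6L) parts[[6L]] else ""
}

last_dotted <- function(x) {
  parts <- strsplit(x, ".", fixed = TRUE)[[1L]]
  parts[[length(parts)]]
}

#' Load serialized provenance as a visualization graph
#'
#' Parses one or more RDF provenance files (or takes an already loaded
#' [provenance_document()]), merges them, and projects the triples onto a
#' directed property graph. Object metadata is copied into node attributes
#' according to the `attributes` / `annotations` selection, and function
#' parameters are attached to function nodes (optionally prefixed by the
#' function name). Loading the same file twice is idempotent.
#'
#' @param x character vector of RDF file paths, or a
#'   `provenance_document`.
#' @param attributes character vector of attribute names to copy onto
#'   object nodes, or `TRUE` for all (default); unknown names are simply
#'   absent.
#' @param annotations annotation names to copy, or `TRUE` for all.
#' @param prefix_params prefix parameter attribute names with the function
#'   name (`fun.param`)?
#' @return a directed `igraph` graph whose vertex names are URNs.
#' @export
provenance_graph <- function(x, attributes = TRUE, annotations = TRUE,
                             prefix_params = FALSE) {
  doc <- if (inherits(x, "rdf_graph")) x else read_provenance(x)
  tf <- triples_frame(doc)
  type_p <- paste0(RDF_NS, "type")

  node_class <- function(cls) {
    tf$s[tf$p == type_p & tf$o == paste0(ALPACA_NS, cls)]
  }
  objects <- unique(node_class("DataObjectEntity"))
  files <- unique(node_class("FileEntity"))
  execs <- unique(node_class("FunctionExecution"))

  lit <- function(s, p) {
    v <- tf$o[tf$s == s & tf$p == paste0(ALPACA_NS, p)]
    if (length(v) == 0L) NA_character_ else v[[1L]]
  }
  # name/value pairs hanging off `s` through property `p`
  nvp_values <- function(s, p) {
    bn <- tf$o[tf$s == s & tf$p == paste0(ALPACA_NS, p) &
                 tf$o_kind == "bnode"]
    if (length(bn) == 0L) return(list())
    out <- list()
    for (b in bn) {
      nm <- tf$o[tf$s == b & tf$p == paste0(ALPACA_NS, "pairName")]
      val <- tf$o[tf$s == b & tf$p == paste0(ALPACA_NS, "pairValue")]
      if (length(nm) == 1L && length(val) >= 1L) out[[nm]] <- val[[1L]]
    }
    out
  }
  select_pairs <- function(pairs, selection) {
    if (isTRUE(selection)) return(pairs)
    if (is.character(selection)) return(pairs[intersect(selection,
                                                        names(pairs))])
    list()
  }

  nodes <- list()
  add_node <- function(urn, base, extra = list()) {
    nodes[[urn]] <<- c(base, extra)
  }

  fn_name_of <- function(exec) {
    fn <- tf$o[tf$s == exec & tf$p == paste0(ALPACA_NS, "usedFunction")]
    if (length(fn) == 0L) return(list(name = "unknown", module = ""))
    nm <- lit(fn[[1L]], "functionName")
    md <- lit(fn[[1L]], "implementedIn")
    list(name = if (is.na(nm)) "unknown" else nm,
         module = if (is.na(md)) "" else md)
  }

  exec_order <- integer(0L)
  for (ex in execs) {
    fn <- fn_name_of(ex)
    ord <- suppressWarnings(as.integer(lit(ex, "executionOrder")))
    exec_order[[ex]] <- if (is.na(ord)) 0L else ord
    params <- nvp_values(ex, "hasParameter")
    if (length(params) > 0L) {
      pkey <- paste(bsort(paste0(names(params), "=", unlist(params))),
                    collapse = ";")
    } else pkey <- ""
    if (prefix_params && length(params) > 0L) {
      names(params) <- paste(fn$name, names(params), sep = ".")
    }
    add_node(ex,
             list(type = "function", label = fn$name,
                  Python_name = paste0(fn$module,
                                       if (nzchar(fn$module)) "." else "",
                                       fn$name),
                  hashSource = "",
                  param_key = pkey),
             params)
  }
  for (ob in objects) {
    cls <- object_class_from_urn(ob)
    attrs <- select_pairs(nvp_values(ob, "hasAttribute"), attributes)
    anns <- select_pairs(nvp_values(ob, "hasAnnotation"), annotations)
    hs <- lit(ob, "hashSource")
    add_node(ob,
             list(type = "object", label = last_dotted(cls),
                  Python_name = cls,
                  hashSource = if (is.na(hs)) "" else hs,
                  param_key = ""),
             c(attrs, anns))
  }
  for (fl in files) {
    pth <- lit(fl, "filePath")
    add_node(fl,
             list(type = "file", label = "File", Python_name = "",
                  hashSource = "", param_key = "",
                  File_path = if (is.na(pth)) "" else pth,
                  data_hash = tail(split_urn(fl), 1L)))
  }

  # data-flow and membership edges
  ef <- list(from = character(0L), to = character(0L),
             membership = logical(0L), label = character(0L))
  add_edge <- function(from, to, membership = FALSE, label = "") {
    ef$from <<- c(ef$from, from)
    ef$to <<- c(ef$to, to)
    ef$membership <<- c(ef$membership, membership)
    ef$label <<- c(ef$label, label)
  }
  used <- tf[tf$p == prov_p("used"), , drop = FALSE]
  for (i in seq_len(nrow(used))) add_edge(used$o[[i]], used$s[[i]])
  gen <- tf[tf$p == prov_p("wasGeneratedBy"), , drop = FALSE]
  for (i in seq_len(nrow(gen))) add_edge(gen$o[[i]], gen$s[[i]])
  mem <- tf[tf$p == prov_p("hasMember"), , drop = FALSE]
  for (i in seq_len(nrow(mem))) {
    el <- mem$o[[i]]
    acc_attr <- lit(el, "fromAttribute")
    acc_idx <- lit(el, "containerIndex")
    acc_slice <- lit(el, "containerSlice")
    lbl <- if (!is.na(acc_attr)) paste0(".", acc_attr)
           else if (!is.na(acc_idx)) paste0("[", acc_idx, "]")
           else if (!is.na(acc_slice)) paste0("[", acc_slice, "]")
           else ""
    add_edge(mem$s[[i]], el, membership = TRUE, label = lbl)
  }

  # drop edge endpoints without a node record (defensive)
  keep <- ef$from %in% names(nodes) & ef$to %in% names(nodes)
  ef <- lapply(ef, function(v) v[keep])

  # vertex data frame over the union of attribute names
  all_attr <- unique(unlist(lapply(nodes, names)))
  vdf <- data.frame(name = names(nodes), stringsAsFactors = FALSE)
  for (at in all_attr) {
    vdf[[at]] <- vapply(nodes, function(nd) {
      v <- nd[[at]]
      if (is.null(v)) "" else as.character(v)
    }, character(1L))
  }
  edf <- data.frame(from = ef$from, to = ef$to,
                    membership = ef$membership, label = ef$label,
                    stringsAsFactors = FALSE)
  edf <- unique(edf)
  g <- igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)

  # time intervals from execution order
  vn <- igraph::V(g)$name
  start <- rep(NA_integer_, length(vn))
  end <- rep(NA_integer_, length(vn))
  ord_of <- function(urn) exec_order[[urn]]
  is_exec <- vn %in% execs
  start[is_exec] <- vapply(vn[is_exec], ord_of, integer(1L))
  end[is_exec] <- start[is_exec]
  el <- igraph::as_data_frame(g, what = "edges")
  flow <- el[!el$membership, , drop = FALSE]
  for (i in which(!is_exec)) {
    urn <- vn[[i]]
    gen_o <- flow$from[flow$to == urn]
    use_o <- flow$to[flow$from == urn]
    ords <- c(vapply(gen_o[gen_o %in% execs], ord_of, integer(1L)),
              vapply(use_o[use_o %in% execs], ord_of, integer(1L)))
    if (length(ords) > 0L) {
      start[[i]] <- min(ords)
      end[[i]] <- max(ords)
    }
  }
  # pure containers inherit the hull of their members' intervals
  memb <- el[el$membership, , drop = FALSE]
  for (i in which(is.na(start))) {
    urn <- vn[[i]]
    nb <- unique(c(memb$to[memb$from == urn], memb$from[memb$to == urn]))
    ords <- c(start[match(nb, vn)], end[match(nb, vn)])
    ords <- ords[!is.na(ords)]
    if (length(ords) > 0L) {
      start[[i]] <- min(ords)
      end[[i]] <- max(ords)
    } else {
      start[[i]] <- 0L
      end[[i]] <- 0L
    }
  }
  igraph::V(g)$`Time Interval` <- sprintf("<[%d,%d]>", start, end)
  g
}

#' Remove null-return nodes
#'
#' Functions called for their side effects return the null object; its
#' entity nodes (hash method UUID) carry no data lineage and can be
#' omitted from the visualization. Incident edges are removed with the
#' nodes; everything else is untouched.
#'
#' @param g graph from [provenance_graph()].
#' @return the reduced graph.
#' @export
remove_none_nodes <- function(g) {
  drop <- igraph::V(g)[igraph::V(g)$type == "object" &
                         igraph::V(g)$hashSource == "UUID"]
  igraph::delete_vertices(g, drop)
}

#' Condense container-access chains
#'
#' A chain of membership hops (e.g. container --`.segments`-->
#' list --`[1]`--> element) is collapsed to a single edge labeled with
#' the concatenated accessor (`.segments[1]`). Intermediate nodes are
#' removed only when membership hops are their sole incident provenance
#' edges; an intermediate that also feeds a function execution is
#' retained and the chain is not collapsed across it.
#'
#' @param g graph from [provenance_graph()].
#' @return graph with condensed membership edges.
#' @export
condense_memberships <- function(g) {
  repeat {
    el <- igraph::as_data_frame(g, what = "edges")
    vn <- igraph::V(g)$name
    candidate <- NULL
    for (v in vn) {
      inc_in <- el[el$to == v, , drop = FALSE]
      inc_out <- el[el$from == v, , drop = FALSE]
      if (nrow(inc_in) + nrow(inc_out) == 0L) next
      if (!all(inc_in$membership) || !all(inc_out$membership)) next
      if (nrow(inc_in) >= 1L && nrow(inc_out) >= 1L) {
        candidate <- v
        break
      }
    }
    if (is.null(candidate)) break
    inc_in <- el[el$to == candidate, , drop = FALSE]
    inc_out <- el[el$from == candidate, , drop = FALSE]
    for (i in seq_len(nrow(inc_in))) {
      for (j in seq_len(nrow(inc_out))) {
        g <- igraph::add_edges(
          g, c(inc_in$from[[i]], inc_out$to[[j]]),
          attr = list(membership = TRUE,
                      label = paste0(inc_in$label[[i]], inc_out$label[[j]])))
      }
    }
    g <- igraph::delete_vertices(g, candidate)
  }
  g
}

# --- SNAP aggregation -------------------------------------------------------

node_group_key <- function(g, group_attributes, use_parameters) {
  vs <- igraph::V(g)
  key <- paste(vs$type, vs$label, vs$Python_name, sep = "\r")
  for (at in group_attributes) {
    vals <- igraph::vertex_attr(g, at)
    if (is.null(vals)) vals <- rep("", length(vs))
    vals[is.na(vals)] <- "<missing>"
    key <- paste(key, vals, sep = "\r")
  }
  if (use_parameters) {
    pk <- igraph::vertex_attr(g, "param_key")
    if (!is.null(pk)) key <- paste(key, pk, sep = "\r")
  }
  key
}

#' Aggregate a provenance graph (SNAP summarization)
#'
#' Summarization by Grouping Nodes on Attributes and Pairwise edges:
#' nodes are first grouped by type, label, implementation path, the
#' selected attribute values (missing values form their own group) and,
#' optionally, the recorded function parameters; groups are then refined
#' until grouped nodes have compatible edges (two nodes stay grouped only
#' if they connect to the same set of neighbor groups, per direction and
#' edge kind). Each supernode lists its member URNs in the `members`
#' attribute and their number in `member_count`; supernode time
#' intervals are the hull of the member intervals.
#'
#' @param g graph from [provenance_graph()].
#' @param group_attributes character vector of node-attribute names whose
#'   values distinguish groups (e.g. an annotation holding the trial type).
#' @param use_parameters take function-parameter values into account?
#' @return the aggregated `igraph`; `sum(member_count)` equals the
#'   node count of `g`.
#' @export
aggregate_graph <- function(g, group_attributes = character(),
                            use_parameters = FALSE) {
  n <- igraph::vcount(g)
  if (n == 0L) return(g)
  key <- node_group_key(g, group_attributes, use_parameters)
  el <- igraph::as_data_frame(g, what = "edges")
  vn <- igraph::V(g)$name
  from_i <- match(el$from, vn)
  to_i <- match(el$to, vn)
  # edge compatibility distinguishes the relation kind (container access
  # vs data flow), not the accessor text: two nodes whose members are
  # reached by different positional indices are still the same step
  ekind <- ifelse(el$membership, "member", "flow")

  # refine until the pairwise-edge condition holds
  repeat {
    grp <- match(key, unique(key))
    out_sig <- vapply(seq_len(n), function(i) {
      idx <- which(from_i == i)
      paste(bsort(unique(paste0("O", ekind[idx], "|", grp[to_i[idx]]))),
            collapse = ";")
    }, character(1L))
    in_sig <- vapply(seq_len(n), function(i) {
      idx <- which(to_i == i)
      paste(bsort(unique(paste0("I", ekind[idx], "|", grp[from_i[idx]]))),
            collapse = ";")
    }, character(1L))
    newkey <- paste(key, out_sig, in_sig, sep = "\n")
    if (length(unique(newkey)) == length(unique(key))) break
    key <- newkey
  }

  grp <- match(key, unique(key))
  groups <- split(seq_len(n), grp)

  shared_or_blank <- function(vals) {
    u <- unique(vals[!is.na(vals)])
    if (length(u) == 1L) u else ""
  }
  attr_names <- igraph::vertex_attr_names(g)
  sup <- data.frame(name = vapply(groups, function(idx) {
    paste0(igraph::V(g)$type[idx[[1L]]], ":",
           igraph::V(g)$label[idx[[1L]]], ":",
           substr(digest::digest(key[idx[[1L]]], algo = "sha1"), 1L, 10L))
  }, character(1L)), stringsAsFactors = FALSE)
  for (at in setdiff(attr_names, "name")) {
    vals <- igraph::vertex_attr(g, at)
    sup[[at]] <- vapply(groups, function(idx) shared_or_blank(vals[idx]),
                        character(1L))
  }
  sup$members <- vapply(groups, function(idx) {
    paste(bsort(vn[idx]), collapse = ";")
  }, character(1L))
  sup$member_count <- vapply(groups, length, integer(1L))
  intervals <- igraph::vertex_attr(g, "Time Interval")
  if (!is.null(intervals)) {
    lo <- suppressWarnings(as.integer(sub("^<\\[(\\-?[0-9]+),.*$", "\\1",
                                          intervals)))
    hi <- suppressWarnings(as.integer(sub("^.*,(\\-?[0-9]+)\\]>$", "\\1",
                                          intervals)))
    sup$`Time Interval` <- vapply(groups, function(idx) {
      if (all(is.na(lo[idx]))) "<[0,0]>"
      else sprintf("<[%d,%d]>", min(lo[idx], na.rm = TRUE),
                   max(hi[idx], na.rm = TRUE))
    }, character(1L))
  }

  gmap <- stats::setNames(sup$name[grp], vn)
  sedges <- data.frame(from = unname(gmap[el$from]),
                       to = unname(gmap[el$to]),
                       membership = el$membership, label = el$label,
                       stringsAsFactors = FALSE)
  sedges <- unique(sedges)
  igraph::graph_from_data_frame(sedges, directed = TRUE, vertices = sup)
}

# --- export -----------------------------------------------------------------

#' Export a visualization graph
#'
#' Writes GEXF 1.2 or GraphML. All node and edge attributes are exported;
#' values are stringified where the format requires it.
#'
#' @param g `igraph` graph.
#' @param path destination file.
#' @param format `"gexf"` (default) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("gexf", "graphml")) {
  format <- match.arg(tolower(format[1L]), c("gexf", "graphml"))
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    write_gexf(g, path)
  }
  invisible(path)
}

write_gexf <- function(g, path) {
  doc <- xml2::xml_new_root("gexf", xmlns = "http://gexf.net/1.2",
                            version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "directed",
                               mode = "static")
  nattr <- setdiff(igraph::vertex_attr_names(g), c("name", "label"))
  eattr <- setdiff(igraph::edge_attr_names(g), character(0L))
  attrs_node <- xml2::xml_add_child(graph, "attributes", class = "node")
  for (i in seq_along(nattr)) {
    xml2::xml_add_child(attrs_node, "attribute", id = as.character(i - 1L),
                        title = nattr[[i]], type = "string")
  }
  if (length(eattr) > 0L) {
    attrs_edge <- xml2::xml_add_child(graph, "attributes", class = "edge")
    for (i in seq_along(eattr)) {
      xml2::xml_add_child(attrs_edge, "attribute", id = as.character(i - 1L),
                          title = eattr[[i]], type = "string")
    }
  }
  nodes <- xml2::xml_add_child(graph, "nodes")
  vdf <- igraph::as_data_frame(g, what = "vertices")
  labels <- if ("label" %in% names(vdf)) vdf$label else vdf$name
  for (i in seq_len(nrow(vdf))) {
    nd <- xml2::xml_add_child(nodes, "node", id = vdf$name[[i]],
                              label = as.character(labels[[i]]))
    if (length(nattr) > 0L) {
      av <- xml2::xml_add_child(nd, "attvalues")
      for (j in seq_along(nattr)) {
        val <- vdf[[nattr[[j]]]][[i]]
        if (is.null(val) || is.na(val)) val <- ""
        xml2::xml_add_child(av, "attvalue", `for` = as.character(j - 1L),
                            value = as.character(val))
      }
    }
  }
  edges <- xml2::xml_add_child(graph, "edges")
  edf <- igraph::as_data_frame(g, what = "edges")
  for (i in seq_len(nrow(edf))) {
    ed <- xml2::xml_add_child(edges, "edge", id = paste0("e", i - 1L),
                              source = edf$from[[i]], target = edf$to[[i]])
    if (length(eattr) > 0L) {
      av <- xml2::xml_add_child(ed, "attvalues")
      for (j in seq_along(eattr)) {
        val <- edf[[eattr[[j]]]][[i]]
        if (is.null(val) || is.na(val)) val <- ""
        xml2::xml_add_child(av, "attvalue", `for` = as.character(j - 1L),
                            value = as.character(val))
      }
    }
  }
  xml2::write_xml(doc, path)
}

#' Read a GEXF file back into an igraph graph
#'
#' Counterpart of [export_graph()] for inspection and round-trip checks.
#'
#' @param path GEXF file.
#' @return directed `igraph` graph with the stored attributes.
#' @export
read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  adecl <- list()
  for (attrs in xml2::xml_find_all(doc, ".//attributes")) {
    cls <- xml2::xml_attr(attrs, "class")
    for (at in xml2::xml_find_all(attrs, "./attribute")) {
      adecl[[paste0(cls, "|", xml2::xml_attr(at, "id"))]] <-
        xml2::xml_attr(at, "title")
    }
  }
  node_els <- xml2::xml_find_all(doc, ".//nodes/node")
  vdf <- data.frame(name = xml2::xml_attr(node_els, "id"),
                    label = xml2::xml_attr(node_els, "label"),
                    stringsAsFactors = FALSE)
  for (i in seq_along(node_els)) {
    for (av in xml2::xml_find_all(node_els[[i]], "./attvalues/attvalue")) {
      title <- adecl[[paste0("node|", xml2::xml_attr(av, "for"))]]
      if (is.null(title)) next
      if (is.null(vdf[[title]])) vdf[[title]] <- NA_character_
      vdf[[title]][[i]] <- xml2::xml_attr(av, "value")
    }
  }
  edge_els <- xml2::xml_find_all(doc, ".//edges/edge")
  edf <- data.frame(from = xml2::xml_attr(edge_els, "source"),
                    to = xml2::xml_attr(edge_els, "target"),
                    stringsAsFactors = FALSE)
  for (i in seq_along(edge_els)) {
    for (av in xml2::xml_find_all(edge_els[[i]], "./attvalues/attvalue")) {
      title <- adecl[[paste0("edge|", xml2::xml_attr(av, "for"))]]
      if (is.null(title)) next
      if (is.null(edf[[title]])) edf[[title]] <- NA_character_
      edf[[title]][[i]] <- xml2::xml_attr(av, "value")
    }
  }
  igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
}
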