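# Minimal RDF layer: a triple store with Turtle and N-Triples syntax,
# deterministic serialization, blank-node canonicalization for isomorphism
# checks, and set-union merging. Covers the Turtle subset needed for
# PROV provenance documents (prefixed names, IRIs, typed literals,
# labeled and anonymous blank nodes, predicate/object lists).

XSD <- "http://www.w3.org/2001/XMLSchema#"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
PROV_NS <- "http://www.w3.org/ns/prov#"
ALPACA_NS <- "http://purl.org/alpaca/ontology#"

rdf_iri <- function(value) list(kind = "iri", value = value)
rdf_bnode <- function(id) list(kind = "bnode", value = id)
rdf_literal <- function(value, datatype = NULL) {
  list(kind = "literal", value = as.character(value), datatype = datatype)
}

#' Create an empty RDF graph
#'
#' @param namespaces named character vector of prefix -> namespace IRI.
#' @return an `rdf_graph` object (environment-backed, mutated in place by
#'   [rdf_add()]).
#' @keywords internal
rdf_graph <- function(namespaces = character()) {
  g <- new.env(parent = emptyenv())
  g$triples <- vector("list", 256L)
  g$n <- 0L
  g$namespaces <- namespaces
  class(g) <- "rdf_graph"
  g
}

rdf_add <- function(g, s, p, o) {
  # force the arguments before touching the counter: an argument expression
  # may itself add triples to this graph (e.g. entity emission)
  force(s); force(p); force(o)
  if (g$n == length(g$triples)) {
    length(g$triples) <- 2L * max(1L, length(g$triples))
  }
  g$n <- g$n + 1L
  g$triples[[g$n]] <- list(s = s, p = p, o = o)
  invisible(g)
}

rdf_triples <- function(g) {
  if (g$n == 0L) list() else g$triples[seq_len(g$n)]
}

#' @export
print.rdf_graph <- function(x, ...) {
  cat("<rdf_graph> ", x$n, " triples, ", length(x$namespaces),
      " namespaces\n", sep = "")
  invisible(x)
}

#' @export
length.rdf_graph <- function(x) x$n

# Flat view used by the graph projection: one row per triple.
triples_frame <- function(g) {
  tr <- rdf_triples(g)
  data.frame(
    s_kind = vapply(tr, function(t) t$s$kind, character(1L)),
    s = vapply(tr, function(t) t$s$value, character(1L)),
    p = vapply(tr, function(t) t$p, character(1L)),
    o_kind = vapply(tr, function(t) t$o$kind, character(1L)),
    o = vapply(tr, function(t) t$o$value, character(1L)),
    stringsAsFactors = FALSE)
}

# --- serialization ----------------------------------------------------------

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[[i]]
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    res <- character(0L)
    j <- 1L
    while (j <= length(chars)) {
      ch <- chars[[j]]
      if (ch == "\\" && j < length(chars)) {
        nxt <- chars[[j + 1L]]
        res <- c(res, switch(nxt, n = "\n", r = "\r", t = "\t",
                             "\\" = "\\", "\"" = "\"", nxt))
        j <- j + 2L
      } else {
        res <- c(res, ch)
        j <- j + 1L
      }
    }
    out[[i]] <- paste(res, collapse = "")
  }
  out
}

compress_iri <- function(iri, namespaces) {
  for (prefix in names(namespaces)) {
    ns <- namespaces[[prefix]]
    if (startsWith(iri, ns)) {
      local <- substring(iri, nchar(ns) + 1L)
      if (grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", local) &&
          !endsWith(local, ".")) {
        return(paste0(prefix, ":", local))
      }
    }
  }
  paste0("<", iri, ">")
}

term_turtle <- function(node, namespaces) {
  switch(node$kind,
    iri = compress_iri(node$value, namespaces),
    bnode = paste0("_:", node$value),
    literal = {
      lit <- paste0("\"", escape_literal(node$value), "\"")
      dt <- node$datatype
      if (!is.null(dt) && dt != paste0(XSD, "string")) {
        lit <- paste0(lit, "^^", compress_iri(dt, namespaces))
      }
      lit
    })
}

term_ntriples <- function(node) {
  switch(node$kind,
    iri = paste0("<", node$value, ">"),
    bnode = paste0("_:", node$value),
    literal = {
      lit <- paste0("\"", escape_literal(node$value), "\"")
      dt <- node$datatype
      if (!is.null(dt) && dt != paste0(XSD, "string")) {
        lit <- paste0(lit, "^^<", dt, ">")
      }
      lit
    })
}

bsort <- function(x) sort(x, method = "radix")

# Deterministic Turtle: prefixes, then subjects in byte order; rdf:type
# first as "a"; blank nodes referenced exactly once inline as [...].
serialize_turtle <- function(g) {
  tr <- rdf_triples(g)
  ns <- g$namespaces
  header <- paste0("@prefix ", names(ns), ": <", unname(ns), "> .")
  header <- header[bsort_order(names(ns))]

  skey <- vapply(tr, function(t) paste0(t$s$kind, "|", t$s$value),
                 character(1L))
  obj_bnode_count <- table(unlist(lapply(tr, function(t) {
    if (t$o$kind == "bnode") t$o$value else NULL
  })))
  subj_bnodes <- unique(unlist(lapply(tr, function(t) {
    if (t$s$kind == "bnode") t$s$value else NULL
  })))
  inline_ids <- names(obj_bnode_count)[obj_bnode_count == 1L]

  by_subject <- split(tr, skey)

  render_object <- function(o) {
    if (o$kind == "bnode" && o$value %in% inline_ids) {
      inner <- by_subject[[paste0("bnode|", o$value)]]
      if (is.null(inner)) return("[]")
      paste0("[ ", render_predicates(inner, indent = FALSE), " ]")
    } else {
      term_turtle(o, ns)
    }
  }

  render_predicates <- function(triples, indent = TRUE) {
    preds <- vapply(triples, function(t) t$p, character(1L))
    type_iri <- paste0(RDF_NS, "type")
    ord <- order(preds != type_iri, preds, method = "radix")
    triples <- triples[ord]
    preds <- preds[ord]
    parts <- character(0L)
    for (p in unique(preds)) {
      objs <- vapply(triples[preds == p], function(t) render_object(t$o),
                     character(1L))
      objs <- bsort(objs)
      plabel <- if (p == type_iri) "a" else compress_iri(p, ns)
      parts <- c(parts, paste0(plabel, " ", paste(objs, collapse = ", ")))
    }
    sep <- if (indent) " ;\n    " else " ; "
    paste(parts, collapse = sep)
  }

  blocks <- character(0L)
  top_keys <- names(by_subject)
  # IRIs first (sorted), then blank-node subjects not rendered inline
  iri_keys <- bsort(top_keys[startsWith(top_keys, "iri|")])
  bn_keys <- top_keys[startsWith(top_keys, "bnode|")]
  bn_keys <- bn_keys[!(sub("^bnode\\|", "", bn_keys) %in% inline_ids)]
  bn_keys <- bsort(bn_keys)
  for (key in c(iri_keys, bn_keys)) {
    triples <- by_subject[[key]]
    subj <- triples[[1L]]$s
    blocks <- c(blocks, paste0(term_turtle(subj, ns), " ",
                               render_predicates(triples), " ."))
  }
  paste0(paste(header, collapse = "\n"), "\n\n",
         paste(blocks, collapse = "\n\n"), "\n")
}

bsort_order <- function(x) order(x, method = "radix")

serialize_ntriples <- function(g) {
  tr <- rdf_triples(g)
  lines <- vapply(tr, function(t) {
    paste0(term_ntriples(t$s), " <", t$p, "> ", term_ntriples(t$o), " .")
  }, character(1L))
  paste0(paste(bsort(unique(lines)), collapse = "\n"), "\n")
}

# --- Turtle parser ----------------------------------------------------------

# One-pass vectorized tokenizer: a master alternation extracts all tokens,
# then each token is classified. Anything between tokens must be whitespace
# or a comment.
tokenize_turtle <- function(text) {
  master <- paste0(
    "#[^\n]*",                                     # comment
    "|@prefix\\b|@base\\b",
    "|<[^<>\"{}|^`\\\\ ]*>",                       # IRIREF
    "|\"(?:[^\"\\\\]|\\\\.)*\"",                   # STRING
    "|_:[A-Za-z0-9][A-Za-z0-9_.-]*",               # BNODE
    "|\\^\\^",                                     # DTYPE
    "|[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z_][A-Za-z0-9_.%-]*",  # PNAME
    "|[A-Za-z][A-Za-z0-9_.-]*:",                   # PNAME_NS
    "|[+-]?[0-9]+(?:\\.[0-9]+)?(?:[eE][+-]?[0-9]+)?",      # NUMBER
    "|true\\b|false\\b",
    "|a\\b",
    "|@[a-zA-Z]+(?:-[a-zA-Z0-9]+)*",               # LANGTAG
    "|[.;,\\[\\]()]")
  m <- gregexpr(master, text, perl = TRUE)[[1L]]
  toks <- if (m[[1L]] == -1L) character(0L) else regmatches(text, list(m))[[1L]]
  leftover <- text
  if (length(toks) > 0L) {
    regmatches(leftover, list(m)) <- list(rep("", length(toks)))
  }
  if (grepl("[^ \t\r\n]", leftover)) {
    bad <- regmatches(leftover, regexpr("[^ \t\r\n]+", leftover))
    stop("Turtle tokenizer: unexpected input: ", substr(bad, 1L, 30L),
         call. = FALSE)
  }
  type <- character(length(toks))
  type[startsWith(toks, "#")] <- "COMMENT"
  type[toks == "@prefix"] <- "PREFIX_DECL"
  type[toks == "@base"] <- "BASE_DECL"
  type[startsWith(toks, "<")] <- "IRIREF"
  type[startsWith(toks, "\"")] <- "STRING"
  type[startsWith(toks, "_:")] <- "BNODE"
  type[toks == "^^"] <- "DTYPE"
  type[type == "" & grepl("^[A-Za-z][A-Za-z0-9_.-]*:.+$", toks)] <- "PNAME"
  type[type == "" & grepl("^[A-Za-z][A-Za-z0-9_.-]*:$", toks)] <- "PNAME_NS"
  type[type == "" & grepl("^[+-]?[0-9]", toks)] <- "NUMBER"
  type[type == "" & toks %in% c("true", "false")] <- "BOOLEAN"
  type[type == "" & toks == "a"] <- "KW_A"
  type[type == "" & startsWith(toks, "@")] <- "LANGTAG"
  type[type == "" & toks %in% c(".", ";", ",", "[", "]", "(", ")")] <- "PUNCT"
  if (any(type == "")) {
    stop("Turtle tokenizer: unclassifiable token '",
         toks[type == ""][[1L]], "'", call. = FALSE)
  }
  keep <- type != "COMMENT"
  toks <- toks[keep]
  type <- type[keep]
  mapply(function(ty, tx) list(type = ty, text = tx), type, toks,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Parse Turtle text into an RDF graph
#'
#' Supports the subset of Turtle this package writes, plus labeled and
#' anonymous blank nodes, object/predicate lists, numeric and boolean
#' shorthand literals.
#'
#' @param text Turtle source as a single string.
#' @return an `rdf_graph`.
#' @keywords internal
parse_turtle <- function(text) {
  tokens <- tokenize_turtle(text)
  g <- rdf_graph()
  prefixes <- character(0L)
  i <- 1L
  bnode_auto <- 0L

  peek <- function() if (i <= length(tokens)) tokens[[i]] else NULL
  advance <- function() {
    tok <- tokens[[i]]
    i <<- i + 1L
    tok
  }
  expect_punct <- function(ch) {
    tok <- advance()
    if (is.null(tok) || tok$text != ch) {
      stop("Turtle parser: expected '", ch, "' got '",
           if (is.null(tok)) "<eof>" else tok$text, "'", call. = FALSE)
    }
  }
  expand_pname <- function(txt) {
    parts <- regmatches(txt, regexpr(":", txt, fixed = TRUE),
                        invert = TRUE)[[1L]]
    prefix <- parts[[1L]]
    local <- if (length(parts) > 1L) parts[[2L]] else ""
    if (!(prefix %in% names(prefixes))) {
      stop("Turtle parser: undefined prefix '", prefix, ":'", call. = FALSE)
    }
    paste0(prefixes[[prefix]], local)
  }

  parse_node <- function(role) {
    tok <- advance()
    switch(tok$type,
      IRIREF = rdf_iri(substr(tok$text, 2L, nchar(tok$text) - 1L)),
      PNAME = ,
      PNAME_NS = rdf_iri(expand_pname(tok$text)),
      BNODE = rdf_bnode(substring(tok$text, 3L)),
      KW_A = rdf_iri(paste0(RDF_NS, "type")),
      STRING = {
        value <- unescape_literal(substr(tok$text, 2L,
                                         nchar(tok$text) - 1L))
        dt <- NULL
        nxt <- peek()
        if (!is.null(nxt) && nxt$type == "DTYPE") {
          advance()
          dt_node <- parse_node("datatype")
          dt <- dt_node$value
        } else if (!is.null(nxt) && nxt$type == "LANGTAG") {
          advance()  # language tags accepted, not preserved separately
        }
        rdf_literal(value, dt)
      },
      NUMBER = {
        dt <- if (grepl("[.eE]", tok$text)) paste0(XSD, "decimal")
              else paste0(XSD, "integer")
        rdf_literal(tok$text, dt)
      },
      BOOLEAN = rdf_literal(tok$text, paste0(XSD, "boolean")),
      PUNCT = {
        if (tok$text == "[") {
          bnode_auto <<- bnode_auto + 1L
          node <- rdf_bnode(paste0("anon", bnode_auto))
          nxt <- peek()
          if (!is.null(nxt) && !(nxt$type == "PUNCT" && nxt$text == "]")) {
            parse_predicate_object_list(node)
          }
          expect_punct("]")
          node
        } else {
          stop("Turtle parser: unexpected '", tok$text, "' as ", role,
               call. = FALSE)
        }
      },
      stop("Turtle parser: unexpected token ", tok$type, " as ", role,
           call. = FALSE))
  }

  parse_predicate_object_list <- function(subject) {
    repeat {
      pred <- parse_node("predicate")
      repeat {
        obj <- parse_node("object")
        rdf_add(g, subject, pred$value, obj)
        nxt <- peek()
        if (!is.null(nxt) && nxt$type == "PUNCT" && nxt$text == ",") {
          advance()
        } else break
      }
      nxt <- peek()
      if (!is.null(nxt) && nxt$type == "PUNCT" && nxt$text == ";") {
        advance()
        nxt <- peek()
        # dangling ';' before '.' or ']'
        if (!is.null(nxt) && nxt$type == "PUNCT" &&
            nxt$text %in% c(".", "]")) break
      } else break
    }
  }

  while (!is.null(peek())) {
    tok <- peek()
    if (tok$type == "PREFIX_DECL") {
      advance()
      ns_tok <- advance()
      iri_tok <- advance()
      prefix <- sub(":$", "", ns_tok$text)
      prefixes[[prefix]] <- substr(iri_tok$text, 2L, nchar(iri_tok$text) - 1L)
      expect_punct(".")
    } else if (tok$type == "BASE_DECL") {
      advance(); advance(); expect_punct(".")
    } else {
      subject <- parse_node("subject")
      nxt <- peek()
      if (!is.null(nxt) && !(nxt$type == "PUNCT" && nxt$text == ".")) {
        parse_predicate_object_list(subject)
      }
      expect_punct(".")
    }
  }
  g$namespaces <- prefixes
  g
}

# --- canonicalization and isomorphism --------------------------------------

ground_key <- function(node) {
  switch(node$kind,
    iri = paste0("I", node$value),
    literal = paste0("L", node$value, "^^",
                     if (is.null(node$datatype)) "" else node$datatype),
    bnode = "B")
}

# Iterative signature refinement over blank nodes; ground neighborhoods
# propagate through up to `rounds` hops. Vectorized over triples.
bnode_signatures <- function(g, rounds = 4L) {
  tr <- rdf_triples(g)
  s_kind <- vapply(tr, function(t) t$s$kind, character(1L))
  o_kind <- vapply(tr, function(t) t$o$kind, character(1L))
  s_val <- vapply(tr, function(t) t$s$value, character(1L))
  o_val <- vapply(tr, function(t) t$o$value, character(1L))
  p_val <- vapply(tr, function(t) t$p, character(1L))
  s_ground <- vapply(tr, function(t) ground_key(t$s), character(1L))
  o_ground <- vapply(tr, function(t) ground_key(t$o), character(1L))

  ids <- unique(c(s_val[s_kind == "bnode"], o_val[o_kind == "bnode"]))
  if (length(ids) == 0L) return(character(0L))
  sig <- stats::setNames(rep("b", length(ids)), ids)
  out_idx <- which(s_kind == "bnode")
  in_idx <- which(o_kind == "bnode")
  for (round in seq_len(rounds)) {
    okey <- o_ground[out_idx]
    ob <- o_kind[out_idx] == "bnode"
    okey[ob] <- paste0("B", sig[o_val[out_idx][ob]])
    out_parts <- split(paste0("OUT|", p_val[out_idx], "|", okey),
                       s_val[out_idx])
    skey <- s_ground[in_idx]
    sb <- s_kind[in_idx] == "bnode"
    skey[sb] <- paste0("B", sig[s_val[in_idx][sb]])
    in_parts <- split(paste0("IN|", skey, "|", p_val[in_idx]),
                      o_val[in_idx])
    newsig <- vapply(ids, function(id) {
      digest::digest(bsort(c(out_parts[[id]], in_parts[[id]])),
                     algo = "sha1")
    }, character(1L))
    names(newsig) <- ids
    if (identical(unname(newsig), unname(sig))) break
    sig <- newsig
  }
  sig
}

# Canonical N-Triples: blank nodes renamed deterministically from their
# structural signatures (ties broken by signature-group order), lines
# sorted bytewise. Two graphs are isomorphic iff their canonical forms are
# byte-identical (exact for the tree-shaped blank nodes this package
# produces).
canonical_ntriples <- function(g) {
  sig <- bnode_signatures(g)
  if (length(sig) > 0L) {
    ord <- order(sig, method = "radix")
    label <- stats::setNames(sprintf("c%06d", seq_along(ord)),
                             names(sig)[ord])
    g2 <- rdf_graph(g$namespaces)
    for (t in rdf_triples(g)) {
      s <- if (t$s$kind == "bnode") rdf_bnode(label[[t$s$value]]) else t$s
      o <- if (t$o$kind == "bnode") rdf_bnode(label[[t$o$value]]) else t$o
      rdf_add(g2, s, t$p, o)
    }
    g <- g2
  }
  serialize_ntriples(g)
}

#' Test two RDF graphs for isomorphism
#'
#' Blank-node renaming is allowed; everything else must match exactly.
#'
#' @param g1,g2 `rdf_graph` objects.
#' @return logical.
#' @keywords internal
graph_isomorphic <- function(g1, g2) {
  identical(canonical_ntriples(g1), canonical_ntriples(g2))
}

# Set-union of graphs. Ground triples are deduplicated; blank nodes from
# different graphs are kept apart by relabeling, so no identities are
# invented -- entities with equal URNs unify automatically.
merge_graphs <- function(graphs) {
  out <- rdf_graph()
  ns <- character(0L)
  seen <- new.env(parent = emptyenv())
  for (k in seq_along(graphs)) {
    g <- graphs[[k]]
    ns <- c(ns, g$namespaces[setdiff(names(g$namespaces), names(ns))])
    for (t in rdf_triples(g)) {
      s <- if (t$s$kind == "bnode") {
        rdf_bnode(paste0("g", k, "_", t$s$value))
      } else t$s
      o <- if (t$o$kind == "bnode") {
        rdf_bnode(paste0("g", k, "_", t$o$value))
      } else t$o
      if (s$kind != "bnode" && o$kind != "bnode") {
        key <- paste(ground_key(s), t$p, ground_key(o), sep = "\r")
        if (!is.null(seen[[digest::digest(key, algo = "xxhash64")]])) next
        seen[[digest::digest(key, algo = "xxhash64")]] <- TRUE
      }
      rdf_add(out, s, t$p, o)
    }
  }
  out$namespaces <- ns
  out
}
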