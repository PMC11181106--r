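# Visualization graph: projection, simplification, export.

test_that("a single execution projects to entities + activity with flow edges", {
  local_clean_capture()
  s <- single_record_session()
  g <- provenance_graph(provenance_document(s))
  vdf <- igraph::as_data_frame(g, what = "vertices")
  expect_equal(sum(vdf$type == "function"), 1L)
  expect_equal(sum(vdf$type == "object"), 3L)
  expect_equal(vdf$label[vdf$type == "function"], "welch_psd")
  expect_equal(vdf$Python_name[vdf$type == "function"],
               "provtrace.welch_psd")
  el <- igraph::as_data_frame(g, what = "edges")
  flow <- el[!el$membership, ]
  # 1 used edge in, 2 generated edges out
  exec <- vdf$name[vdf$type == "function"]
  expect_equal(sum(flow$to == exec), 1L)
  expect_equal(sum(flow$from == exec), 2L)
  # time intervals derived from the execution order
  expect_equal(unique(vdf$`Time Interval`), "<[1,1]>")
})

test_that("loading the same file twice is idempotent", {
  fx <- demo_fixture()
  g1 <- provenance_graph(fx$ttl)
  g2 <- provenance_graph(c(fx$ttl, fx$ttl))
  expect_equal(igraph::vcount(g1), igraph::vcount(g2))
  expect_equal(igraph::ecount(g1), igraph::ecount(g2))
})

test_that("attribute selection controls the exported node metadata", {
  fx <- demo_fixture()
  g_all <- provenance_graph(fx$ttl)
  g_sel <- provenance_graph(fx$ttl, attributes = "shape",
                            annotations = character(0))
  vdf <- igraph::as_data_frame(g_sel, what = "vertices")
  expect_true("shape" %in% names(vdf))
  expect_false("units" %in% names(vdf))
  expect_true("units" %in%
                names(igraph::as_data_frame(g_all, what = "vertices")))
  # unknown selected attributes are silently absent
  g_unknown <- provenance_graph(fx$ttl, attributes = "no_such_attr")
  expect_false("no_such_attr" %in%
                 names(igraph::as_data_frame(g_unknown, "vertices")))
})

test_that("parameter prefixing marks function-node attributes", {
  fx <- demo_fixture()
  g <- provenance_graph(fx$ttl, prefix_params = TRUE)
  vdf <- igraph::as_data_frame(g, what = "vertices")
  expect_true("butter_filter.lowpass_frequency" %in% names(vdf))
})

test_that("null-node removal drops exactly the uuid-hash entities", {
  local_clean_capture()
  s <- with_session(function() {
    plot1 <- track(function(x) invisible(NULL), inputs = "x",
                   name = "plot1")
    plot2 <- track(function(x) invisible(NULL), inputs = "x",
                   name = "plot2")
    plot1(1); plot2(2)
  })
  g <- provenance_graph(provenance_document(s))
  # the null object is a shared session singleton: both plotting calls
  # generate the same uuid-hash entity (oracle: count uuid-hash entities)
  n_uuid <- sum(igraph::V(g)$hashSource == "UUID")
  expect_equal(n_uuid, 1L)
  g2 <- remove_none_nodes(g)
  expect_equal(igraph::vcount(g2), igraph::vcount(g) - n_uuid)
  expect_equal(sum(igraph::V(g2)$type == "function"), 2L)
  # idempotent on graphs without null nodes
  expect_equal(igraph::vcount(remove_none_nodes(g2)), igraph::vcount(g2))
})

test_that("membership chains condense into a single labeled edge", {
  local_clean_capture()
  blk <- block(segments = list(segment()))
  s <- with_session(function() {
    f <- track(function(seg) 1, inputs = "seg", name = "f")
    f(blk$segments[[1]])
  })
  g <- provenance_graph(provenance_document(s))
  gc <- condense_memberships(g)
  # the pure-container list node disappears
  expect_equal(igraph::vcount(gc), igraph::vcount(g) - 1L)
  el <- igraph::as_data_frame(gc, what = "edges")
  expect_true(".segments[1]" %in% el$label)
  # graphs without memberships are unchanged
  s2 <- with_session(function() {
    f <- track(function(x) x, inputs = "x", name = "f")
    f(5)
  })
  g2 <- provenance_graph(provenance_document(s2))
  expect_equal(igraph::vcount(condense_memberships(g2)),
               igraph::vcount(g2))
})

test_that("intermediates feeding a function are retained when condensing", {
  local_clean_capture()
  blk <- block(segments = list(segment()))
  s <- with_session(function() {
    f <- track(function(seg) 1, inputs = "seg", name = "f")
    g_ <- track(function(lst) length(lst), inputs = "lst", name = "g_")
    f(blk$segments[[1]])
    g_(blk$segments)       # the intermediate list also feeds a function
  })
  g <- provenance_graph(provenance_document(s))
  gc <- condense_memberships(g)
  labels <- igraph::V(gc)$label
  expect_true("list" %in% labels)  # intermediate kept
  el <- igraph::as_data_frame(gc, what = "edges")
  expect_false(".segments[1]" %in% el$label)  # chain not fully collapsed
})

test_that("condensation preserves reachability between non-container nodes", {
  fx <- demo_fixture()
  g <- remove_none_nodes(provenance_graph(fx$ttl))
  gc <- condense_memberships(g)
  common <- intersect(igraph::V(g)$name, igraph::V(gc)$name)
  d1 <- igraph::distances(g, v = common, to = common, mode = "out")
  d2 <- igraph::distances(gc, v = common, to = common, mode = "out")
  expect_identical(is.finite(d1), is.finite(d2))
})

test_that("GEXF export round-trips topology and attributes", {
  local_clean_capture()
  s <- single_record_session()
  g <- provenance_graph(provenance_document(s))
  p <- tempfile(fileext = ".gexf")
  export_graph(g, p, format = "gexf")
  g2 <- read_gexf(p)
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  v1 <- igraph::as_data_frame(g, "vertices")
  v2 <- igraph::as_data_frame(g2, "vertices")
  ord <- match(v1$name, v2$name)
  expect_equal(v2$type[ord], v1$type)
  expect_equal(v2$`Time Interval`[ord], v1$`Time Interval`)

  # well-formed XML with the GEXF 1.2 namespace and declared attributes
  x <- xml2::read_xml(p)
  expect_equal(xml2::xml_ns(x)[[1]], "http://gexf.net/1.2")
  xml2::xml_ns_strip(x)
  ids <- xml2::xml_attr(xml2::xml_find_all(x, ".//nodes/node"), "id")
  expect_setequal(ids, igraph::V(g)$name)
  for (av in xml2::xml_find_all(x, ".//attvalue")) {
    expect_false(is.na(xml2::xml_attr(av, "value")))
  }
})

test_that("GEXF export of an empty graph is valid", {
  g <- igraph::make_empty_graph(directed = TRUE)
  p <- tempfile(fileext = ".gexf")
  export_graph(g, p)
  x <- xml2::read_xml(p)
  xml2::xml_ns_strip(x)
  expect_length(xml2::xml_find_all(x, ".//nodes/node"), 0L)
})

test_that("GraphML export round-trips through igraph", {
  local_clean_capture()
  s <- single_record_session()
  g <- provenance_graph(provenance_document(s))
  p <- tempfile(fileext = ".graphml")
  export_graph(g, p, format = "graphml")
  g2 <- igraph::read_graph(p, format = "graphml")
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
})
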