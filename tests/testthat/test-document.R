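# PROV mapping: node classes, ontology properties, URN determinism.

count_class <- function(doc, cls) {
  sum(vapply(provtrace:::rdf_triples(doc), function(t) {
    t$p == paste0(provtrace:::RDF_NS, "type") &&
      t$o$kind == "iri" && t$o$value == paste0(provtrace:::ALPACA_NS, cls)
  }, logical(1)))
}

prop_values <- function(doc, prop) {
  out <- character(0)
  for (t in provtrace:::rdf_triples(doc)) {
    if (t$p == paste0(provtrace:::ALPACA_NS, prop) &&
        t$o$kind == "literal") {
      out <- c(out, t$o$value)
    }
  }
  out
}

test_that("a single spectral-estimation record serializes to the expected node set", {
  local_clean_capture()
  s <- single_record_session()
  doc <- provenance_document(s)
  # the welch call returns two arrays, plus the signal input: 3 entities
  expect_equal(count_class(doc, "DataObjectEntity"), 3L)
  expect_equal(count_class(doc, "FunctionExecution"), 1L)
  expect_equal(count_class(doc, "Function"), 1L)
  expect_equal(count_class(doc, "ScriptAgent"), 1L)
  expect_gt(count_class(doc, "NameValuePair"), 0L)
  expect_true("frequency_resolution" %in% prop_values(doc, "pairName"))
  expect_true(all(prop_values(doc, "hashSource") %in%
                    c("joblib_SHA1", "Python_hash", "UUID")))
})

test_that("functions deduplicate across records", {
  local_clean_capture()
  s <- with_session(function() {
    f <- track(function(x) x + 1, inputs = "x", name = "inc")
    f(1); f(2)
  })
  doc <- provenance_document(s)
  expect_equal(count_class(doc, "FunctionExecution"), 2L)
  expect_equal(count_class(doc, "Function"), 1L)
  # oracle: distinct objects of the usedFunction property
  used <- unique(vapply(Filter(function(t) {
    t$p == paste0(provtrace:::ALPACA_NS, "usedFunction")
  }, provtrace:::rdf_triples(doc)), function(t) t$o$value, character(1)))
  expect_length(used, 1L)
})

test_that("URNs are deterministic across rebuilds of the same history", {
  local_clean_capture()
  s <- single_record_session()
  iris <- function(doc) {
    sort(unique(unlist(lapply(provtrace:::rdf_triples(doc), function(t) {
      c(if (t$s$kind == "iri") t$s$value,
        if (t$o$kind == "iri") t$o$value)
    }))))
  }
  expect_identical(iris(provenance_document(s)),
                   iris(provenance_document(s)))
})

test_that("URNs follow the published template grammar", {
  local_clean_capture()
  out_file <- tempfile()
  # a "script" function: defined outside any package namespace
  writer_fn <- eval(quote(function(x, path) writeLines(format(x), path)),
                    envir = globalenv())
  s <- with_session(function() {
    w <- track(writer_fn, inputs = "x", file_outputs = "path",
               name = "writer")
    w(analog_signal(matrix(0, 4, 2), sampling_rate = 10), out_file)
  })
  doc <- provenance_document(s)
  iris <- unique(unlist(lapply(provtrace:::rdf_triples(doc), function(t) {
    c(if (t$s$kind == "iri") t$s$value, if (t$o$kind == "iri") t$o$value)
  })))
  auth <- provtrace_settings()$authority
  expect_true(any(grepl(sprintf(
    "^urn:%s:alpaca:object:Python:provtrace\\.AnalogSignal:[0-9a-f]{40}$",
    auth), iris)))
  expect_true(any(grepl(sprintf(
    "^urn:%s:alpaca:file:sha256:[0-9a-f]{64}$", auth), iris)))
  expect_true(any(grepl(sprintf(
    "^urn:%s:alpaca:function:Python:__main__\\.writer$", auth), iris)))
  expect_true(any(grepl(sprintf(
    "^urn:%s:alpaca:function_execution:Python:[0-9a-f]{64}:%s:%s#%s$",
    auth, "[0-9a-f-]{36}", "__main__\\.writer", "[0-9a-f-]{36}"), iris)))
  expect_true(any(grepl(sprintf(
    "^urn:%s:alpaca:script:Python:.+:[0-9a-f]{64}#[0-9a-f-]{36}$", auth),
    iris)))
})

test_that("every activity is associated with exactly one script agent", {
  local_clean_capture()
  s <- with_session(function() {
    f <- track(function(x) x, inputs = "x", name = "f")
    f(1); f(2); f(3)
  })
  doc <- provenance_document(s)
  tr <- provtrace:::rdf_triples(doc)
  assoc <- Filter(function(t) {
    t$p == paste0(provtrace:::PROV_NS, "wasAssociatedWith")
  }, tr)
  execs <- vapply(assoc, function(t) t$s$value, character(1))
  agents <- vapply(assoc, function(t) t$o$value, character(1))
  expect_equal(length(execs), 3L)
  expect_length(unique(execs), 3L)
  expect_length(unique(agents), 1L)
})

test_that("membership triples carry exactly one accessor property each", {
  local_clean_capture()
  blk <- block(segments = list(segment()))
  s <- with_session(function() {
    f <- track(function(seg) 1, inputs = "seg", name = "f")
    f(blk$segments[[1]])
  })
  doc <- provenance_document(s)
  tr <- provtrace:::rdf_triples(doc)
  members <- Filter(function(t) {
    t$p == paste0(provtrace:::PROV_NS, "hasMember")
  }, tr)
  expect_length(members, 2L)
  for (m in members) {
    el <- m$o$value
    acc_props <- Filter(function(t) {
      t$s$kind == "iri" && t$s$value == el &&
        t$p %in% paste0(provtrace:::ALPACA_NS,
                        c("fromAttribute", "containerIndex",
                          "containerSlice"))
    }, tr)
    expect_length(unique(vapply(acc_props, function(t) t$p, character(1))),
                  1L)
  }
})
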