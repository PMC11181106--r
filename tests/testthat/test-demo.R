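# Synthetic recording generator and the end-to-end demo pipeline.

test_that("recording generation is seeded and counts events correctly", {
  cfg <- demo_config(channels = 3L, trials_per_type = 4L)
  r1 <- generate_recording(cfg, seed = 7)
  r2 <- generate_recording(cfg, seed = 7)
  expect_identical(r1, r2)

  evt <- r1$segments[[1]]$events[[1]]
  labels <- attr(evt, "array_annotations")$trial_event_labels
  expect_equal(sum(labels == "CUE-OFF"), 16L)  # 4 trials x 4 types
  types <- attr(evt, "array_annotations")$belongs_to_trialtype
  expect_setequal(unique(types), c("SGLF", "SGHF", "PGLF", "PGHF"))
  expect_equal(unname(table(types)[provtrace:::TRIAL_TYPES]),
               rep(4L, 4L), ignore_attr = TRUE)
  # events lie within the recording
  sig <- r1$segments[[1]]$analogsignals[[1]]
  expect_true(all(unclass(evt) >= 0 &
                    unclass(evt) < attr(sig, "t_stop")))
  expect_error(generate_recording(demo_config(channels = 0L)), "positive")
})

test_that("a pure sinusoid has its Welch peak at the ground-truth bin", {
  # closed form: a 20 Hz sinusoid sampled at 500 Hz, estimated at 2 Hz
  # resolution, concentrates its power at the 20 Hz bin
  fs <- 500
  t <- (0:(fs * 2 - 1)) / fs
  sig <- analog_signal(matrix(sin(2 * pi * 20 * t), ncol = 1),
                       sampling_rate = fs)
  wp <- welch_psd(sig, frequency_resolution = 2)
  freqs <- as.numeric(wp[[1]])
  psd <- wp[[2]]
  expect_equal(length(freqs), 126L)   # 0..250 Hz in 2 Hz steps
  expect_equal(freqs[which.max(psd[1, ])], 20)
  # Hanning leakage is confined to the adjacent bins: the closed form puts
  # 2/3 of the power in the center bin (0.5^2 vs two 0.25^2 side bins)
  expect_equal(max(psd[1, ]) / sum(psd[1, ]), 2 / 3, tolerance = 0.01)
  in_band <- freqs >= 18 & freqs <= 22
  expect_gt(sum(psd[1, in_band]) / sum(psd[1, ]), 0.999)
})

test_that("the provenance sidecar records the shape propagation", {
  fx <- demo_fixture()
  g <- provenance_graph(fx$ttl)
  vdf <- igraph::as_data_frame(g, what = "vertices")
  el <- igraph::as_data_frame(g, what = "edges")
  flow <- el[!el$membership, ]

  ds_execs <- vdf$name[vdf$label == "downsample_signal"]
  in_shapes <- vdf$shape[match(flow$from[flow$to %in% ds_execs], vdf$name)]
  out_shapes <- vdf$shape[match(flow$to[flow$from %in% ds_execs], vdf$name)]
  # 500 ms at 30 kHz = 15,000 samples; divided by 60 = 250; 6 channels
  # minus the 2 excluded = 4
  expect_equal(unique(in_shapes), "(15000, 4)")
  expect_equal(unique(out_shapes), "(250, 4)")

  welch_execs <- vdf$name[vdf$label == "welch_psd"]
  w_out <- vdf[match(flow$to[flow$from %in% welch_execs], vdf$name), ]
  expect_true("(126,)" %in% w_out$shape)       # frequency array
  expect_true("(4, 126)" %in% w_out$shape)     # per-channel power
  expect_true("Hz" %in% w_out$units)
})

test_that("stage parameters are recoverable from the RDF alone", {
  fx <- demo_fixture()
  g <- provenance_graph(fx$ttl, prefix_params = TRUE)
  vdf <- igraph::as_data_frame(g, what = "vertices")
  grab <- function(col) unique(vdf[[col]][nzchar(vdf[[col]])])
  expect_equal(grab("butter_filter.lowpass_frequency"), "250")
  expect_equal(grab("downsample_signal.factor"), "60")
  expect_equal(grab("welch_psd.frequency_resolution"), "2")
  expect_equal(grab("welch_psd.window"), "hanning")
  expect_equal(grab("welch_psd.overlap"), "0.5")
  expect_equal(grab("add_epoch.post"), "0.5")
  tt <- grab("get_events.properties")
  expect_length(tt, 4L)  # one parameter set per trial type
  expect_true(all(grepl("CUE-OFF", tt)))
})

test_that("the plot file is reachable from every input entity", {
  fx <- demo_fixture()
  g <- provenance_graph(fx$ttl)
  vdf <- igraph::as_data_frame(g, what = "vertices")
  files <- vdf$name[vdf$type == "file"]
  png_node <- files[grepl("\\.png$", vdf$File_path[match(files, vdf$name)])]
  expect_length(png_node, 1L)
  sources <- setdiff(files, png_node)
  expect_gte(length(sources), 1L)
  d <- igraph::distances(g, v = sources, to = png_node, mode = "out")
  expect_true(all(is.finite(d)))
  expect_true(igraph::is_connected(g, mode = "weak"))
})

test_that("split pipeline modes produce the expected RDF file counts", {
  expect_length(split_fixture("single")$rdf, 1L)
  expect_length(split_fixture("two_process")$rdf, 2L)
  expect_length(split_fixture("two_stage")$rdf, 3L)
})

test_that("concatenated split-run provenance forms one connected graph", {
  for (mode in c("two_process", "two_stage")) {
    g <- provenance_graph(split_fixture(mode)$rdf)
    expect_true(igraph::is_connected(g, mode = "weak"), label = mode)
  }
})

test_that("two-stage runs connect through the intermediate file identity", {
  fx <- split_fixture("two_stage")
  docs <- lapply(fx$rdf, read_provenance)
  file_urns <- function(doc) {
    unique(unlist(lapply(provtrace:::rdf_triples(doc), function(t) {
      v <- c(if (t$s$kind == "iri") t$s$value,
             if (t$o$kind == "iri") t$o$value)
      grep(":alpaca:file:sha256:", v, value = TRUE)
    })))
  }
  stage1_files <- file_urns(docs[[1]])
  plot_files <- file_urns(docs[[3]])
  expect_gte(length(intersect(stage1_files, plot_files)), 1L)
})

test_that("config files round-trip through the key-value reader", {
  p <- tempfile(fileext = ".cfg")
  writeLines(c("channels = 8",
               "trials_per_type = 2",
               "lowpass_frequency = 250",
               "exclude_channels = chan 2, chan 4",
               "# a comment",
               "window = hanning"), p)
  cfg <- read_demo_config(p)
  expect_equal(cfg$channels, 8)
  expect_equal(cfg$trials_per_type, 2)
  expect_equal(cfg$exclude_channels, c("chan 2", "chan 4"))
  expect_equal(cfg$window, "hanning")
  expect_equal(cfg$downsample_factor, 60L)  # untouched default
  expect_error(demo_config(not_a_key = 1), "unknown configuration")
})
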