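# provtrace

Lightweight provenance capture for data-analysis scripts in R.

When an analysis script produces a result file — say a figure of mean
power spectral densities (PSDs) computed from a multichannel
electrophysiology recording — everything that explains the result exists
only at run time: which events defined the trial epochs, which channels
were excluded, the filter cutoff, the downsampling factor, the spectral
resolution, and the shapes of every intermediate array. provtrace records
this lineage while the script runs, with minimal instrumentation, and
writes it as a machine-readable sidecar file next to the result. It is
aimed at scientists who share analysis outputs in collaborative settings
and need the "how was this made" to travel with the file.

## What it records and how

Data-processing functions are wrapped once:

```r
welch <- track(welch_psd, inputs = "sig")
```

While a session is active (`activate()`), every call through a wrapper
appends one execution record: descriptors of the inputs and outputs
(class, implementing package, content hash, memory address, attribute
and annotation snapshots such as `shape`, `units`, `t_start`), SHA-256
digests for file inputs/outputs, all remaining arguments as parameters —
including declared defaults that were never typed at the call site — the
source statement, start/end timestamps, and a global execution order.
Container accesses in argument expressions (`block$segments[[1]]`) are
decomposed into per-hop membership records by analyzing the call
expression against the live frame.

The history serializes to RDF (Turtle by default) under the W3C PROV-O
ontology plus a small extension vocabulary: function executions are
Activities, data objects and files are Entities, the script is a
SoftwareAgent, and parameters/metadata are name–value blank nodes. Every
node has a deterministic URN built from content hashes, so RDF files
written by independent runs (parallel processes, multi-stage pipelines)
can simply be concatenated and unify into one connected lineage graph.

A visualization layer projects RDF files onto directed igraph graphs
(data flow: used entity → execution → generated entity), simplifies them
(null-return removal, condensing access chains like `.segments[1]` to
one edge), summarizes them with SNAP aggregation (grouping nodes on
attributes and pairwise edge compatibility, with `members` /
`member_count` on each supernode), and exports GEXF 1.2 or GraphML for
tools such as Gephi. `exec/provtrace-graph` wraps this layer as a
command-line tool.

## Worked example

The package ships a synthetic analogue of a reach-to-grasp LFP analysis:
a multichannel 30 kHz recording with CUE-OFF events for four trial types
(SGLF/SGHF/PGLF/PGHF), processed per trial by channel exclusion, a
250 Hz low-pass Butterworth filter, downsampling by 60, and a Welch PSD
at 2 Hz resolution (Hanning window, 50% overlap), then averaged and
plotted. Every stage is a tracked call.

```r
library(provtrace)

cfg <- demo_config(channels = 6, trials_per_type = 2,
                   exclude_channels = c("chan 2", "chan 4"))
rec <- generate_recording(cfg, seed = 42, subject = "subject_N")
res <- run_demo_pipeline(rec, cfg, output_dir = "psd_demo")
res$n_records
#> [1] 71
```

The run leaves `psd_demo/demo_psd.png` and its provenance sidecar
`psd_demo/demo_psd.ttl`, holding 71 tracked executions. Everything below
is read back from the sidecar alone:

```r
g <- provenance_graph(res$ttl)
igraph::vcount(g); igraph::ecount(g)
#> [1] 185
#> [1] 253

# shape recorded for the signals leaving the downsample stage:
vdf <- igraph::as_data_frame(g, what = "vertices")
el  <- igraph::as_data_frame(g, what = "edges")
ds  <- vdf$name[vdf$label == "downsample_signal"]
unique(vdf$shape[match(el$to[el$from %in% ds & !el$membership], vdf$name)])
#> [1] "(250, 4)"
```

`(250, 4)` is the provenance answering two questions at once: the 500 ms
epochs held 15,000 samples at 30 kHz and left the factor-60 downsample
stage with 250, and only 4 of the 6 channels survived the exclusion.
Parameters are equally recoverable:

```r
gp <- provenance_graph(res$ttl, prefix_params = TRUE)
v <- igraph::V(gp)$butter_filter.lowpass_frequency
unique(v[nzchar(v)])
#> [1] "250"
```

Aggregation collapses the structurally identical trial paths into a
birds-eye summary:

```r
ag <- aggregate_graph(condense_memberships(remove_none_nodes(g)))
igraph::vcount(ag); sum(igraph::V(ag)$member_count)
#> [1] 36
#> [1] 170
export_graph(ag, "psd_demo/demo_aggregated.gexf")
```

36 supernodes summarize all 170 simplified nodes; grouping with
`group_attributes = "belongs_to_trialtype"` instead keeps the four
trial-type paths separate. `run_split_pipeline()` demonstrates the same
analysis split across independent runs whose RDF files merge into one
connected graph.

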