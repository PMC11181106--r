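---
title: "Capturing analysis provenance with provtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capturing analysis provenance with provtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

A data-analysis script transforms inputs into result files through a
sequence of function calls whose parameters, intermediate objects, and
data flow exist only at run time. Once the result file is shared, none of
that context travels with it: the epoching windows, filter cutoffs, or
spectral-estimation settings that produced a figure cannot be recovered
from the figure. provtrace records this lineage while the script runs and
stores it as a machine-readable sidecar file next to the result.

The provenance model is W3C PROV-O. Each tracked call becomes an
*Activity* (`FunctionExecution`); every data object or file that a call
reads or produces becomes an *Entity* (`DataObjectEntity`,
`FileEntity`); the running script is a *SoftwareAgent*
(`ScriptAgent`). `prov:used` and `prov:wasGeneratedBy` edges carry the
data flow; `prov:hasMember` records container accesses. Two extension
classes carry tool-specific structure: `Function` (identity of the
callable: name, implementing package, version) and `NameValuePair`
(blank nodes holding parameters, object attributes, and annotations).
The extension properties (`hasParameter`, `executionOrder`,
`codeStatement`, `usedFunction`, `hasAttribute`, `hasAnnotation`,
`hashSource`, `filePath`, `scriptPath`, `functionName`,
`implementedIn`, `functionVersion`, `pairName`, `pairValue`) follow the
published extension vocabulary of the originating tool so that records
are interoperable with its consumers. For the same reason the URN
grammar is kept byte-exact, including its literal language token:

```
urn:[authority]:alpaca:object:Python:[class]:[hash]
urn:[authority]:alpaca:file:[hash type]:[file hash]
urn:[authority]:alpaca:function_execution:Python:[script hash]:[session]:[function]#[execution]
urn:[authority]:alpaca:function:Python:[function]
urn:[authority]:alpaca:script:Python:[file name]:[script hash]#[session]
```

Identity lives entirely in these URNs: an object is named by its class
and content hash, a file by its SHA-256 digest. Because the names are
deterministic, RDF files written by independent runs can simply be
concatenated — entities that denote the same bytes unify without any
rewriting, which is what makes multi-process and multi-stage workflows
merge into one connected lineage graph. The ontology namespace is not
printed in the published description; this package fixes it to
`http://purl.org/alpaca/ontology#` and treats that string as part of its
stable interface.

## Capture semantics in R

The published design is a Python function decorator; this package maps
the mechanics onto R semantics. These mappings are design choices of
this implementation:

* **Wrapping.** `track(fun, inputs=, file_inputs=, file_outputs=)`
  returns a closure with identical call behavior. Declared roles are
  validated against the formals at wrap time. When no session is active
  the wrapper evaluates the original call unchanged.
* **Parameter capture.** Arguments are re-bound against the declared
  signature, and *declared defaults are resolved and recorded as
  parameters* even when not written at the call site — the recorded
  record answers "what did this call actually use", not "what was
  typed".
* **Multiple returns.** R has no tuples; a *plain unclassed list* return
  is enumerated positionally as separate outputs. Classed lists
  (data frames, model fits, the package's own containers) are single
  outputs.
* **Null returns.** `NULL` is a shared singleton: it receives one UUID
  per session (hash method `UUID`), so side-effect-only calls all point
  at a single null entity, which the graph layer can drop.
* **Container accesses.** The argument expression of each input is
  decomposed into `$`/`@` (attribute), `[[` (index), and `[` (slice)
  hops; one membership record per hop is emitted, with intermediate
  objects resolved from the live calling frame. Only chains that bottom
  out in a plain variable are analyzed, so re-evaluating prefixes is
  side-effect free; anything else (including dynamically built calls)
  contributes no memberships while the call itself is still recorded.
  Index accessors held in variables are resolved to their runtime value;
  slice accessors keep their source text (`"1:5"`).
* **Statements.** When calls carry source references (scripts run via
  `Rscript` or `source(keep.source = TRUE)`), the recorded
  `codeStatement` is the full statement found in the parsed activated
  script, multi-line statements as one unit. Otherwise it degrades to
  the deparsed call expression.
* **Error policy.** Capture failures warn and degrade to bounded string
  placeholders; they never alter the user computation. This is the
  "lightweight" contract: the wrapped call's value is bit-identical to
  the unwrapped call's.

### Object identity and hashing

The default identity of an object is a SHA-1 digest over its class name
and serialized state (`digest::digest(list(class, object))`), the
analogue of a content hash over buffer bytes, shape, dtype, and units
for array-likes — those all live in the serialized state of an R object.
The recipe only needs to be deterministic within this implementation;
the serialized `hashSource` literal is one of the three fixed vocabulary
strings (`joblib_SHA1`, `Python_hash`, `UUID`) regardless of internals.

Two cases bypass content hashing. Packages listed in
`builtin_hash_packages` use an identity-based hash (class + memory
address), for objects whose content digest would be expensive or
misleadingly sensitive. Environments — R's reference objects — always
use the identity hash: a mutable reference object is *one* object to the
script, and giving each mutation state a fresh identity would shred its
lineage. The demo's figure and result-bundle accumulators rely on this:
every plotting call uses and regenerates the same figure entity, exactly
as a plotting toolkit's figure object behaves, which also keeps repeated
plotting steps structurally identical for aggregation. The in-place
detection rule (an input whose content hash changed during the call is
additionally emitted as an output) remains in force for value-semantics
objects.

Memory addresses are recorded on descriptors as session-local
disambiguators only; they never enter URNs, because content identity is
what lets graphs from different runs merge. The full attribute snapshot
covers all object attributes plus, when present, `shape`, `dtype`,
`units`, `t_start`, `t_stop`, `sampling_rate`, `nix_name`,
`dimensionality`, `id`, `pid`, `create_time`; annotation dictionaries
(`annotations`, `array_annotations`) are captured directly or through a
metadata plugin registered per package. Values are stored as literals
when scalar and as strings capped at 256 characters otherwise — metadata
should describe bulk data, not embed it.

### Injectable identifiers and clocks

`provtrace_settings(id_source=, clock=)` lets callers replace the
UUID generator and timestamp source. With fixed sources, rebuilding and
serializing the same history is byte-identical Turtle (the writer sorts
prefixes, subjects, predicates, and objects deterministically), which is
how the round-trip and stability tests pin the serialization down.
Timestamps are ISO-8601 UTC with microsecond precision.

## Serialization

No RDF library exists in this R environment, so the package carries a
minimal triple store with a Turtle writer/parser and an N-Triples
writer (`turtle` is the default sidecar format; these two are the
supported syntaxes). The parser covers the Turtle subset the writer
emits plus labeled/anonymous blank nodes, object and predicate lists,
and numeric/boolean shorthand. Graph isomorphism (used by the
round-trip tests) canonicalizes blank nodes by iterated neighborhood
hashing — exact for the tree-shaped `NameValuePair` blank nodes these
documents contain. `merge_provenance()` is a set-union over ground
triples with per-document blank-node relabeling: identity comes from the
URNs, never from rewriting.

## Visualization graphs

`provenance_graph()` projects RDF files onto a directed igraph object.
Edges follow data flow (used-entity → activity → generated-entity;
container → element for memberships). Every node carries `type`
(object / file / function), `label` (class name, function name, or
"File"), `Python_name` (dotted implementation path, the attribute key
kept bit-exact for tool interoperability), and `Time Interval`, a
Gephi-style interval string `<[start,end]>` built from execution order:
an activity with order *o* gets `<[o,o]>`; an entity spans first
generation to last use; pure containers inherit the hull of their
members; supernodes take the hull of member intervals. Object metadata
and function parameters are copied onto nodes according to the user's
attribute/annotation selection, with optional `function.parameter`
prefixing.

Simplification follows the published options: `remove_none_nodes()`
drops the uuid-hash entities of null returns; `condense_memberships()`
replaces each maximal chain of membership hops with one edge labeled by
the concatenated accessor (`.segments[1]`), removing an intermediate
only when membership hops are its sole provenance edges — an
intermediate that also feeds a function survives and the chain is not
collapsed across it. Condensation preserves reachability between the
remaining nodes.

`aggregate_graph()` implements SNAP summarization: nodes are first
grouped by `(type, label, Python_name)`, the values of user-selected
attributes (missing values form their own group), and optionally the
function-parameter multiset; groups are then refined until grouped nodes
connect to identical neighbor-group sets per edge direction and kind.
Edge *kind* distinguishes membership from data-flow edges but not the
accessor text: positional indices (`[1]` vs `[2]`) encode loop
position, and treating them as distinct relations would split
structurally identical iterations — the opposite of what summarization
is for. Supernodes list their members (`members`, `member_count`);
their identifiers concatenate the shared type/label with a digest of the
group key, so exports are reproducible. Export formats are GEXF 1.2
(hand-written via xml2, with a reader for round trips) and GraphML (via
igraph); the `provtrace-graph` script in `exec/` wraps the whole layer
for shell use.

## The demo pipeline and its generator

`generate_recording()` emulates the structure of a multichannel
reach-to-grasp recording: by default 96 channels sampled at 30 kHz, a
CUE-OFF event series cycling through the four trial types
(SGLF/SGHF/PGLF/PGHF, four trials each, all flagged `correct_trial`),
and a signal that is a common 20 Hz sinusoid (amplitude 10, noise SD 2)
across channels. The known spectral peak makes the PSD stage's output
predictable; what the generator does *not* emulate is real LFP
statistics — no 1/f background, channel covariance, movement artifacts,
or per-trial variability in timing — so passing tests demonstrate
correct capture and bookkeeping, not neuroscientific validity of the
synthetic signals.

The tracked pipeline mirrors the published use case: event selection by
annotation dictionary, epoch definition 0–500 ms after CUE-OFF, trial
cutting (15,000 samples at 30 kHz), exclusion of channels "chan 2" and
"chan 4", a 4th-order 250 Hz low-pass Butterworth (`signal::butter` +
`filtfilt`), downsampling by 60 (plain subsampling is exact here because
the signal is already band-limited to the new Nyquist frequency), and a
Welch PSD at 2 Hz resolution with a Hanning window and 50% overlap
(segment length `rate / resolution` = 250 samples, constant detrend,
one-sided density, 126 frequency bins at 500 Hz). Per-trial channel
means accumulate through explicit tracked append steps so the lineage
stays connected from the input files to the PNG; the across-trial
mean/SEM feed an environment-backed figure accumulator.

`run_split_pipeline()` reproduces the distributed scenarios: `single`
(one session, one RDF file), `two_process` (two independent sessions,
the second also plotting the first's in-memory results — entity hashes
unify on merge, emulating a message-passing run without MPI), and
`two_stage` (two compute sessions writing intermediate files plus a
plotting session reading them — file hashes unify on merge). The
merged two-stage graph differs from the single-run graph only by the
save/load steps and the intermediate file entities.

### Problem sizes

The full study conditions (96 channels, 4 trials per type) are the
generator defaults. The test suite exercises the pipeline at 6 channels
× 2 trials per type (and 4 × 1 for the split scenarios); the acceptance
script runs the full 96 channels with one trial per type. The
spectral chain (30 kHz, 500 ms, factor 60, 2 Hz) is identical at every
size — channel and trial counts scale the graph, not the shapes the
records assert.

## Known limitations

* Only calls lexically inside the single activated scope are tracked;
  helpers called *inside* tracked functions are black boxes.
* No capture of the execution environment (interpreter, packages, OS)
  and no control-flow representation — loops appear as parallel paths.
* Wrapped functions are evaluated with standard semantics; functions
  relying on lazy evaluation or non-standard evaluation of their
  arguments should not be tracked.
* Content hashing uses R serialization, so identity is stable within an
  R version's serialization format, not across languages.
* RDF support is limited to Turtle and N-Triples; no RDF/XML, JSON-LD,
  or SPARQL endpoint.
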