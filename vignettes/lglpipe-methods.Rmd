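---
title: "Design and methods of lglpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design and methods of lglpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lglpipe)
```

## The model

`lglpipe` treats a data analysis as an annotated DAG. Nodes are
*processors* — ordinary R functions — and each node produces exactly one
*resource* (which may be an arbitrarily structured object). Root nodes
provide primary resources, the ground truth of the analysis; leaves produce
the final results. The association of one resource per node is what makes
the bookkeeping tractable: a resource is identified by its node's label,
states are per node, and provenance is the executed subgraph.

Two assumptions carry the whole consistency machinery:

1. **Automaticity** — every derived resource is obtained exclusively by
   running node functions on primary resources. Manual edits of cached
   objects, or hidden dependencies on data outside the pipeline, defeat the
   fingerprint checks.
2. **Determinism of node functions** — a rebuilt node is assumed to
   reproduce its previous output if neither its code nor its inputs
   changed. The engine never verifies this; nondeterministic nodes simply
   make caching semantics fuzzy (see Limitations).

## Language semantics: the choices that were open

The LGL constructs (arrows, item sets, named graphs, `@` references, forks,
flags) have fixed meanings, but several surface details had to be pinned
down. These are the package's choices:

* **One graph object per anonymous statement.** A statement with no label
  and no `@` reference creates a new anonymous graph; `@` statements extend
  the referenced graph in place. This reproduces the reference behavior in
  which a named definition followed by two paste statements yields three
  graph objects. The practical consequence — that a pipeline written as a
  plain list of edge statements would fragment into many tiny graphs — is
  absorbed one level up: `pipeline_graph()` merges all registry graphs by
  node label when the program defines more than one, so the edge-list
  coding style still produces a single executable pipeline.
* **Fork grammar.** `parent < /b1 /b2 \bk;` — every branch but the last
  opens with `/`, the last with `\`. A branch is an item, an item set, or a
  further forked operand, which gives trees of arbitrary depth and degree.
  A lone void item `.` as a branch head is elided: its children attach
  directly to the parent.
* **Identifiers** are letters, digits and underscore, not starting with a
  digit — they must be valid R function names, since binding is by name.
  Comments run from `#` to end of line; `|` and newlines are whitespace.
* **Same-label unification.** Within one graph object, a plain item reuses
  an existing node with that label; pasting a named graph always mints
  fresh node instances (so deliberate duplicates are possible). Flags are
  unioned on reuse and survive copying.
* **Reference endpoints are snapshots.** `@G` used as an arrow endpoint
  denotes `G`'s roots/leaves *as the statement began*; nodes added by the
  same statement do not retroactively become endpoints. Without this,
  `D -> @G1;` would also create a self-edge on `D`.
* **Graph-to-graph arrows** connect the left graph's leaves to the right
  graph's roots — the composition of the two node/graph rules.
* **Duplicate edges are suppressed** (the edge list is a set, but its
  creation order is kept, because argument order depends on it).
* **Restrictions**: all `@` references in one statement must name the same
  graph, a named definition cannot contain references, and redefining a
  named label is an error. Each rules out a construct with no established
  meaning, rather than guessing one.
* **Flag vocabulary**: any single letters are accepted and stored; only `F`
  has engine semantics.

## Engine mechanics

**Binding.** Each node label must resolve to a same-named function in the
node source (a file sourced into a private environment, or an
environment/list). Arity must equal in-degree unless the function takes
`...`. The graph must validate as a DAG (depth-first search with a
witnessing cycle in the error).

**Fingerprints.** The code fingerprint of a node is `rlang::hash()` of the
function's extracted source text (its `srcref`, falling back to
`deparse()`). Raw-text hashing is deliberately conservative: reformatting
or comment edits invalidate, which errs on the side of rebuilding rather
than trusting a stale resource. Snapshots of the hashed text are kept under
`srcdb/` for inspection.

**Resource states.** `available` (in RAM), `dumped` (disk blob only),
`to-be-built` (nothing cached), `unavailable` (last build failed). A cached
resource is *valid* for lazy execution only if its stored fingerprint
matches the current source and, for F-nodes, its recorded files are fresh.

**Scheduling.** A request computes the needed set (uncached ancestors,
pruned at any valid cached resource) and levels it into waves by longest
path. Within a wave no node depends on another, so waves are the unit of
parallelism; `parallel::mclapply` forks the pure function calls while all
bookkeeping stays in the parent process. The contract is purely
observational — a sequential executor is a valid implementation — which is
also why parallel and sequential runs must be byte-identical. Two nodes
run in the same wave exactly when neither is an ancestor of the other;
sharing a common ancestor (as two sibling branches always do) does not
prevent parallel execution.

**Argument order.** A node with several parents receives their resources
in incoming-edge creation order from the LGL program. This is the one
place where edge *order* (not just the edge set) is semantic, so the
fixture functions embed their inputs in their output string to make any
ordering bug visible.

**Copy semantics.** `provide()` returns the cached object itself (R's
copy-on-modify protects the cache for ordinary values), while
`getinputs()` returns deep copies via serialization, so mutating reference
objects obtained there can never corrupt the cache.

**Persistence layout.** `metadata.json` (labels, fingerprints, states,
file lists, timings; timestamps ISO-8601, digests hex) plus one
`resources/<uid>.blob` RDS file per dumped resource. Node uids are assigned
deterministically while evaluating the LGL program, so an unchanged
program yields the same uids across sessions; if the pipeline definition
itself changes, records whose label no longer matches are discarded and
those nodes simply rebuild. Switching dumping off stops value blobs only —
metadata is always persisted.

**F-node file tracking.** An F-node's resource must be a character vector
of file names, and the files must exist when the build returns (anything
else is a type error at build time). Staleness is *equality* of the
recorded and current modification timestamps plus existence — an older
timestamp is just as suspicious as a newer one; sizes are recorded for
reporting only.

**Failure policy.** A failing node records state `unavailable`, its
pending descendants are dropped from the plan, unrelated branches complete,
and the original error condition is then re-signalled unmodified.
Previously cached resources are never rolled back.

## Publisher

`protocol_statistics()` populates the protocol's statistics block: node
and F-node counts, output-file count and total size (sizes are re-measured
at call time), and total CPU time; per node, the description, output
files, last build time and required CPU time. CPU time renders as
`HH:MM:SS.cc` and sizes with binary prefixes and two decimals (`2.32G`).
The per-node description is the first line of the function's leading
comment block — R's closest analogue of a docstring; the full block
appears on the node's detail page.

`publish_html()` writes a static, dependency-free HTML tree (inline CSS):
an index with the statistics and a pipeline map, plus one page per node.
The map is a self-generated layered SVG (column = longest path from a
root) with one hyperlink per node; F-nodes are drawn with straight
corners, other nodes rounded. Nothing in the output depends on the time of
publishing, so republishing an unchanged protocol is byte-identical.
`export_graphics()` always writes DOT and delegates rendering to the
external `dot` tool when present, degrading to a warning plus the DOT file
otherwise.

## Synthetic pipelines and what the tests show

`make_string_pipeline()` generates the canonical three-node comparison
pipeline (a root passes a string to two leaves that append distinct
suffixes), written to a real source file so that tests can edit node code
on disk the way a user would. `random_dag(n, p, seed)` ranks nodes and
draws each forward edge with probability `p` — acyclic by construction —
and emits edge-list LGL plus generated node functions that fold their
label, body variant and inputs into the output string. `naive_execute()`
is the reference executor: every node exactly once, topological order, no
caching.

The generators emulate the *control-flow* reality of pipelines — fan-out,
fan-in, deep chains, isolated nodes, code edits (variant bumps) — with
pure, instantaneous string processors. They do not emulate long-running
jobs, external tools, large resources, nondeterministic nodes, or
concurrent writes to shared files. Green tests therefore demonstrate the
engine's scheduling, caching, invalidation and persistence logic, not its
behavior under I/O contention or memory pressure.

Problem sizes were chosen to exercise the combinatorics while keeping the
default suite fast: random DAGs of up to 10 nodes, around a hundred seeded
pipelines for the oracle-equivalence and invalidation properties, and 20
repetitions of the parallel-versus-sequential diamond. Graphs this small
already contain every local structure the engine distinguishes (a node,
its parents, its non-ancestors), and the properties are label-insensitive,
so larger graphs add runtime rather than coverage.

## Limitations

* `provide()` and friends address nodes by label; pipelines that
  deliberately contain several copies of a node need uids for those nodes
  (the error message lists them).
* Fingerprints see only a function's own source text. Changes in helper
  functions it calls, in package versions, or in global state do not
  invalidate resources — `untrust()` exists for exactly those cases.
* The `trust()` workflow operates on current bindings: after editing a
  file, trust from a freshly created protocol (or after
  `detect_code_changes()`, which refreshes bindings but also invalidates).
* File timestamp comparison inherits the filesystem's mtime resolution.
* Parallel execution uses forked processes and is sequential on platforms
  without fork.
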