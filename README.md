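# lglpipe

Lazy, cached, provenance-tracked pipelines for R, driven by LGL graph
definitions.

## The problem

Custom bioinformatic analyses are developed incrementally: partial results
drive new branches of the analysis, code is edited continuously, and
intermediate data objects accumulate in ad-hoc variables and files. Without
structure this becomes hard to reproduce — which intermediate results are
still consistent with the current code? which steps actually produced a
given file? `lglpipe` layers a light pipeline formality over ordinary R
code: the analysis is declared as a directed acyclic graph (DAG) whose
nodes are *processors* (plain R functions) and whose edges carry
*resources* (the single data object each processor produces). The engine
then takes over consistency bookkeeping: lazy execution, transparent
caching, code-change invalidation and protocol publication.

## The LGL graph language

Pipelines are declared in LGL, a small formal language whose text visually
resembles the graph it encodes. It can live in a standalone `.lgl` file or
in a multi-line string inside the same R source file that implements the
node functions. The core constructs:

| Statement            | Meaning                                              |
|----------------------|------------------------------------------------------|
| `A -> B, C;`         | edges `(A,B)`, `(A,C)` — comma binds tighter than arrow |
| `A <- B, C;`         | edges `(B,A)`, `(C,A)`                               |
| `G1: A -> B, C;`     | named graph `G1`                                     |
| `D -> G1;`           | paste a fresh *copy* of `G1`, connect `D` to its roots |
| `D -> @G1;`          | extend the stored graph `G1` itself, in place        |
| `A < /B \C;`         | fork: a visually tree-shaped `A -> B, C;`            |
| `A < /B \.;`         | `.` is the void placeholder — that branch is elided  |
| `B[F]`               | flag `F`: `B`'s resource is the name(s) of file(s) it wrote |

Pipe characters (`|`) and newlines are ignored, so a definition can be laid
out to mirror its drawing. `#` starts a comment. Cyclic graphs can be
*expressed* in LGL, but the execution engine only accepts DAGs.

## The execution model

`lgl_project()` binds each graph node to the same-named R function (a node
with N incoming edges binds to an N-argument function) and returns a
protocol object. Then:

* `provide(pr, "node")` returns that node's resource: from RAM if
  available, loaded from disk if dumped, built on the fly otherwise — and
  only the uncached ancestors on the path to the request are executed.
* `run_pipeline(pr)` provides every leaf (final) resource, executing
  independent ready nodes in parallel when `workers > 1`.
* Every produced resource is transparently stored in RAM and on disk
  (`set_dumping()` switches persistence off), so a later session over the
  same project directory resumes with everything `dumped` and executes
  nothing.
* The engine fingerprints each node's source code. After an edit,
  `detect_code_changes()` clears exactly the edited nodes and their
  descendants; `trust()` accepts an existing resource despite the edit;
  `untrust()` force-clears a node and its dependents.
* Nodes flagged `F` return the file names they produced; the files'
  modification timestamps are tracked and stale or missing files trigger a
  rebuild.
* `publish_html(pr, dir)` exports the executed pipeline as a hypertext
  protocol: a clickable pipeline map, per-node pages with source code,
  documentation, timings and produced files, and whole-pipeline statistics.
  `export_graphics()` writes Graphviz DOT (rendering is delegated to `dot`
  when available).

## Worked example

```r
library(lglpipe)
fx <- make_string_pipeline()      # writes nodes.R with three tiny functions
cat(fx$lgl)
#> first_task -> second_task, third_task;

pr <- lgl_project(fx$source, project_dir = file.path(fx$dir, "proj"))
provide(pr, "second_task")
#> [1] "hello-2"
node_runs(pr)                     # third_task was never executed
#>  first_task second_task  third_task
#>           1           1           0

run_pipeline(pr)                  # completes the remaining branch
#> $second_task  "hello-2"
#> $third_task   "hello-3"

# a new session over the same project directory resumes from disk
pr2 <- lgl_project(fx$source, project_dir = file.path(fx$dir, "proj"))
list_states(pr2)
#>  first_task second_task  third_task
#>    "dumped"    "dumped"    "dumped"

# edit second_task's source, then ask what became inconsistent
write_string_pipeline(fx$source, suffixes = c(second_task = "-2!", third_task = "-3"))
detect_code_changes(pr2)
#> [1] "second_task"
provide(pr2, "second_task")       # only the edited node is rebuilt
#> [1] "hello-2!"
```

`provide()` returned `"hello-2"` by running `first_task` (which emits
`"hello"`) and `second_task` (which appends `"-2"`), while `third_task`'s
counter stayed at 0: laziness. After the edit, exactly `second_task` was
invalidated — `first_task`'s cached `"hello"` was reused for the rebuild.

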