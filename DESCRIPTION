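Package: lglpipe
Title: Lazy, Cached, Provenance-Tracked Pipelines from LGL Graph Definitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A small formal graph language (LGL) for declaring analysis
    pipelines inside ordinary R source files, together with an execution
    engine that binds graph nodes to same-named R functions and provides
    lazy resource production, RAM and disk caching, source-code
    fingerprinting with cascading invalidation, file-output tracking,
    parallel execution of independent nodes, and publication of the
    executed pipeline as a hypertext protocol with per-node provenance
    and whole-pipeline statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    parallel,
    rlang,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
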