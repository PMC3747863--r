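# Deterministic example pipelines and a naive reference executor. The
# generated node functions are pure and tag their output with their own
# label, input values and body variant, so any caching, ordering or
# invalidation bug shows up in the resource value itself.

#' Generate the three-node string-passing example pipeline
#'
#' Builds the classic demonstration pipeline: `first_task` passes a text
#' string to `second_task` and `third_task`, which each append a distinct
#' suffix. The node functions (and a `pipeline` LGL string) are written to
#' an R source file so the fixture can be used with [lgl_project()] and the
#' command line alike, and so tests can edit node sources on disk.
#'
#' @param dir Directory to create the fixture in (created if needed).
#' @param greeting The string emitted by `first_task`.
#' @param suffixes Named character vector of suffixes for the two leaves.
#' @return An object of class `lgl_fixture`: list with `lgl` (the pipeline
#'   text), `source` (path of the generated R file), `dir`, and `expected`
#'   (named list of every node's expected resource).
#' @export
make_string_pipeline <- function(dir = tempfile("lglfix-"),
                                 greeting = "hello",
                                 suffixes = c(second_task = "-2",
                                              third_task = "-3")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "nodes.R")
  write_string_pipeline(path, greeting = greeting, suffixes = suffixes)
  lgl <- sprintf("first_task -> %s;", paste(names(suffixes), collapse = ", "))
  expected <- c(list(first_task = greeting),
                stats::setNames(as.list(paste0(greeting, suffixes)),
                                names(suffixes)))
  structure(list(lgl = lgl, source = path, dir = dir, expected = expected,
                 seed = NULL),
            class = "lgl_fixture")
}

#' Write (or rewrite) the string-pipeline node source file
#'
#' Rewriting with a different `greeting` or suffix is how tests emulate the
#' user editing a node's implementation between sessions.
#'
#' @param path File to write.
#' @inheritParams make_string_pipeline
#' @return `path`, invisibly.
#' @export
write_string_pipeline <- function(path, greeting = "hello",
                                  suffixes = c(second_task = "-2",
                                               third_task = "-3")) {
  lines <- c(
    sprintf("pipeline <- \"first_task -> %s;\"",
            paste(names(suffixes), collapse = ", ")),
    "",
    "first_task <- function() {",
    "  # Emits the text string shared by all downstream tasks.",
    sprintf("  \"%s\"", greeting),
    "}"
  )
  for (nm in names(suffixes)) {
    lines <- c(lines, "",
               sprintf("%s <- function(x) {", nm),
               sprintf("  # Appends the '%s' suffix to its input.", suffixes[[nm]]),
               sprintf("  paste0(x, \"%s\")", suffixes[[nm]]),
               "}")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Generate a random DAG pipeline
#'
#' Nodes are ranked `tsk1 .. tskN` and an edge `tski -> tskj` is drawn with
#' probability `p` for every `i < j`, so the result is acyclic by
#' construction. The pipeline is emitted in the edge-list LGL style (one
#' statement per edge, isolated nodes as bare statements) and each node
#' function deterministically combines its inputs into a string of the form
#' `"tskK.vV(in1,in2)"`. The same seed always yields the same pipeline and
#' the same outputs.
#'
#' @param n Number of nodes (>= 1).
#' @param p Edge probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param dir Directory for the generated source file.
#' @param variants Optional named integer vector (label -> body variant).
#'   Regenerating with a bumped variant changes that node's source and its
#'   output, emulating a code edit.
#' @return An `lgl_fixture` (see [make_string_pipeline()]).
#' @export
random_dag <- function(n, p = 0.3, seed = 1L, dir = tempfile("lgldag-"),
                       variants = NULL) {
  stopifnot(n >= 1, p >= 0, p <= 1)
  labels <- paste0("tsk", seq_len(n))
  edges <- local_seed(seed, {
    from <- character(0)
    to <- character(0)
    if (n > 1) {
      for (i in seq_len(n - 1L)) {
        for (j in seq((i + 1L), n)) {
          if (stats::runif(1) < p) {
            from <- c(from, labels[[i]])
            to <- c(to, labels[[j]])
          }
        }
      }
    }
    list(from = from, to = to)
  })
  isolated <- setdiff(labels, c(edges$from, edges$to))
  lgl <- c(sprintf("%s -> %s;", edges$from, edges$to),
           sprintf("%s;", isolated))
  lgl <- paste(lgl, collapse = "\n")

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "nodes.R")
  lines <- c(sprintf("pipeline <- \"%s\"", gsub("\n", " ", lgl)))
  for (lab in labels) {
    k <- sum(edges$to == lab)
    v <- if (!is.null(variants) && lab %in% names(variants)) {
      as.integer(variants[[lab]])
    } else 1L
    args <- if (k > 0) paste0("a", seq_len(k)) else character(0)
    body <- if (k > 0) {
      sprintf("  paste0(\"%s.v%d(\", paste(c(%s), collapse = \",\"), \")\")",
              lab, v, paste(args, collapse = ", "))
    } else {
      sprintf("  \"%s.v%d()\"", lab, v)
    }
    lines <- c(lines, "",
               sprintf("%s <- function(%s) {", lab, paste(args, collapse = ", ")),
               sprintf("  # synthetic processor %s, body variant %d", lab, v),
               body,
               "}")
  }
  writeLines(lines, path)
  structure(list(lgl = lgl, source = path, dir = dir, expected = NULL,
                 seed = seed),
            class = "lgl_fixture")
}

local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Naive reference executor
#'
#' Executes every node of a pipeline exactly once, in topological order,
#' with no caching, no persistence and no laziness — the ground truth that
#' the engine's lazily cached results are checked against.
#'
#' @param x An `lgl_fixture`, or LGL text.
#' @param functions Optional environment or named list of node functions;
#'   defaults to the fixture's generated source file.
#' @return Named list, node label -> resource, for every node.
#' @export
naive_execute <- function(x, functions = NULL) {
  if (inherits(x, "lgl_fixture")) {
    lgl <- x$lgl
    if (is.null(functions)) functions <- x$source
  } else {
    lgl <- x
  }
  env <- load_node_source(functions)$env
  g <- pipeline_graph(lgl_evaluate(lgl))
  chk <- validate_dag(g)
  if (!chk$ok) {
    stop_lgl_eval(sprintf("cannot execute a cyclic graph (%s)",
                          paste(chk$cycle, collapse = " -> ")))
  }
  out <- list()
  for (uid in topo_order(g)) {
    lab <- g$nodes[[uid]]$label
    fn <- get(lab, envir = env, inherits = TRUE)
    args <- lapply(parents_of(g, uid), function(pu) out[[pu]])
    out[[uid]] <- do.call(fn, args)
  }
  stats::setNames(out, unname(node_labels(g)[names(out)]))
}
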