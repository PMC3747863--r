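#' Create an executable pipeline protocol
#'
#' Binds the nodes of an LGL pipeline graph to same-named R functions and
#' returns the protocol object through which resources are requested
#' ([provide()], [run_pipeline()]), inspected ([list_states()],
#' [node_runs()]) and invalidated ([detect_code_changes()], [trust()],
#' [untrust()]).
#'
#' Binding is by name: every node label must resolve to exactly one function
#' with the same name in `source`, and a node with N incoming edges must be
#' bound to a function accepting N arguments (functions with `...` accept
#' any arity). The graph must be a DAG.
#'
#' Prior session metadata found in `project_dir` is loaded, so a fresh
#' protocol over the same project directory reconstructs all resource states
#' without executing any node.
#'
#' @param source Where the node functions live: path to an R source file
#'   (sourced into a private environment with source references kept), an
#'   environment, or a named list of functions. When a file also defines a
#'   character scalar `pipeline`, that is used as the LGL text if `lgl` is
#'   missing.
#' @param lgl The pipeline definition: LGL text, an `lgl_program`, or `NULL`
#'   to take it from the `pipeline` variable of the source file.
#' @param project_dir Directory for caches and metadata (`metadata.json`,
#'   `resources/<uid>.blob`, `srcdb/<uid>.txt`). Defaults to a fresh
#'   temporary directory, which makes the project ephemeral.
#' @param graph Optional named-graph label selecting the pipeline when the
#'   LGL program defines several graphs (see [pipeline_graph()]).
#' @param workers Maximum number of parallel workers for independent nodes.
#' @param dumping Whether newly produced resources are also written to disk.
#' @return An object of class `lgl_protocol` (reference semantics: the
#'   engine operations mutate it in place).
#' @examples
#' fx <- make_string_pipeline()
#' pr <- lgl_project(fx$source)
#' provide(pr, "second_task")
#' @export
lgl_project <- function(source, lgl = NULL, project_dir = NULL, graph = NULL,
                        workers = 1L, dumping = TRUE) {
  src <- load_node_source(source)
  if (is.null(lgl)) {
    lgl <- src$pipeline_text
    if (is.null(lgl)) {
      stop("no LGL text: pass `lgl` or define a `pipeline` string in the source file")
    }
  }
  reg <- lgl_evaluate(lgl)
  g <- pipeline_graph(reg, name = graph)
  chk <- validate_dag(g)
  if (!chk$ok) {
    stop_lgl_eval(sprintf("pipeline graph is not a DAG; cycle: %s",
                          paste(chk$cycle, collapse = " -> ")))
  }
  if (is.null(project_dir)) {
    project_dir <- tempfile("lglpipe-project-")
  }
  dir.create(project_dir, recursive = TRUE, showWarnings = FALSE)

  p <- new.env(parent = emptyenv())
  class(p) <- "lgl_protocol"
  p$graph <- g
  p$registry <- reg
  p$source <- src
  p$project_dir <- project_dir
  p$dumping <- isTRUE(dumping)
  p$workers <- as.integer(workers)
  p$values <- new.env(parent = emptyenv()) # uid -> resource (RAM cache)
  p$records <- list()                      # uid -> metadata record
  p$runs <- integer(0)                     # uid -> executions this session
  bind_functions(p)
  load_metadata(p)
  p
}

#' @export
print.lgl_protocol <- function(x, ...) {
  cat("<lgl_protocol> ", length(x$graph$nodes), " nodes, ",
      nrow(x$graph$edges), " edges\n", sep = "")
  st <- list_states(x)
  for (i in seq_along(st)) {
    cat(sprintf("  %-24s %s\n", names(st)[[i]], st[[i]]))
  }
  invisible(x)
}

# -- node source ------------------------------------------------------------

load_node_source <- function(source) {
  if (is.character(source) && length(source) == 1L) {
    if (!file.exists(source)) stop(sprintf("source file not found: %s", source))
    env <- new.env(parent = globalenv())
    old <- options(keep.source = TRUE)
    on.exit(options(old))
    sys.source(source, envir = env, keep.source = TRUE)
    pip <- if (exists("pipeline", envir = env, inherits = FALSE) &&
               is.character(env$pipeline)) {
      paste(env$pipeline, collapse = "\n")
    }
    list(kind = "file", path = source, env = env, pipeline_text = pip)
  } else if (is.environment(source)) {
    list(kind = "env", path = NULL, env = source, pipeline_text = NULL)
  } else if (is.list(source)) {
    env <- list2env(source, parent = globalenv())
    list(kind = "env", path = NULL, env = env, pipeline_text = NULL)
  } else {
    stop("`source` must be a file path, an environment, or a named list of functions")
  }
}

fn_source_text <- function(fn) {
  ref <- attr(fn, "srcref")
  if (!is.null(ref)) {
    paste(as.character(ref), collapse = "\n")
  } else {
    paste(deparse(fn), collapse = "\n")
  }
}

fingerprint <- function(fn) rlang::hash(fn_source_text(fn))

bind_functions <- function(p) {
  g <- p$graph
  bindings <- list()
  fps <- character(0)
  for (node in g$nodes) {
    lab <- node$label
    if (!exists(lab, envir = p$source$env, inherits = FALSE) ||
        !is.function(get(lab, envir = p$source$env, inherits = FALSE))) {
      stop(sprintf("binding error: no function '%s' for pipeline node '%s'",
                   lab, lab))
    }
    fn <- get(lab, envir = p$source$env, inherits = FALSE)
    indeg <- length(parents_of(g, node$uid))
    fmls <- formals(fn)
    if (!"..." %in% names(fmls) && length(fmls) != indeg) {
      stop(sprintf(
        "binding error: node '%s' has %d incoming edge(s) but function '%s' takes %d argument(s)",
        lab, indeg, lab, length(fmls)))
    }
    bindings[[node$uid]] <- fn
    fps[[node$uid]] <- fingerprint(fn)
  }
  p$bindings <- bindings
  p$fp <- fps
  invisible(p)
}

# -- label/uid resolution ---------------------------------------------------

resolve_uid <- function(p, label) {
  if (label %in% names(p$graph$nodes)) return(label)
  labs <- node_labels(p$graph)
  hits <- names(labs)[labs == label]
  if (length(hits) == 0L) {
    stop(sprintf("unknown pipeline node '%s'", label))
  }
  if (length(hits) > 1L) {
    stop(sprintf("node label '%s' is ambiguous (%d instances); use a uid (%s)",
                 label, length(hits), paste(hits, collapse = ", ")))
  }
  hits
}

uid_label <- function(p, uid) p$graph$nodes[[uid]]$label

is_fnode <- function(p, uid) "F" %in% p$graph$nodes[[uid]]$flags

# -- persistence ------------------------------------------------------------

blob_path <- function(p, uid) {
  file.path(p$project_dir, "resources", paste0(uid, ".blob"))
}

srcdb_path <- function(p, uid) {
  file.path(p$project_dir, "srcdb", paste0(uid, ".txt"))
}

metadata_path <- function(p) file.path(p$project_dir, "metadata.json")

iso_time <- function(t) {
  format(as.POSIXct(t, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%OS6Z")
}

write_metadata <- function(p) {
  nodes <- lapply(p$records, function(r) {
    out <- list(
      label = r$label,
      fingerprint = r$fingerprint,
      dumped = isTRUE(r$dumped),
      failed = isTRUE(r$failed),
      cpu = r$cpu,
      wall = r$wall,
      last_build = r$last_build,
      last_build_iso = iso_time(r$last_build)
    )
    if (!is.null(r$files)) {
      out$files <- lapply(seq_len(nrow(r$files)), function(i) {
        list(path = r$files$path[[i]],
             mtime = r$files$mtime[[i]],
             mtime_iso = iso_time(r$files$mtime[[i]]),
             size = r$files$size[[i]])
      })
    }
    out
  })
  obj <- list(version = 1L, nodes = nodes)
  path <- metadata_path(p)
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  file.rename(tmp, path)
  invisible(NULL)
}

load_metadata <- function(p) {
  path <- metadata_path(p)
  if (!file.exists(path)) return(invisible(NULL))
  obj <- jsonlite::read_json(path)
  for (uid in names(obj$nodes)) {
    r <- obj$nodes[[uid]]
    if (!uid %in% names(p$graph$nodes)) next
    if (!identical(r$label, uid_label(p, uid))) next # layout changed
    files <- NULL
    if (!is.null(r$files)) {
      files <- data.frame(
        path = vapply(r$files, function(f) f$path, character(1)),
        mtime = vapply(r$files, function(f) as.numeric(f$mtime), numeric(1)),
        size = vapply(r$files, function(f) as.numeric(f$size), numeric(1)),
        stringsAsFactors = FALSE
      )
    }
    p$records[[uid]] <- list(
      label = r$label,
      fingerprint = r$fingerprint,
      dumped = isTRUE(r$dumped) && file.exists(blob_path(p, uid)),
      failed = isTRUE(r$failed),
      cpu = as.numeric(r$cpu),
      wall = as.numeric(r$wall),
      last_build = as.numeric(r$last_build),
      files = files
    )
  }
  invisible(NULL)
}

# -- resource states --------------------------------------------------------

resource_state <- function(p, uid) {
  r <- p$records[[uid]]
  if (!is.null(r) && isTRUE(r$failed)) return("unavailable")
  if (exists(uid, envir = p$values, inherits = FALSE)) return("available")
  if (!is.null(r) && isTRUE(r$dumped) && file.exists(blob_path(p, uid))) {
    return("dumped")
  }
  "to-be-built"
}

#' List the state of all resources
#'
#' @param protocol An `lgl_protocol`.
#' @return A named character vector, node label -> one of `"available"`
#'   (in RAM), `"dumped"` (on disk only), `"to-be-built"` (nothing cached),
#'   `"unavailable"` (last build failed).
#' @export
list_states <- function(protocol) {
  uids <- names(protocol$graph$nodes)
  stats::setNames(vapply(uids, resource_state, character(1), p = protocol),
                  unname(node_labels(protocol$graph)[uids]))
}

#' Per-node execution counters for the current session
#'
#' Counts how many times each node function has been executed by this
#' protocol object. Useful for verifying lazy processing: a cached node's
#' counter stays at zero.
#'
#' @param protocol An `lgl_protocol`.
#' @return Named integer vector, label -> executions.
#' @export
node_runs <- function(protocol) {
  uids <- names(protocol$graph$nodes)
  n <- vapply(uids, function(u) {
    if (u %in% names(protocol$runs)) protocol$runs[[u]] else 0L
  }, integer(1))
  stats::setNames(n, unname(node_labels(protocol$graph)[uids]))
}
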