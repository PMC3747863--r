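# Lazy execution, caching, invalidation and file tracking for lgl_protocol
# objects. A resource is considered valid when a record of it exists, the
# fingerprint of the code that produced it matches the current binding, a
# copy is reachable (RAM or disk blob), and — for F-nodes — every recorded
# output file still exists with its recorded modification timestamp.

cached_valid <- function(p, uid) {
  r <- p$records[[uid]]
  if (is.null(r) || isTRUE(r$failed)) return(FALSE)
  if (!identical(r$fingerprint, p$fp[[uid]])) return(FALSE)
  in_ram <- exists(uid, envir = p$values, inherits = FALSE)
  on_disk <- isTRUE(r$dumped) && file.exists(blob_path(p, uid))
  if (!in_ram && !on_disk) return(FALSE)
  if (is_fnode(p, uid) && !files_fresh(p, uid)$fresh) return(FALSE)
  TRUE
}

files_fresh <- function(p, uid) {
  r <- p$records[[uid]]
  if (is.null(r) || is.null(r$files) || nrow(r$files) == 0L) {
    return(list(fresh = TRUE, stale = character(0)))
  }
  stale <- character(0)
  for (i in seq_len(nrow(r$files))) {
    path <- r$files$path[[i]]
    if (!file.exists(path)) {
      stale <- c(stale, path)
    } else {
      now <- as.numeric(file.mtime(path))
      if (!isTRUE(abs(now - r$files$mtime[[i]]) < 1e-6)) {
        stale <- c(stale, path)
      }
    }
  }
  list(fresh = length(stale) == 0L, stale = stale)
}

#' Check an F-node's tracked output files
#'
#' A node flagged `F` returns the name(s) of the file(s) it produced; the
#' engine records each file's modification timestamp at build time. This
#' check reports whether every recorded file still exists with an unchanged
#' timestamp. Stale F-node resources are treated as invalid by [provide()]
#' and rebuilt, unless [trust()]ed after re-recording.
#'
#' @param protocol An `lgl_protocol`.
#' @param label Label of a node carrying the `F` flag.
#' @return List with `fresh` (logical) and `stale` (character vector of
#'   offending file paths).
#' @export
check_file_outputs <- function(protocol, label) {
  uid <- resolve_uid(protocol, label)
  if (!is_fnode(protocol, uid)) {
    stop(sprintf("node '%s' does not carry the F flag", label))
  }
  if (is.null(protocol$records[[uid]])) {
    stop(sprintf("node '%s' has no stored resource to check", label))
  }
  files_fresh(protocol, uid)
}

# -- scheduling -------------------------------------------------------------

needed_uids <- function(p, targets) {
  need <- new.env(parent = emptyenv())
  visit <- function(u) {
    if (exists(u, envir = need, inherits = FALSE)) return(invisible(NULL))
    if (cached_valid(p, u)) return(invisible(NULL))
    assign(u, TRUE, envir = need)
    for (parent in parents_of(p$graph, u)) visit(parent)
    invisible(NULL)
  }
  for (t in targets) visit(t)
  ls(need)
}

schedule_uids <- function(p, targets) {
  needed <- needed_uids(p, targets)
  if (length(needed) == 0L) return(list())
  order <- topo_order(p$graph)
  needed <- order[order %in% needed]
  level <- stats::setNames(rep(1L, length(needed)), needed)
  for (u in needed) {
    ps <- intersect(parents_of(p$graph, u), needed)
    if (length(ps)) level[[u]] <- max(level[ps]) + 1L
  }
  lapply(seq_len(max(level)), function(k) needed[level[needed] == k])
}

#' Execution plan for requested resources
#'
#' Computes the ordered waves of node executions that [provide()] would
#' perform: exactly the needed, non-cached ancestors of the requested nodes.
#' Within one wave no node depends on another, so waves are the engine's
#' units of parallelism; concatenated waves respect topological order.
#'
#' @param protocol An `lgl_protocol`.
#' @param labels Character vector of requested node labels.
#' @return List of character vectors of node labels (possibly empty).
#' @export
protocol_schedule <- function(protocol, labels) {
  targets <- vapply(labels, resolve_uid, character(1), p = protocol)
  waves <- schedule_uids(protocol, targets)
  lapply(waves, function(w) unname(node_labels(protocol$graph)[w]))
}

# -- execution --------------------------------------------------------------

get_value <- function(p, uid) {
  if (exists(uid, envir = p$values, inherits = FALSE)) {
    return(get(uid, envir = p$values, inherits = FALSE))
  }
  bp <- blob_path(p, uid)
  r <- p$records[[uid]]
  if (!is.null(r) && isTRUE(r$dumped) && file.exists(bp)) {
    val <- readRDS(bp)
    assign(uid, val, envir = p$values)
    return(val)
  }
  stop(sprintf("resource '%s' is not built", uid_label(p, uid)))
}

# Pure part of a node build, safe to run in a forked worker: call the bound
# function and time it. All bookkeeping stays in the parent process.
call_node <- function(fn, args) {
  cond <- NULL
  value <- NULL
  t <- system.time(
    value <- tryCatch(do.call(fn, args), error = function(e) {
      cond <<- e
      NULL
    })
  )
  list(ok = is.null(cond), value = value, cond = cond,
       cpu = unname(t[["user.self"]] + t[["sys.self"]]),
       wall = unname(t[["elapsed"]]))
}

record_success <- function(p, uid, res) {
  val <- res$value
  files <- NULL
  if (is_fnode(p, uid)) {
    if (!is.character(val)) {
      stop(sprintf(
        "F-node '%s' must return the name(s) of the file(s) it produced, got %s",
        uid_label(p, uid), class(val)[[1]]))
    }
    missing <- val[!file.exists(val)]
    if (length(missing)) {
      stop(sprintf("F-node '%s' reported files that do not exist: %s",
                   uid_label(p, uid), paste(missing, collapse = ", ")))
    }
    info <- file.info(val)
    files <- data.frame(path = val, mtime = as.numeric(info$mtime),
                        size = as.numeric(info$size), stringsAsFactors = FALSE)
  }
  assign(uid, val, envir = p$values)
  dumped <- FALSE
  if (isTRUE(p$dumping)) {
    dir.create(file.path(p$project_dir, "resources"), recursive = TRUE,
               showWarnings = FALSE)
    saveRDS(val, blob_path(p, uid))
    dumped <- TRUE
  }
  dir.create(file.path(p$project_dir, "srcdb"), recursive = TRUE,
             showWarnings = FALSE)
  writeLines(fn_source_text(p$bindings[[uid]]), srcdb_path(p, uid))
  p$records[[uid]] <- list(
    label = uid_label(p, uid),
    fingerprint = p$fp[[uid]],
    dumped = dumped,
    failed = FALSE,
    cpu = res$cpu,
    wall = res$wall,
    last_build = as.numeric(Sys.time()),
    files = files
  )
  bump_runs(p, uid)
  invisible(NULL)
}

record_failure <- function(p, uid) {
  if (exists(uid, envir = p$values, inherits = FALSE)) rm(list = uid, envir = p$values)
  p$records[[uid]] <- list(
    label = uid_label(p, uid),
    fingerprint = p$fp[[uid]],
    dumped = FALSE,
    failed = TRUE,
    cpu = 0, wall = 0,
    last_build = as.numeric(Sys.time()),
    files = NULL
  )
  bump_runs(p, uid)
  invisible(NULL)
}

bump_runs <- function(p, uid) {
  if (!uid %in% names(p$runs)) p$runs[[uid]] <- 0L
  p$runs[[uid]] <- p$runs[[uid]] + 1L
}

execute_plan <- function(p, waves, workers = NULL) {
  workers <- if (is.null(workers)) p$workers else as.integer(workers)
  failed_first <- NULL
  skip <- character(0)
  for (wave in waves) {
    wave <- setdiff(wave, skip)
    if (length(wave) == 0L) next
    # make sure every parent value sits in RAM before (possibly) forking
    for (u in wave) for (pu in parents_of(p$graph, u)) {
      if (!pu %in% skip) get_value(p, pu)
    }
    jobs <- lapply(wave, function(u) {
      args <- lapply(parents_of(p$graph, u), get_value, p = p)
      fn <- p$bindings[[u]]
      function() call_node(fn, args)
    })
    use_parallel <- workers > 1L && length(wave) > 1L &&
      .Platform$OS.type == "unix"
    results <- if (use_parallel) {
      parallel::mclapply(jobs, function(job) job(),
                         mc.cores = min(workers, length(wave)))
    } else {
      lapply(jobs, function(job) job())
    }
    for (i in seq_along(wave)) {
      u <- wave[[i]]
      res <- results[[i]]
      if (!is.list(res) || is.null(res$ok)) { # worker-level failure
        res <- list(ok = FALSE,
                    cond = simpleError(paste("worker failed for node",
                                             uid_label(p, u))))
      }
      if (isTRUE(res$ok)) {
        record_success(p, u, res)
      } else {
        record_failure(p, u)
        if (is.null(failed_first)) failed_first <- res$cond
        skip <- c(skip, u, descendants_of(p$graph, u))
      }
    }
    write_metadata(p)
  }
  if (!is.null(failed_first)) stop(failed_first)
  invisible(NULL)
}

# -- the Table-style API ----------------------------------------------------

#' Provide a resource
#'
#' Returns the resource produced by the named node: from RAM if available,
#' loaded from disk if dumped, built on the fly otherwise. Building is lazy:
#' only uncached nodes on paths from primary resources to the requested node
#' are executed, in dependency order, and every newly produced resource is
#' transparently stored in RAM and (when dumping is on) on disk. A node with
#' several incoming edges receives its ancestors' resources as arguments in
#' incoming-edge creation order; a node with several outgoing edges provides
#' the same resource along each edge.
#'
#' @param protocol An `lgl_protocol`.
#' @param label Node label (or uid).
#' @param workers Optional worker-count override for this call.
#' @return The node's resource.
#' @export
provide <- function(protocol, label, workers = NULL) {
  uid <- resolve_uid(protocol, label)
  execute_plan(protocol, schedule_uids(protocol, uid), workers = workers)
  get_value(protocol, uid)
}

#' Clear a resource, then provide it
#'
#' @inheritParams provide
#' @return The freshly built resource.
#' @export
rebuild <- function(protocol, label, workers = NULL) {
  uid <- resolve_uid(protocol, label)
  clear_resource(protocol, label)
  undump(protocol, label)
  provide(protocol, label, workers = workers)
}

#' Provide all final (leaf) resources
#'
#' Executes whatever part of the pipeline is still needed so that every
#' out-degree-0 node's resource is available, running independent ready
#' nodes in parallel when `workers > 1`. The final cache state is identical
#' to a sequential topological execution.
#'
#' @inheritParams provide
#' @return Named list, leaf label -> resource.
#' @export
run_pipeline <- function(protocol, workers = NULL) {
  leaves <- names(graph_leaves(protocol$graph))
  execute_plan(protocol, schedule_uids(protocol, leaves), workers = workers)
  stats::setNames(lapply(leaves, get_value, p = protocol),
                  unname(node_labels(protocol$graph)[leaves]))
}

#' Detect source-code changes and invalidate dependent resources
#'
#' Re-reads the node source (when the protocol was built from a file),
#' refreshes the bindings, and compares each stored resource's code
#' fingerprint with the current source. Every node whose producing code
#' changed — plus all its descendants — has its resource cleared from RAM
#' and disk, unless the user [trust()]s it first.
#'
#' @param protocol An `lgl_protocol`.
#' @return Character vector of invalidated node labels (empty when nothing
#'   changed).
#' @export
detect_code_changes <- function(protocol) {
  if (identical(protocol$source$kind, "file")) {
    protocol$source <- load_node_source(protocol$source$path)
  }
  bind_functions(protocol)
  changed <- character(0)
  for (uid in names(protocol$records)) {
    r <- protocol$records[[uid]]
    if (!identical(r$fingerprint, protocol$fp[[uid]])) {
      changed <- c(changed, uid)
    }
  }
  invalid <- unique(c(changed, descendants_of(protocol$graph, changed)))
  for (uid in invalid) drop_resource(protocol, uid)
  write_metadata(protocol)
  unname(node_labels(protocol$graph)[invalid])
}

drop_resource <- function(p, uid) {
  if (exists(uid, envir = p$values, inherits = FALSE)) {
    rm(list = uid, envir = p$values)
  }
  bp <- blob_path(p, uid)
  if (file.exists(bp)) unlink(bp)
  p$records[[uid]] <- NULL
  invisible(NULL)
}

#' Trust an existing resource despite a code change
#'
#' Assigns the node's stored resource to the current version of its source:
#' the stored fingerprint is updated so that [detect_code_changes()] no
#' longer invalidates it (or its dependents). The resource value itself and
#' all dependent resources are untouched.
#'
#' @param protocol An `lgl_protocol`.
#' @param label Node label.
#' @export
trust <- function(protocol, label) {
  uid <- resolve_uid(protocol, label)
  r <- protocol$records[[uid]]
  has_copy <- exists(uid, envir = protocol$values, inherits = FALSE) ||
    (!is.null(r) && isTRUE(r$dumped) && file.exists(blob_path(protocol, uid)))
  if (is.null(r) || !has_copy) {
    stop(sprintf("cannot trust '%s': no stored resource", label))
  }
  protocol$records[[uid]]$fingerprint <- protocol$fp[[uid]]
  protocol$records[[uid]]$failed <- FALSE
  dir.create(file.path(protocol$project_dir, "srcdb"), recursive = TRUE,
             showWarnings = FALSE)
  writeLines(fn_source_text(protocol$bindings[[uid]]),
             srcdb_path(protocol, uid))
  write_metadata(protocol)
  invisible(NULL)
}

#' Clear a resource and all its dependents
#'
#' Removes the node's resource and every descendant's resource from both RAM
#' and disk, forcing them to be rebuilt on the next request. Idempotent.
#'
#' @inheritParams trust
#' @export
untrust <- function(protocol, label) {
  uid <- resolve_uid(protocol, label)
  for (u in unique(c(uid, descendants_of(protocol$graph, uid)))) {
    drop_resource(protocol, u)
  }
  write_metadata(protocol)
  invisible(NULL)
}

#' Clear resources from RAM
#'
#' `clear_resource()` removes one node's RAM copy (the state falls back to
#' `dumped` when a disk blob exists); `clear_all()` does so for every node.
#' Clearing an absent resource is a no-op.
#'
#' @inheritParams trust
#' @export
clear_resource <- function(protocol, label) {
  uid <- resolve_uid(protocol, label)
  if (exists(uid, envir = protocol$values, inherits = FALSE)) {
    rm(list = uid, envir = protocol$values)
  }
  invisible(NULL)
}

#' @rdname clear_resource
#' @export
clear_all <- function(protocol) {
  rm(list = ls(protocol$values), envir = protocol$values)
  invisible(NULL)
}

#' Clear dumped resources from the disk
#'
#' `undump()` deletes one node's disk blob (the state falls back to
#' `available` when a RAM copy exists, else `to-be-built`); `undump_all()`
#' does so for every node.
#'
#' @inheritParams trust
#' @export
undump <- function(protocol, label) {
  uid <- resolve_uid(protocol, label)
  bp <- blob_path(protocol, uid)
  if (file.exists(bp)) unlink(bp)
  if (!is.null(protocol$records[[uid]])) {
    protocol$records[[uid]]$dumped <- FALSE
    if (!exists(uid, envir = protocol$values, inherits = FALSE)) {
      # no reachable copy left: the record no longer describes a resource
      protocol$records[[uid]] <- NULL
    }
    write_metadata(protocol)
  }
  invisible(NULL)
}

#' @rdname undump
#' @export
undump_all <- function(protocol) {
  for (uid in names(protocol$graph$nodes)) {
    bp <- blob_path(protocol, uid)
    if (file.exists(bp)) unlink(bp)
    if (!is.null(protocol$records[[uid]])) {
      protocol$records[[uid]]$dumped <- FALSE
      if (!exists(uid, envir = protocol$values, inherits = FALSE)) {
        protocol$records[[uid]] <- NULL
      }
    }
  }
  write_metadata(protocol)
  invisible(NULL)
}

#' Switch disk dumping on or off
#'
#' With dumping off, newly produced resources are kept in RAM only; metadata
#' is still persisted. Default is on.
#'
#' @param protocol An `lgl_protocol`.
#' @param enabled Logical.
#' @export
set_dumping <- function(protocol, enabled) {
  protocol$dumping <- isTRUE(enabled)
  invisible(NULL)
}

#' Collect a node's input resources
#'
#' Returns copies of each parent resource in argument (incoming-edge
#' creation) order, producing missing parents on the fly. The returned
#' values are deep copies: mutating them never changes the cached resources.
#'
#' @inheritParams trust
#' @return List of resource values (empty for a root node).
#' @export
getinputs <- function(protocol, label) {
  uid <- resolve_uid(protocol, label)
  parents <- parents_of(protocol$graph, uid)
  lapply(parents, function(pu) {
    execute_plan(protocol, schedule_uids(protocol, pu))
    unserialize(serialize(get_value(protocol, pu), NULL))
  })
}
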