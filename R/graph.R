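#' Evaluate LGL statements into graph objects
#'
#' Walks a parsed LGL program statement by statement and builds graph
#' objects. Semantics:
#'
#' * An item names a node; a comma-separated item set names several.
#'   Within one graph object a plain item reuses an existing node with the
#'   same label, otherwise it creates one.
#' * An arrow adds one edge per (source, target) pair; the comma binds
#'   tighter than the arrow, so `A -> B, C` yields edges `(A,B)` and `(A,C)`.
#' * A previously defined named-graph label used as an item is replaced by a
#'   fresh *copy* of that graph (new node instances); the arrow then targets
#'   the copy's roots (nodes with no incoming edges) or sources its leaves
#'   (no outgoing edges).
#' * An `@`-prefixed label refers to the stored graph object itself, which is
#'   extended in place instead of copied.
#' * Each statement without a label and without `@` references creates a new
#'   anonymous graph object; a labelled statement creates a named graph; a
#'   statement with `@` references extends the referenced graph.
#' * Forks (`<` with `/` and `\\` branches) connect a parent to each branch
#'   head; a void `.` branch head is elided so its children attach directly
#'   to the parent.
#' * Flags in square brackets (for example `B[F]`) are attached to the node
#'   and survive copying.
#'
#' @param x An `lgl_program` from [lgl_parse()], or LGL text.
#' @return An object of class `lgl_registry`: a list with element `graphs`,
#'   the graph objects in definition order. Each graph has class `lgl_graph`
#'   with fields `name` (or `NULL`), `nodes` (named list, uid ->
#'   `list(uid, label, flags)`) and `edges` (data.frame `from`, `to` of uids,
#'   in creation order).
#' @examples
#' reg <- lgl_evaluate("G1: A -> B, C; D -> @G1; @G1 -> D;")
#' length(reg$graphs)
#' @export
lgl_evaluate <- function(x) {
  if (is.character(x)) x <- lgl_parse(x)
  stopifnot(inherits(x, "lgl_program"))
  R <- new.env(parent = emptyenv())
  R$graphs <- list()
  R$named <- integer(0) # label -> index into R$graphs
  R$uid <- 0L
  for (s in x) eval_statement(s, R)
  graphs <- lapply(R$graphs, finalize_graph)
  structure(list(graphs = graphs), class = "lgl_registry")
}

new_uid <- function(R) {
  R$uid <- R$uid + 1L
  sprintf("n%d", R$uid)
}

new_graph_env <- function(name) {
  g <- new.env(parent = emptyenv())
  g$name <- name
  g$nodes <- list()            # uid -> list(uid, label, flags)
  g$node_by_label <- character(0)
  g$edges_from <- character(0)
  g$edges_to <- character(0)
  g
}

finalize_graph <- function(g) {
  structure(
    list(name = g$name,
         nodes = g$nodes,
         edges = data.frame(from = g$edges_from, to = g$edges_to,
                            stringsAsFactors = FALSE)),
    class = "lgl_graph"
  )
}

collect_refs <- function(chain) {
  out <- list()
  walk_operand <- function(op) {
    for (it in op$items) {
      if (isTRUE(it$is_ref)) out[[length(out) + 1L]] <<- it
    }
    if (!is.null(op$fork)) for (b in op$fork$branches) walk_operand(b)
  }
  for (op in chain$operands) walk_operand(op)
  out
}

eval_statement <- function(s, R) {
  refs <- collect_refs(s$chain)
  if (!is.null(s$label)) {
    if (length(refs)) {
      stop_lgl_eval("a named graph definition cannot contain '@' references",
                    refs[[1]]$line)
    }
    if (s$label %in% names(R$named)) {
      stop_lgl_eval(sprintf("graph '%s' is already defined", s$label), s$line)
    }
    g <- new_graph_env(s$label)
    eval_chain(s$chain, g, R)
    R$graphs[[length(R$graphs) + 1L]] <- g
    R$named[[s$label]] <- length(R$graphs)
  } else if (length(refs)) {
    targets <- unique(vapply(refs, `[[`, character(1), "name"))
    if (length(targets) > 1L) {
      stop_lgl_eval(sprintf("one statement references several graphs (%s)",
                            paste(targets, collapse = ", ")), refs[[1]]$line)
    }
    if (!targets %in% names(R$named)) {
      stop_lgl_eval(sprintf("undefined reference '@%s'", targets),
                    refs[[1]]$line)
    }
    g <- R$graphs[[R$named[[targets]]]]
    # an @reference denotes the graph as it stood when the statement began;
    # nodes added by the statement itself are not part of its roots/leaves
    g$ref_snapshot <- names(g$nodes)
    eval_chain(s$chain, g, R)
    g$ref_snapshot <- NULL
  } else {
    g <- new_graph_env(NULL)
    eval_chain(s$chain, g, R)
    R$graphs[[length(R$graphs) + 1L]] <- g
  }
  invisible(NULL)
}

eval_chain <- function(chain, g, R) {
  val <- eval_operand(chain$operands[[1]], g, R)
  for (i in seq_along(chain$arrows)) {
    nxt <- eval_operand(chain$operands[[i + 1L]], g, R)
    if (chain$arrows[[i]] == "right") {
      add_edges(g, val$src, nxt$dst)
    } else {
      add_edges(g, nxt$src, val$dst)
    }
    val <- nxt
  }
  val
}

# An operand's value is its pair of endpoint sets: `src` (used when the
# operand is an arrow source) and `dst` (arrow target). For plain items both
# are the node itself; for graph copies/references they are the (sub)graph's
# leaves and roots, snapshotted when the operand is evaluated.
eval_operand <- function(op, g, R) {
  src <- character(0)
  dst <- character(0)
  for (it in op$items) {
    if (isTRUE(it$is_void)) {
      stop_lgl_eval("the void item '.' is only allowed as a fork branch head",
                    it$line)
    }
    if (isTRUE(it$is_ref)) {
      # working graph g is the referenced graph by construction
      uids <- if (is.null(g$ref_snapshot)) names(g$nodes) else g$ref_snapshot
      src <- c(src, sub_leaves(g, uids))
      dst <- c(dst, sub_roots(g, uids))
    } else if (it$name %in% names(R$named)) {
      cp <- copy_graph_into(g, R$graphs[[R$named[[it$name]]]], R)
      src <- c(src, sub_leaves(g, cp))
      dst <- c(dst, sub_roots(g, cp))
    } else {
      uid <- get_or_create_node(g, it$name, it$flags, R)
      src <- c(src, uid)
      dst <- c(dst, uid)
    }
  }
  if (!is.null(op$fork)) expand_fork(src, op$fork, g, R)
  list(src = unique(src), dst = unique(dst))
}

expand_fork <- function(parent_src, fork, g, R) {
  for (branch in fork$branches) {
    lone_void <- length(branch$items) == 1L && isTRUE(branch$items[[1]]$is_void)
    if (lone_void) {
      # elided head: children of the void attach directly to the parent
      if (!is.null(branch$fork)) expand_fork(parent_src, branch$fork, g, R)
    } else {
      head_only <- list(items = branch$items, fork = NULL)
      bval <- eval_operand(head_only, g, R)
      add_edges(g, parent_src, bval$dst)
      if (!is.null(branch$fork)) expand_fork(bval$src, branch$fork, g, R)
    }
  }
  invisible(NULL)
}

get_or_create_node <- function(g, label, flags, R) {
  uid <- g$node_by_label[label]
  if (is.na(uid)) {
    uid <- new_uid(R)
    g$nodes[[uid]] <- list(uid = uid, label = label, flags = unique(flags))
    g$node_by_label[[label]] <- uid
  } else if (length(flags)) {
    g$nodes[[uid]]$flags <- unique(c(g$nodes[[uid]]$flags, flags))
  }
  uid
}

# Paste a fresh copy of `src` (a graph env or finalized graph) into `g`,
# minting new uids. Returns the copied uids. Copied labels are registered for
# later plain-item reuse only where the label is not already taken.
copy_graph_into <- function(g, src, R) {
  src_nodes <- if (is.environment(src)) src$nodes else src$nodes
  src_from <- if (is.environment(src)) src$edges_from else src$edges$from
  src_to <- if (is.environment(src)) src$edges_to else src$edges$to
  map <- character(0)
  for (node in src_nodes) {
    uid <- new_uid(R)
    g$nodes[[uid]] <- list(uid = uid, label = node$label, flags = node$flags)
    map[[node$uid]] <- uid
    if (!node$label %in% names(g$node_by_label)) {
      g$node_by_label[[node$label]] <- uid
    }
  }
  for (i in seq_along(src_from)) {
    add_edges(g, map[[src_from[[i]]]], map[[src_to[[i]]]])
  }
  unname(map)
}

add_edges <- function(g, from, to) {
  for (f in from) for (t in to) {
    key <- paste(f, t, sep = "\r")
    if (!key %in% paste(g$edges_from, g$edges_to, sep = "\r")) {
      g$edges_from <- c(g$edges_from, f)
      g$edges_to <- c(g$edges_to, t)
    }
  }
  invisible(NULL)
}

sub_roots <- function(g, uids) {
  uids[!uids %in% edges_within(g, uids)$to]
}

sub_leaves <- function(g, uids) {
  uids[!uids %in% edges_within(g, uids)$from]
}

edges_within <- function(g, uids) {
  keep <- g$edges_from %in% uids & g$edges_to %in% uids
  list(from = g$edges_from[keep], to = g$edges_to[keep])
}

# -- public graph queries ---------------------------------------------------

#' Roots and leaves of a graph
#'
#' Roots are nodes with no incoming edges; leaves are nodes with no outgoing
#' edges. In a pipeline, roots are bound to primary-resource providers and
#' leaves produce the final resources.
#'
#' @param graph An `lgl_graph`.
#' @return A character vector of node labels, named by node uid.
#' @export
graph_roots <- function(graph) {
  node_subset(graph, setdiff(names(graph$nodes), graph$edges$to))
}

#' @rdname graph_roots
#' @export
graph_leaves <- function(graph) {
  node_subset(graph, setdiff(names(graph$nodes), graph$edges$from))
}

node_subset <- function(graph, uids) {
  labs <- vapply(graph$nodes[uids], `[[`, character(1), "label")
  stats::setNames(unname(labs), uids)
}

node_labels <- function(graph) {
  vapply(graph$nodes, `[[`, character(1), "label")
}

#' Check that a graph is a DAG
#'
#' LGL can express arbitrary directed graphs, including cyclic ones, but a
#' graph describing a data flow must be acyclic before it can be executed.
#'
#' @param graph An `lgl_graph`.
#' @return A list with `ok` (logical). When `ok` is `FALSE`, `cycle` holds
#'   one witnessing cycle as a character vector of node labels, first label
#'   repeated at the end.
#' @export
validate_dag <- function(graph) {
  uids <- names(graph$nodes)
  adj <- split(graph$edges$to, factor(graph$edges$from, levels = uids))
  color <- stats::setNames(rep(0L, length(uids)), uids) # 0 white 1 grey 2 black
  stack <- character(0)
  cycle <- NULL
  visit <- function(u) {
    color[[u]] <<- 1L
    stack <<- c(stack, u)
    for (v in adj[[u]]) {
      if (!is.null(cycle)) return(invisible(NULL))
      if (color[[v]] == 0L) {
        visit(v)
      } else if (color[[v]] == 1L) {
        start <- match(v, stack)
        cycle <<- c(stack[start:length(stack)], v)
      }
    }
    color[[u]] <<- 2L
    stack <<- stack[-length(stack)]
    invisible(NULL)
  }
  for (u in uids) {
    if (color[[u]] == 0L && is.null(cycle)) visit(u)
  }
  if (is.null(cycle)) {
    list(ok = TRUE)
  } else {
    list(ok = FALSE,
         cycle = unname(vapply(graph$nodes[cycle], `[[`, character(1), "label")))
  }
}

#' Topological order of a DAG
#'
#' @param graph An `lgl_graph` that passes [validate_dag()].
#' @return Character vector of uids in an order where every edge points
#'   forward. Ties are broken by node creation order (deterministic).
#' @keywords internal
topo_order <- function(graph) {
  uids <- names(graph$nodes)
  indeg <- stats::setNames(rep(0L, length(uids)), uids)
  for (t in graph$edges$to) indeg[[t]] <- indeg[[t]] + 1L
  out <- character(0)
  ready <- uids[indeg[uids] == 0L]
  while (length(ready)) {
    u <- ready[[1]]
    ready <- ready[-1]
    out <- c(out, u)
    for (i in which(graph$edges$from == u)) {
      v <- graph$edges$to[[i]]
      indeg[[v]] <- indeg[[v]] - 1L
      if (indeg[[v]] == 0L) ready <- c(ready, v)
    }
    ready <- ready[order(match(ready, uids))]
  }
  if (length(out) != length(uids)) {
    stop_lgl_eval("graph contains a cycle and has no topological order")
  }
  out
}

parents_of <- function(graph, uid) {
  graph$edges$from[graph$edges$to == uid] # in edge creation order
}

children_of <- function(graph, uid) {
  graph$edges$to[graph$edges$from == uid]
}

descendants_of <- function(graph, uids) {
  seen <- character(0)
  frontier <- uids
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, children_of, graph = graph)))
    nxt <- setdiff(nxt, c(seen, uids))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

ancestors_of <- function(graph, uids) {
  seen <- character(0)
  frontier <- uids
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, parents_of, graph = graph)))
    nxt <- setdiff(nxt, c(seen, uids))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# -- registry ---------------------------------------------------------------

#' Extract the executable pipeline graph from a registry
#'
#' A registry may hold several graph objects (named component graphs plus
#' anonymous ones). The pipeline is selected as follows: with `name`, the
#' named graph of that name; with a single graph in the registry, that graph;
#' otherwise all graphs are merged into one by unifying nodes with equal
#' labels (flags are unioned, edges deduplicated, creation order preserved).
#' The merge supports the edge-list coding style in which a pipeline is
#' written as one small statement per edge.
#'
#' @param registry An `lgl_registry` from [lgl_evaluate()].
#' @param name Optional named-graph label to select.
#' @return An `lgl_graph`.
#' @export
pipeline_graph <- function(registry, name = NULL) {
  stopifnot(inherits(registry, "lgl_registry"))
  graphs <- registry$graphs
  if (!is.null(name)) {
    for (g in graphs) if (identical(g$name, name)) return(g)
    stop_lgl_eval(sprintf("no named graph '%s' in registry", name))
  }
  if (length(graphs) == 0L) {
    return(structure(list(name = NULL, nodes = list(),
                          edges = data.frame(from = character(0),
                                             to = character(0),
                                             stringsAsFactors = FALSE)),
                     class = "lgl_graph"))
  }
  if (length(graphs) == 1L) return(graphs[[1]])
  nodes <- list()
  by_label <- character(0)
  uid_n <- 0L
  from <- character(0)
  to <- character(0)
  for (g in graphs) {
    map <- character(0)
    for (node in g$nodes) {
      uid <- by_label[node$label]
      if (is.na(uid)) {
        uid_n <- uid_n + 1L
        uid <- sprintf("p%d", uid_n)
        nodes[[uid]] <- list(uid = uid, label = node$label, flags = node$flags)
        by_label[[node$label]] <- uid
      } else if (length(node$flags)) {
        nodes[[uid]]$flags <- unique(c(nodes[[uid]]$flags, node$flags))
      }
      map[[node$uid]] <- uid
    }
    for (i in seq_along(g$edges$from)) {
      f <- map[[g$edges$from[[i]]]]
      t <- map[[g$edges$to[[i]]]]
      if (!any(from == f & to == t)) {
        from <- c(from, f)
        to <- c(to, t)
      }
    }
  }
  structure(list(name = NULL, nodes = nodes,
                 edges = data.frame(from = from, to = to,
                                    stringsAsFactors = FALSE)),
            class = "lgl_graph")
}

#' @export
print.lgl_registry <- function(x, ...) {
  cat("<lgl_registry> ", length(x$graphs), " graph(s)\n", sep = "")
  for (g in x$graphs) {
    nm <- if (is.null(g$name)) "<anonymous>" else g$name
    cat("  ", nm, ": ", length(g$nodes), " nodes, ",
        nrow(g$edges), " edges\n", sep = "")
  }
  invisible(x)
}

#' @export
print.lgl_graph <- function(x, ...) {
  nm <- if (is.null(x$name)) "<anonymous>" else x$name
  cat("<lgl_graph> ", nm, ": ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  labs <- node_labels(x)
  for (i in seq_len(nrow(x$edges))) {
    cat("  ", labs[[x$edges$from[[i]]]], " -> ", labs[[x$edges$to[[i]]]],
        "\n", sep = "")
  }
  invisible(x)
}

# -- export -----------------------------------------------------------------

#' Export a graph as Graphviz DOT text
#'
#' Nodes flagged `F` (file-producing processors) are drawn with straight
#' corners (`shape=box`); other nodes are ellipses. Node identifiers in the
#' DOT source are uids so duplicate labels stay distinct, while the displayed
#' label is the node label.
#'
#' @param graph An `lgl_graph`.
#' @param docs Optional named character vector (label -> one-line
#'   description) rendered as node tooltips.
#' @return A single string of DOT source.
#' @export
graph_to_dot <- function(graph, docs = NULL) {
  lines <- c("digraph pipeline {", "  rankdir=LR;")
  for (node in graph$nodes) {
    shape <- if ("F" %in% node$flags) "box" else "ellipse"
    attrs <- sprintf("label=\"%s\", shape=%s", dot_escape(node$label), shape)
    if (!is.null(docs) && node$label %in% names(docs) &&
        nzchar(docs[[node$label]])) {
      attrs <- paste0(attrs, sprintf(", tooltip=\"%s\"",
                                     dot_escape(docs[[node$label]])))
    }
    lines <- c(lines, sprintf("  \"%s\" [%s];", node$uid, attrs))
  }
  for (i in seq_len(nrow(graph$edges))) {
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\";",
                              graph$edges$from[[i]], graph$edges$to[[i]]))
  }
  paste(c(lines, "}"), collapse = "\n")
}

dot_escape <- function(x) gsub("\"", "\\\\\"", x)

#' Export a graph as JSON
#'
#' The machine-readable compiler output: nodes with uid, label and flags,
#' plus the ordered edge list.
#'
#' @param graph An `lgl_graph`.
#' @param path Optional file path; when given the JSON is written there and
#'   the path returned invisibly.
#' @return JSON text (class `json`), or the path when `path` is given.
#' @export
graph_to_json <- function(graph, path = NULL) {
  obj <- list(
    name = graph$name,
    nodes = lapply(unname(graph$nodes), function(n) {
      list(uid = n$uid, label = n$label, flags = as.list(n$flags))
    }),
    edges = lapply(seq_len(nrow(graph$edges)), function(i) {
      list(from = graph$edges$from[[i]], to = graph$edges$to[[i]])
    })
  )
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null")
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null")
    invisible(path)
  }
}
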