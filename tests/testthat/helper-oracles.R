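# Independent oracles and small utilities shared by the tests. These stay
# deliberately naive (path enumeration, full recomputation) so they never
# share code paths with the implementation they check.

# edges of a graph as "from->to" label strings, order-free comparisons
edge_set <- function(g) {
  labs <- sapply(g$nodes, function(n) n$label)
  if (nrow(g$edges) == 0) return(character(0))
  sort(paste0(unname(labs[g$edges$from]), "->", unname(labs[g$edges$to])))
}

label_set <- function(g) sort(unname(sapply(g$nodes, function(n) n$label)))

# strip source line numbers for AST equality
strip_lines <- function(x) {
  if (is.list(x)) {
    x$line <- NULL
    x <- lapply(x, strip_lines)
  }
  x
}

ast_equal <- function(a, b) {
  identical(strip_lines(unclass(a)), strip_lines(unclass(b)))
}

# brute-force cycle detection: boolean transitive closure (Warshall);
# a cycle exists iff some node reaches itself
brute_force_cyclic <- function(g) {
  uids <- names(g$nodes)
  n <- length(uids)
  if (n == 0) return(FALSE)
  reach <- matrix(FALSE, n, n, dimnames = list(uids, uids))
  for (i in seq_len(nrow(g$edges))) {
    reach[g$edges$from[[i]], g$edges$to[[i]]] <- TRUE
  }
  for (k in uids) for (i in uids) for (j in uids) {
    if (reach[i, k] && reach[k, j]) reach[i, j] <- TRUE
  }
  any(diag(reach))
}

# descendant closure by reachability on labels (for invalidation checks)
descendant_closure <- function(g, labels) {
  labs <- sapply(g$nodes, function(n) n$label)
  uids <- names(labs)[labs %in% labels]
  reach <- uids
  repeat {
    step <- unique(g$edges$to[g$edges$from %in% reach])
    new <- setdiff(step, reach)
    if (length(new) == 0) break
    reach <- c(reach, new)
  }
  sort(unname(labs[reach]))
}

# random directed graph (cycles allowed) built through the LGL edge-list
# style; returns the merged pipeline graph
random_digraph <- function(n, p, seed) {
  set.seed(seed)
  labels <- paste0("x", seq_len(n))
  stmts <- character(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && runif(1) < p) {
      stmts <- c(stmts, sprintf("%s -> %s;", labels[[i]], labels[[j]]))
    }
  }
  stmts <- c(stmts, paste0(labels, ";"))
  pipeline_graph(lgl_evaluate(paste(stmts, collapse = "\n")))
}

# recursive expansion oracle for fork trees written as nested lists:
# list(parent, child, child, ...) where a child is a label or another list
fork_tree_edges <- function(tree) {
  out <- character(0)
  walk <- function(t) {
    parent <- t[[1]]
    for (child in t[-1]) {
      head <- if (is.list(child)) child[[1]] else child
      out <<- c(out, paste0(parent, "->", head))
      if (is.list(child)) walk(child)
    }
  }
  walk(tree)
  sort(out)
}

expect_edges <- function(g, expected) {
  expect_setequal(edge_set(g), expected)
}

new_project_dir <- function() {
  d <- tempfile("lgltest-proj-")
  dir.create(d, recursive = TRUE)
  d
}
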