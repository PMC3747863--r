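# Publishing an executed pipeline as a hypertext bioinformatic protocol:
# whole-pipeline statistics, one detail page per node (source code, docs,
# timings, produced files) and a clickable pipeline map.

#' Format seconds as `HH:MM:SS.cc`
#'
#' @param seconds Non-negative number of CPU seconds.
#' @return A string like `"03:02:15.25"`.
#' @export
format_hms <- function(seconds) {
  seconds <- max(0, seconds)
  h <- floor(seconds / 3600)
  m <- floor((seconds - h * 3600) / 60)
  s <- seconds - h * 3600 - m * 60
  sprintf("%02d:%02d:%05.2f", as.integer(h), as.integer(m), s)
}

#' Format a byte count with binary prefixes
#'
#' @param bytes Non-negative number of bytes.
#' @return A string like `"2.32G"`; plain integer below 1024 bytes.
#' @export
format_bytes <- function(bytes) {
  units <- c("K", "M", "G", "T", "P")
  if (bytes < 1024) return(format(as.integer(round(bytes))))
  v <- bytes
  u <- 0L
  while (v >= 1024 && u < length(units)) {
    v <- v / 1024
    u <- u + 1L
  }
  sprintf("%.2f%s", v, units[[u]])
}

# Leading comment block inside a function body, the R rendering of a
# docstring: lines starting with '#' immediately after `function(...) {`.
extract_node_doc <- function(fn) {
  lines <- strsplit(fn_source_text(fn), "\n", fixed = TRUE)[[1]]
  open <- grep("\\{", lines)
  if (length(open) == 0L) return(character(0))
  doc <- character(0)
  for (ln in lines[-seq_len(open[[1]])]) {
    if (grepl("^\\s*#", ln)) {
      doc <- c(doc, sub("^\\s*#+\\s?", "", ln))
    } else if (grepl("^\\s*$", ln) && length(doc) == 0L) {
      next
    } else {
      break
    }
  }
  doc
}

node_doc_first_line <- function(fn) {
  doc <- extract_node_doc(fn)
  if (length(doc)) doc[[1]] else ""
}

#' Whole-pipeline and per-node statistics
#'
#' Computes the statistics block of the published protocol: node counts,
#' output-file counts and total size (file sizes are re-measured at call
#' time), and total CPU time, plus a per-node table with the description
#' (first line of the node's leading comment block), output files, last
#' build time and required CPU time. Unbuilt nodes contribute zero time and
#' files.
#'
#' @param protocol An `lgl_protocol`.
#' @return An object of class `lgl_protocol_stats` with fields `n_nodes`,
#'   `n_fnodes`, `n_files`, `total_bytes`, `total_bytes_h`, `total_cpu`,
#'   `total_cpu_hms` and `per_node` (a data.frame).
#' @export
protocol_statistics <- function(protocol) {
  g <- protocol$graph
  uids <- names(g$nodes)
  rows <- lapply(uids, function(u) {
    r <- protocol$records[[u]]
    files <- if (!is.null(r)) r$files
    sizes <- 0
    paths <- character(0)
    if (!is.null(files) && nrow(files)) {
      paths <- files$path
      sizes <- ifelse(file.exists(paths),
                      as.numeric(file.info(paths)$size), files$size)
    }
    cpu <- if (!is.null(r) && !isTRUE(r$failed)) r$cpu else 0
    data.frame(
      label = uid_label(protocol, u),
      description = node_doc_first_line(protocol$bindings[[u]]),
      n_files = length(paths),
      bytes = sum(sizes),
      files = paste(basename(paths), collapse = ", "),
      last_build = if (!is.null(r)) {
        format(as.POSIXct(r$last_build, origin = "1970-01-01"),
               "%a %b %e %H:%M:%S %Y")
      } else "",
      cpu = cpu,
      cpu_hms = format_hms(cpu),
      stringsAsFactors = FALSE
    )
  })
  per_node <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(label = character(0), description = character(0),
               n_files = integer(0), bytes = numeric(0), files = character(0),
               last_build = character(0), cpu = numeric(0),
               cpu_hms = character(0), stringsAsFactors = FALSE)
  }
  structure(list(
    n_nodes = length(uids),
    n_fnodes = sum(vapply(uids, is_fnode, logical(1), p = protocol)),
    n_files = sum(per_node$n_files),
    total_bytes = sum(per_node$bytes),
    total_bytes_h = format_bytes(sum(per_node$bytes)),
    total_cpu = sum(per_node$cpu),
    total_cpu_hms = format_hms(sum(per_node$cpu)),
    per_node = per_node
  ), class = "lgl_protocol_stats")
}

#' @export
print.lgl_protocol_stats <- function(x, ...) {
  cat("Statistics for the entire analysis\n")
  cat(sprintf("  %-30s %s\n", "Number of nodes", x$n_nodes))
  cat(sprintf("  %-30s %s\n", "Number of F-nodes", x$n_fnodes))
  cat(sprintf("  %-30s %s\n", "Total number of output files", x$n_files))
  cat(sprintf("  %-30s %s\n", "Total size of output files", x$total_bytes_h))
  cat(sprintf("  %-30s %s\n", "Total CPU time required", x$total_cpu_hms))
  invisible(x)
}

# -- HTML publishing --------------------------------------------------------

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

protocol_css <- paste(
  "body{font-family:sans-serif;margin:2em;max-width:70em}",
  "table{border-collapse:collapse}",
  "td,th{border:1px solid #999;padding:.3em .6em;text-align:left}",
  "pre{background:#f4f4f4;padding:1em;overflow-x:auto}",
  "svg{border:1px solid #ccc;background:#fff}",
  ".state{font-style:italic}",
  sep = "\n")

node_page_name <- function(p) {
  labs <- node_labels(p$graph)
  if (anyDuplicated(labs)) {
    stats::setNames(paste0(names(labs), ".html"), names(labs))
  } else {
    stats::setNames(paste0(unname(labs), ".html"), names(labs))
  }
}

# Simple layered layout: column = longest path from a root, rows stacked in
# node order. Returns per-uid x/y of the top-left corner.
svg_layout <- function(g) {
  uids <- topo_order(g)
  level <- stats::setNames(rep(1L, length(uids)), uids)
  for (u in uids) {
    ps <- parents_of(g, u)
    if (length(ps)) level[[u]] <- max(level[ps]) + 1L
  }
  row <- integer(0)
  counts <- integer(max(level, 1L))
  for (u in names(g$nodes)) {
    counts[[level[[u]]]] <- counts[[level[[u]]]] + 1L
    row[[u]] <- counts[[level[[u]]]]
  }
  list(level = level, row = row,
       width = max(level, 1L) * 190L + 20L,
       height = max(counts, 1L) * 70L + 20L)
}

pipeline_svg <- function(p, pages) {
  g <- p$graph
  if (length(g$nodes) == 0L) {
    return("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"40\" height=\"40\"></svg>")
  }
  lay <- svg_layout(g)
  pos <- function(u) {
    c(x = (lay$level[[u]] - 1L) * 190L + 10L,
      y = (lay$row[[u]] - 1L) * 70L + 10L)
  }
  out <- sprintf(paste0(
    "<svg xmlns=\"http://www.w3.org/2000/svg\" ",
    "xmlns:xlink=\"http://www.w3.org/1999/xlink\" ",
    "width=\"%d\" height=\"%d\">"), lay$width, lay$height)
  for (i in seq_len(nrow(g$edges))) {
    a <- pos(g$edges$from[[i]])
    b <- pos(g$edges$to[[i]])
    out <- c(out, sprintf(
      "<line x1=\"%d\" y1=\"%d\" x2=\"%d\" y2=\"%d\" stroke=\"#555\"/>",
      a[["x"]] + 160L, a[["y"]] + 25L, b[["x"]], b[["y"]] + 25L))
  }
  for (node in g$nodes) {
    xy <- pos(node$uid)
    rx <- if ("F" %in% node$flags) 0L else 12L # straight corners: file producer
    out <- c(out, sprintf(paste0(
      "<a xlink:href=\"nodes/%s\"><rect x=\"%d\" y=\"%d\" width=\"160\" ",
      "height=\"50\" rx=\"%d\" fill=\"#eef\" stroke=\"#336\"/>",
      "<text x=\"%d\" y=\"%d\" text-anchor=\"middle\">%s</text></a>"),
      pages[[node$uid]], xy[["x"]], xy[["y"]], rx,
      xy[["x"]] + 80L, xy[["y"]] + 30L, html_escape(node$label)))
  }
  paste(c(out, "</svg>"), collapse = "\n")
}

#' Publish the pipeline as a hypertext protocol
#'
#' Writes a static, dependency-free HTML tree: `index.html` with the
#' whole-pipeline statistics and a clickable pipeline map (one hyperlink per
#' node), and `nodes/<label>.html` detail pages with each processor's
#' description, source code, execution time, and links to the files it
#' produced together with their sizes. Publishing does not mutate the
#' protocol's metadata, and republishing an unchanged protocol is
#' byte-identical.
#'
#' @param protocol An `lgl_protocol`.
#' @param out_dir Output directory (created if needed).
#' @return Path of the index document, invisibly.
#' @export
publish_html <- function(protocol, out_dir) {
  dir.create(file.path(out_dir, "nodes"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create '%s'", out_dir))
  g <- protocol$graph
  stats <- protocol_statistics(protocol)
  pages <- node_page_name(protocol)
  states <- vapply(names(g$nodes), resource_state, character(1), p = protocol)

  stat_rows <- sprintf("<tr><td>%s</td><td>%s</td></tr>",
    c("Number of nodes", "Number of F-nodes", "Total number of output files",
      "Total size of output files", "Total CPU time required"),
    c(stats$n_nodes, stats$n_fnodes, stats$n_files, stats$total_bytes_h,
      stats$total_cpu_hms))
  node_rows <- vapply(seq_along(g$nodes), function(i) {
    u <- names(g$nodes)[[i]]
    pn <- stats$per_node[stats$per_node$label == uid_label(protocol, u), ][1, ]
    sprintf(paste0("<tr><td><a href=\"nodes/%s\">%s</a></td><td>%s</td>",
                   "<td class=\"state\">%s</td><td>%s</td><td>%s</td></tr>"),
            pages[[u]], html_escape(uid_label(protocol, u)),
            html_escape(pn$description), states[[u]],
            html_escape(pn$last_build), pn$cpu_hms)
  }, character(1))

  index <- c(
    "<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\"/>",
    "<title>Bioinformatic protocol</title>",
    sprintf("<style>%s</style></head><body>", protocol_css),
    "<h1>Bioinformatic protocol</h1>",
    "<h2>Pipeline</h2>",
    pipeline_svg(protocol, pages),
    "<h2>Statistics for the entire analysis</h2>",
    "<table>", stat_rows, "</table>",
    "<h2>Nodes</h2>",
    "<table><tr><th>Node</th><th>Description</th><th>State</th>",
    "<th>Last build time</th><th>Required CPU time</th></tr>",
    node_rows, "</table>",
    "</body></html>")
  writeLines(index, file.path(out_dir, "index.html"))

  for (u in names(g$nodes)) {
    r <- protocol$records[[u]]
    doc <- extract_node_doc(protocol$bindings[[u]])
    pn <- stats$per_node[stats$per_node$label == uid_label(protocol, u), ][1, ]
    file_items <- character(0)
    if (!is.null(r) && !is.null(r$files) && nrow(r$files)) {
      sizes <- ifelse(file.exists(r$files$path),
                      as.numeric(file.info(r$files$path)$size), r$files$size)
      file_items <- sprintf(
        "<li><a href=\"file://%s\">%s</a> (%s bytes, %s)</li>",
        html_escape(normalizePath(r$files$path, mustWork = FALSE)),
        html_escape(basename(r$files$path)),
        format(sizes, trim = TRUE, scientific = FALSE),
        vapply(sizes, format_bytes, character(1)))
    }
    page <- c(
      "<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\"/>",
      sprintf("<title>%s</title>", html_escape(uid_label(protocol, u))),
      sprintf("<style>%s</style></head><body>", protocol_css),
      sprintf("<p><a href=\"../index.html\">&#8592; protocol index</a></p>"),
      sprintf("<h1>%s</h1>", html_escape(uid_label(protocol, u))),
      if (length(doc)) c("<h2>Documentation</h2>",
                         sprintf("<p>%s</p>",
                                 html_escape(paste(doc, collapse = " ")))),
      sprintf("<p>State: <span class=\"state\">%s</span></p>", states[[u]]),
      sprintf("<p>Last build time: %s</p>", html_escape(pn$last_build)),
      sprintf("<p>Required CPU time: %s</p>", pn$cpu_hms),
      if (length(file_items)) c("<h2>Output files</h2>",
                                "<ul>", file_items, "</ul>"),
      "<h2>Source code</h2>",
      sprintf("<pre>%s</pre>",
              html_escape(fn_source_text(protocol$bindings[[u]]))),
      "</body></html>")
    writeLines(page[!vapply(page, is.null, logical(1))],
               file.path(out_dir, "nodes", pages[[u]]))
  }
  invisible(file.path(out_dir, "index.html"))
}

#' Export the pipeline graph for visualization
#'
#' Always writes Graphviz DOT text; when the external `dot` renderer is on
#' the `PATH` and `path` asks for another format (`.pdf`, `.svg`, `.png`),
#' rendering is delegated to it. With `include_docs`, each node's first
#' documentation line is attached as a tooltip. F-flagged nodes are drawn
#' with straight corners (boxes).
#'
#' @param protocol An `lgl_protocol`.
#' @param path Output path; extension selects the format.
#' @param include_docs Attach node documentation?
#' @return The path of the written file (the `.dot` file when no renderer
#'   is available, with a warning).
#' @export
export_graphics <- function(protocol, path, include_docs = FALSE) {
  docs <- NULL
  if (include_docs) {
    labs <- node_labels(protocol$graph)
    docs <- stats::setNames(
      vapply(names(labs), function(u) {
        node_doc_first_line(protocol$bindings[[u]])
      }, character(1)),
      unname(labs))
  }
  dot <- graph_to_dot(protocol$graph, docs = docs)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dot", "gv", "")) {
    writeLines(dot, path)
    return(path)
  }
  dot_path <- paste0(tools::file_path_sans_ext(path), ".dot")
  writeLines(dot, dot_path)
  renderer <- Sys.which("dot")
  if (!nzchar(renderer)) {
    warning(sprintf(
      "Graphviz 'dot' renderer not found; DOT source written to %s", dot_path))
    return(dot_path)
  }
  status <- system2(renderer, c(paste0("-T", ext), "-o", path, dot_path))
  if (!identical(status, 0L)) {
    warning(sprintf("dot renderer exited with status %s; DOT source at %s",
                    status, dot_path))
    return(dot_path)
  }
  path
}
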