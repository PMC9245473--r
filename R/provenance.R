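# Provenance reconstruction.
#
# Every artifact embeds, under provenance/, the metadata and action record of
# itself and of every ancestor artifact back to the initial import steps:
#
#   provenance/metadata.yaml            focal artifact's metadata (copy)
#   provenance/action/action.yaml       focal artifact's action record
#   provenance/citations.bib            focal artifact's citations
#   provenance/artifacts/<uuid>/...     one subtree per ancestor, same layout
#
# The ancestry forms a DAG: nodes are artifacts, a directed edge runs from
# each input artifact to the artifact that consumed it, labelled with the
# input parameter name.

KNOWN_ACTION_KINDS <- c("import", "method", "visualizer", "pipeline")

# Flatten YAML "list of single-pair mappings" (the action.yaml convention for
# inputs/parameters) into a named character vector preserving file order.
# A plain named mapping is tolerated too.
flatten_pairs <- function(x) {
  out <- character()
  if (is.null(x) || length(x) == 0L) return(out)
  if (!is.null(names(x))) x <- lapply(seq_along(x), function(i) x[i])
  for (pair in x) {
    for (nm in names(pair)) {
      v <- pair[[nm]]
      out[[nm]] <- if (is.null(v)) "null" else
        if (is.logical(v)) tolower(as.character(v)) else as.character(v)
    }
  }
  out
}

#' Parse a provenance action record
#'
#' Reads one `action.yaml` document: the step (import, method, visualizer, or
#' pipeline) that produced an artifact, the plugin and action names, the named
#' input artifacts (by UUID, order preserved), and the parameters rendered as
#' text. Unknown action kinds are kept verbatim with `kind_fallback = TRUE`
#' and treated like methods by downstream logic.
#'
#' @param text Contents of an `action.yaml` member.
#' @return A `qz_action` object with fields `action_kind`, `kind_fallback`,
#'   `plugin`, `action_name`, `inputs` (named character: parameter -> uuid),
#'   `parameters` (named character), `output_name`.
#' @export
qz_parse_action <- function(text) {
  y <- tryCatch(
    yaml::yaml.load(text),
    error = function(e) {
      qz_error("qz_provenance_error",
               sprintf("cannot parse action.yaml: %s", conditionMessage(e)))
    }
  )
  if (!is.list(y) || !is.list(y$action)) {
    qz_error("qz_provenance_error",
             "action.yaml has no top-level 'action' mapping")
  }
  a <- y$action
  kind <- if (is.null(a$type)) "method" else as.character(a$type)
  fallback <- !(kind %in% KNOWN_ACTION_KINDS)
  inputs <- flatten_pairs(a$inputs)
  inputs <- vapply(inputs, tolower, "")
  if (length(inputs)) {
    ok <- vapply(names(inputs), function(nm) is_uuid(inputs[[nm]]), TRUE)
    if (!all(ok)) {
      qz_error("qz_validation_error",
               sprintf("action input '%s' is not a valid UUID: '%s'",
                       names(inputs)[!ok][1L], inputs[!ok][1L]))
    }
  }
  if (identical(kind, "import") && length(inputs) > 0L) {
    qz_error("qz_validation_error",
             "an import action cannot have input artifacts")
  }
  structure(
    list(action_kind = kind, kind_fallback = fallback,
         plugin = if (is.null(a$plugin)) NA_character_ else as.character(a$plugin),
         action_name = if (is.null(a$action)) NA_character_ else as.character(a$action),
         inputs = inputs, parameters = flatten_pairs(a$parameters),
         output_name = if (is.null(a[["output-name"]])) NA_character_
                       else as.character(a[["output-name"]])),
    class = "qz_action"
  )
}

read_prov_node <- function(path, members, uuid, prefix, is_focal,
                           fallback_meta = NULL) {
  meta_member <- paste0(prefix, "metadata.yaml")
  meta <- if (zq_has_member(members, meta_member)) {
    qz_read_metadata(zq_read_text(path, meta_member))
  } else fallback_meta
  act_member <- paste0(prefix, "action/action.yaml")
  action <- if (zq_has_member(members, act_member)) {
    qz_parse_action(zq_read_text(path, act_member))
  } else NULL
  structure(
    list(uuid = uuid, metadata = meta, action = action, is_focal = is_focal),
    class = "qz_prov_node"
  )
}

# Kahn topological sort; ties broken by uuid lexicographic (C-locale) order.
topo_order <- function(uuids, edges) {
  indeg <- stats::setNames(integer(length(uuids)), uuids)
  for (v in edges$to) indeg[[v]] <- indeg[[v]] + 1L
  ready <- lex_sort(uuids[indeg == 0L])
  out <- character()
  while (length(ready) > 0L) {
    u <- ready[1L]
    ready <- ready[-1L]
    out <- c(out, u)
    for (v in unique(edges$to[edges$from == u])) {
      k <- sum(edges$from == u & edges$to == v)
      indeg[[v]] <- indeg[[v]] - k
      if (indeg[[v]] == 0L) ready <- lex_sort(c(ready, v))
    }
  }
  if (length(out) != length(uuids)) {
    qz_error("qz_validation_error", "provenance graph contains a cycle")
  }
  out
}

#' Reconstruct the provenance DAG of an artifact
#'
#' Builds the ancestry graph of an artifact from its embedded provenance
#' tree: one node for the focal artifact plus one per recorded ancestor, and
#' one labelled edge per action input (ancestor -> consumer). Input UUIDs
#' that have no corresponding ancestor subtree (truncated archives) become
#' stub nodes and attach a warning rather than failing. The constructed graph
#' is checked to be acyclic.
#'
#' @param artifact A `qz_artifact` or a path to one.
#' @return A `qz_provenance_graph`: `nodes` (named list of nodes), `edges`
#'   (data.frame `from`, `to`, `label`), `focal` (uuid), `order` (topological
#'   node order, ancestors first, ties by uuid), `warnings`.
#' @export
qz_build_graph <- function(artifact) {
  if (is.character(artifact)) artifact <- qz_load_artifact(artifact)
  stopifnot(inherits(artifact, "qz_artifact"))
  if (!artifact$has_provenance) {
    qz_error("qz_provenance_error",
             sprintf("artifact %s has no provenance tree", artifact$metadata$uuid))
  }
  path <- artifact$source_path
  members <- zq_members(path)
  root <- artifact$metadata$uuid
  warnings <- character()

  nodes <- list()
  nodes[[root]] <- read_prov_node(path, members, root,
                                  paste0(root, "/provenance/"),
                                  is_focal = TRUE,
                                  fallback_meta = artifact$metadata)

  anc_prefix <- paste0(root, "/provenance/artifacts/")
  under <- members[startsWith(members, anc_prefix)]
  anc_ids <- unique(sub("/.*$", "", substring(under, nchar(anc_prefix) + 1L)))
  anc_ids <- lex_sort(tolower(anc_ids[nzchar(anc_ids)]))
  for (a in anc_ids) {
    nodes[[a]] <- read_prov_node(path, members, a, paste0(anc_prefix, a, "/"),
                                 is_focal = FALSE)
  }

  edges <- data.frame(from = character(), to = character(), label = character(),
                      stringsAsFactors = FALSE)
  for (u in names(nodes)) {
    act <- nodes[[u]]$action
    if (is.null(act) || length(act$inputs) == 0L) next
    for (i in seq_along(act$inputs)) {
      src <- act$inputs[[i]]
      if (is.null(nodes[[src]])) {
        warnings <- c(warnings, sprintf(
          "dangling input reference %s (consumed by %s); stub node added",
          src, u))
        nodes[[src]] <- structure(
          list(uuid = src, metadata = NULL, action = NULL, is_focal = FALSE),
          class = "qz_prov_node")
      }
      edges <- rbind(edges, data.frame(from = src, to = u,
                                       label = names(act$inputs)[i],
                                       stringsAsFactors = FALSE))
    }
  }
  edges <- unique(edges)
  ord <- topo_order(names(nodes), edges)

  structure(
    list(nodes = nodes, edges = edges, focal = root, order = ord,
         warnings = warnings),
    class = "qz_provenance_graph"
  )
}

node_display <- function(node) {
  meta <- node$metadata
  type <- if (is.null(meta)) "?" else meta$semantic_type
  fmt <- if (is.null(meta) || is.na(meta$data_format)) "-" else meta$data_format
  act <- node$action
  kind <- if (is.null(act)) "-" else act$action_kind
  pa <- if (is.null(act) || is.na(act$plugin)) {
    if (!is.null(act) && !is.na(act$action_name)) act$action_name else "-"
  } else {
    paste0(act$plugin, ":",
           if (is.na(act$action_name)) "" else act$action_name)
  }
  c(type = type, format = fmt, kind = kind, plugin_action = pa)
}

#' Render a provenance graph as a terminal listing
#'
#' One tab-separated line per node in topological order (ancestors before
#' descendants, ties by uuid): uuid, semantic type, data format (or `-`),
#' action kind, plugin:action, and a `*` marker on the focal artifact. With
#' `verbose = TRUE`, action parameters are appended as indented lines.
#'
#' @param graph A `qz_provenance_graph`.
#' @param verbose Also print action parameters.
#' @return Character vector of lines.
#' @export
qz_render_listing <- function(graph, verbose = FALSE) {
  stopifnot(inherits(graph, "qz_provenance_graph"))
  lines <- character()
  for (u in graph$order) {
    node <- graph$nodes[[u]]
    d <- node_display(node)
    lines <- c(lines, paste(u, d[["type"]], d[["format"]], d[["kind"]],
                            d[["plugin_action"]],
                            if (node$is_focal) "*" else "", sep = "\t"))
    if (verbose && !is.null(node$action) && length(node$action$parameters)) {
      p <- node$action$parameters
      lines <- c(lines, sprintf("\t%s = %s", names(p), unname(p)))
    }
  }
  lines
}

dot_escape <- function(x) gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", x))

#' Emit a provenance graph as Graphviz DOT text
#'
#' Produces a deterministic DOT `digraph`: one node statement per artifact in
#' topological order (label: semantic type over the 8-character uuid prefix;
#' full uuid in the tooltip; the focal artifact filled), and one edge
#' statement per labelled input edge. The text can be fed to the external
#' `dot` program to render a PDF/SVG; rendering is never required here.
#'
#' @param graph A `qz_provenance_graph`.
#' @return A single string of DOT source (byte-deterministic per graph).
#' @export
qz_to_dot <- function(graph) {
  stopifnot(inherits(graph, "qz_provenance_graph"))
  lines <- c("digraph provenance {",
             '  rankdir="LR";',
             '  node [shape=box, style="rounded", fontname="Helvetica"];')
  for (u in graph$order) {
    node <- graph$nodes[[u]]
    d <- node_display(node)
    attrs <- sprintf('label="%s\\n%s", tooltip="%s"',
                     dot_escape(d[["type"]]), substr(u, 1L, 8L), u)
    if (node$is_focal) {
      attrs <- paste0(attrs, ', style="rounded,filled", fillcolor="lightgoldenrod1"')
    }
    lines <- c(lines, sprintf('  "%s" [%s];', u, attrs))
  }
  e <- graph$edges
  if (nrow(e) > 0L) {
    e <- e[order(match(e$from, graph$order), match(e$to, graph$order),
                 e$label), , drop = FALSE]
    lines <- c(lines, sprintf('  "%s" -> "%s" [label="%s"];',
                              e$from, e$to, dot_escape(e$label)))
  }
  paste0(paste(c(lines, "}"), collapse = "\n"), "\n")
}

#' @export
print.qz_provenance_graph <- function(x, ...) {
  cat(sprintf("<qz_provenance_graph> %d node(s), %d edge(s); focal %s\n",
              length(x$nodes), nrow(x$edges), x$focal))
  cat(qz_render_listing(x), sep = "\n")
  for (w in x$warnings) cat(sprintf("  warning: %s\n", w))
  invisible(x)
}
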