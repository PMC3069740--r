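# The derived provenance graph: samples feed experiments which produce
# samples; constructs derive the samples of their design experiment;
# targets back the constructs. Graphs are built as breadth-first
# neighborhoods around a centre entity and rendered as Graphviz DOT.

# All directed "feeds into" edges over the store, as a two-column matrix.
# Unreadable endpoints (for the given user) are excluded entirely.
store_edges <- function(store, user = NULL) {
  from <- character(); to <- character()
  add <- function(a, b) { from <<- c(from, a); to <<- c(to, b) }
  for (id in lims_ls(store, "experiment")) {
    exp <- store$objects[[id]]
    for (sid in unlist(exp$input_bindings)) add(sid, id)
    for (sid in unlist(exp$output_sample_ids)) add(id, sid)
  }
  for (id in lims_ls(store, "sample")) {
    s <- store$objects[[id]]
    if (!is.null(s$construct_id)) add(s$construct_id, id)
  }
  for (id in lims_ls(store, "construct")) {
    con <- store$objects[[id]]
    for (tid in unlist(con$target_ids)) add(tid, id)
  }
  keep <- rep(TRUE, length(from))
  if (!is.null(user)) {
    ok <- new.env(parent = emptyenv())
    readable <- function(i) {
      v <- ok[[i]]
      if (is.null(v)) { v <- lims_can_read(store, user, i); ok[[i]] <- v }
      v
    }
    keep <- vapply(seq_along(from), function(k) readable(from[k]) && readable(to[k]),
                   logical(1))
  }
  cbind(from = from[keep], to = to[keep])
}

#' Build a workflow graph around an entity
#'
#' Breadth-first neighborhood of radius \code{depth} edges (in either
#' direction) around the centre. Nodes on the frontier that still have
#' readable neighbors outside the graph are marked truncated — in the
#' rendered diagram these are the green shapes signalling "there is more
#' here". Re-centring on a truncated node reveals the hidden neighborhood.
#'
#' @inheritParams lims_get
#' @param center_id entity id (sample, experiment, construct or target).
#' @param depth radius in edges, >= 1 (default 2: a sample shows its
#'   producing and consuming experiments plus their other samples).
#' @param user username whose visibility applies; unreadable entities are
#'   absent even as truncation markers. NULL for unrestricted.
#' @return an object of class \code{lims_graph}: nodes (data.frame id, kind,
#'   label), edges (data.frame from, to), center, truncated ids.
#' @export
lims_build_graph <- function(store, center_id, depth = 2L, user = NULL) {
  rec <- lims_get(store, center_id)
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1L) abort_validation("depth must be >= 1")
  if (!is.null(user) && !lims_can_read(store, user, center_id))
    abort_permission(sprintf("user '%s' may not read %s", user, center_id))
  edges <- store_edges(store, user)
  nbrs <- split(c(edges[, "to"], edges[, "from"]),
                c(edges[, "from"], edges[, "to"]))
  nbrs <- lapply(nbrs, unique)
  dist <- stats::setNames(0L, center_id)
  frontier <- center_id
  for (d in seq_len(depth)) {
    nxt <- setdiff(unique(unlist(nbrs[frontier])), names(dist))
    if (!length(nxt)) break
    dist[nxt] <- d
    frontier <- nxt
  }
  nodes <- names(dist)
  truncated <- Filter(function(n) length(setdiff(nbrs[[n]] %||% character(), nodes)) > 0L,
                      nodes)
  in_graph <- edges[, "from"] %in% nodes & edges[, "to"] %in% nodes
  sub <- edges[in_graph, , drop = FALSE]
  sub <- sub[order(sub[, "from"], sub[, "to"]), , drop = FALSE]
  nodes <- sort(nodes)
  structure(list(
    nodes = data.frame(
      id = nodes,
      kind = vapply(nodes, function(i) store$objects[[i]]$kind, character(1)),
      label = vapply(nodes, function(i) store$objects[[i]]$name %||% i, character(1)),
      row.names = NULL, stringsAsFactors = FALSE),
    edges = data.frame(from = unname(sub[, "from"]), to = unname(sub[, "to"]),
                       stringsAsFactors = FALSE),
    center = center_id,
    truncated = sort(unlist(truncated, use.names = FALSE)) %||% character()),
    class = "lims_graph")
}

#' @export
print.lims_graph <- function(x, ...) {
  cat("<lims_graph>", nrow(x$nodes), "nodes,", nrow(x$edges), "edges; center",
      x$center, "\n")
  invisible(x)
}

DOT_FILL_DEFAULT <- "#A7C7E7"   # blue
DOT_FILL_TRUNCATED <- "#90EE90" # green: the diagram continues past this node
DOT_FILL_CENTER <- "#FFFFFF"    # white with red border
DOT_BORDER_CENTER <- "#FF0000"

dot_shape <- function(kind) {
  switch(kind, experiment = "ellipse", sample = "diamond",
         construct = "box", target = "hexagon", "oval")
}

#' Render a workflow graph as Graphviz DOT
#'
#' Experiments are ellipses and samples diamonds; nodes are filled blue,
#' truncation points green, and the centre white with a red border.
#'
#' @param graph a [lims_build_graph()] result.
#' @return DOT source as a single string.
#' @export
lims_export_dot <- function(graph) {
  if (!inherits(graph, "lims_graph")) abort_validation("not a lims_graph")
  esc <- function(x) gsub("\"", "\\\\\"", x)
  node_lines <- vapply(seq_len(nrow(graph$nodes)), function(i) {
    id <- graph$nodes$id[i]
    fill <- if (id == graph$center) DOT_FILL_CENTER
            else if (id %in% graph$truncated) DOT_FILL_TRUNCATED
            else DOT_FILL_DEFAULT
    border <- if (id == graph$center) DOT_BORDER_CENTER else "#000000"
    sprintf("  \"%s\" [label=\"%s\", shape=%s, style=filled, fillcolor=\"%s\", color=\"%s\"];",
            esc(id), esc(graph$nodes$label[i]), dot_shape(graph$nodes$kind[i]),
            fill, border)
  }, character(1))
  edge_lines <- if (nrow(graph$edges))
    sprintf("  \"%s\" -> \"%s\";", esc(graph$edges$from), esc(graph$edges$to))
  else character()
  paste(c("digraph workflow {", "  rankdir=LR;", node_lines, edge_lines, "}"),
        collapse = "\n")
}

# Ancestor experiments of a sample: walk produced_by up through input
# bindings; returns the experiment id set.
ancestor_experiments <- function(store, sample_id) {
  seen_exp <- character()
  frontier <- sample_id
  seen_smp <- character()
  guard <- 0L
  while (length(frontier)) {
    guard <- guard + 1L
    if (guard > length(ls(store$objects)) + 1L)
      abort_integrity("provenance traversal did not terminate; the store has a cycle")
    nxt <- character()
    for (sid in frontier) {
      if (sid %in% seen_smp) next
      seen_smp <- c(seen_smp, sid)
      pid <- store$objects[[sid]]$produced_by
      if (is.null(pid) || pid %in% seen_exp) next
      seen_exp <- c(seen_exp, pid)
      nxt <- c(nxt, unlist(store$objects[[pid]]$input_bindings))
    }
    frontier <- setdiff(unique(nxt), seen_smp)
  }
  seen_exp
}

#' Sample history report
#'
#' Every experimental stage that led to the production of a sample:
#' the exhaustive set of ancestor experiments (each exactly once, even under
#' diamond-shaped provenance), topologically ordered ancestors-first with
#' ties broken by (performed_at, id). Each stage records the protocol name,
#' setup and result values, and input/output sample summaries. The report
#' also carries the DOT source of the sample's full ancestry diagram, which
#' the exporters embed.
#'
#' @inheritParams lims_get
#' @param sample_id the subject sample.
#' @param user username whose visibility applies; stages the user may not
#'   read are omitted. NULL for unrestricted.
#' @return an object of class \code{lims_history}: subject, subject_label,
#'   stages (list), dot (character).
#' @export
lims_sample_history <- function(store, sample_id, user = NULL) {
  smp <- lims_get(store, sample_id)
  if (smp$kind != "sample") abort_validation(sprintf("%s is not a sample", sample_id))
  if (!is.null(user) && !lims_can_read(store, user, sample_id))
    abort_permission(sprintf("user '%s' may not read %s", user, sample_id))
  if (has_provenance_cycle(store))
    abort_integrity("provenance graph contains a cycle; store is corrupt")
  exps <- ancestor_experiments(store, sample_id)
  exps <- lims_filter_visible(store, user, exps)
  # precedence: A -> B when an output of A is an input of B
  out_of <- lapply(exps, function(e) unlist(store$objects[[e]]$output_sample_ids))
  names(out_of) <- exps
  preds <- lapply(exps, function(e) {
    ins <- unlist(store$objects[[e]]$input_bindings)
    Filter(function(a) length(intersect(out_of[[a]], ins)) > 0L, exps)
  })
  names(preds) <- exps
  ordered <- character()
  remaining <- exps
  while (length(remaining)) {
    ready <- Filter(function(e) all(preds[[e]] %in% ordered), remaining)
    if (!length(ready)) abort_integrity("cycle among ancestor experiments")
    key <- vapply(ready, function(e) {
      r <- store$objects[[e]]
      paste(r$performed_at %||% "", e)
    }, character(1))
    pick <- unlist(ready)[order(key)][1L]
    ordered <- c(ordered, pick)
    remaining <- setdiff(remaining, pick)
  }
  stages <- lapply(ordered, function(e) {
    exp <- store$objects[[e]]
    prot <- store$objects[[exp$protocol_id]]
    summarize <- function(sid) {
      s <- store$objects[[sid]]
      list(id = sid, label = s$label %||% "", sample_type = s$sample_type)
    }
    list(experiment_id = e, experiment_name = exp$name,
         protocol_name = if (!is.null(prot)) prot$name else exp$protocol_id,
         performed_at = exp$performed_at,
         setup_values = exp$setup_values, result_values = exp$result_values,
         inputs = lapply(unlist(exp$input_bindings) %||% character(), summarize),
         outputs = lapply(unlist(exp$output_sample_ids) %||% character(), summarize),
         n_attachments = length(exp$attachments))
  })
  dot <- lims_export_dot(lims_build_graph(store, sample_id,
                                          depth = max(1L, 2L * length(exps) + 2L),
                                          user = user))
  structure(list(subject = sample_id,
                 subject_label = smp$label %||% smp$name,
                 subject_type = smp$sample_type,
                 stages = stages, dot = dot),
            class = "lims_history")
}

#' @export
print.lims_history <- function(x, ...) {
  cat(lims_export_history(x, "text"), "\n")
  invisible(x)
}

#' Export a sample history report
#'
#' @param report a [lims_sample_history()] result.
#' @param format "text" or "xml". The XML schema is this package's own
#'   (see inst/schema/sample-history.xsd); both renderings embed the DOT
#'   workflow diagram source.
#' @return a single string: the rendered document.
#' @export
lims_export_history <- function(report, format = c("text", "xml")) {
  format <- match.arg(format)
  if (!inherits(report, "lims_history")) abort_validation("not a lims_history")
  if (format == "text") return(history_text(report))
  history_xml(report)
}

history_text <- function(report) {
  lines <- c(sprintf("Sample history: %s (%s, %s)",
                     report$subject, report$subject_label, report$subject_type),
             sprintf("Stages: %d", length(report$stages)))
  for (i in seq_along(report$stages)) {
    st <- report$stages[[i]]
    fmt_vals <- function(v) if (length(v))
      paste(sprintf("%s=%s", names(v), vapply(v, format, character(1))), collapse = ", ")
      else "-"
    fmt_smp <- function(ss) if (length(ss))
      paste(vapply(ss, function(s) sprintf("%s [%s]", s$id, s$sample_type),
                   character(1)), collapse = ", ")
      else "-"
    lines <- c(lines,
               sprintf("%d. %s (protocol: %s, at %s)", i, st$experiment_name,
                       st$protocol_name, st$performed_at %||% "?"),
               sprintf("   setup: %s", fmt_vals(st$setup_values)),
               sprintf("   results: %s", fmt_vals(st$result_values)),
               sprintf("   inputs: %s", fmt_smp(st$inputs)),
               sprintf("   outputs: %s", fmt_smp(st$outputs)))
  }
  paste(c(lines, "", "Workflow diagram (DOT):", report$dot), collapse = "\n")
}

history_xml <- function(report) {
  doc <- xml2::xml_new_root("sample-history")
  xml2::xml_set_attr(doc, "subject", report$subject)
  xml2::xml_set_attr(doc, "subject-type", report$subject_type)
  xml2::xml_set_attr(doc, "stages", as.character(length(report$stages)))
  for (i in seq_along(report$stages)) {
    st <- report$stages[[i]]
    stage <- xml2::xml_add_child(doc, "stage", index = as.character(i))
    xml2::xml_add_child(stage, "experiment", id = st$experiment_id,
                        name = st$experiment_name,
                        "performed-at" = st$performed_at %||% "")
    xml2::xml_add_child(stage, "protocol", name = st$protocol_name)
    params <- xml2::xml_add_child(stage, "parameters")
    add_vals <- function(vals, phase) {
      for (nm in names(vals)) {
        node <- xml2::xml_add_child(params, "parameter", name = nm, phase = phase)
        xml2::xml_set_text(node, format(vals[[nm]]))
      }
    }
    add_vals(st$setup_values, "setup")
    add_vals(st$result_values, "result")
    add_samples <- function(tag, ss) {
      parent <- xml2::xml_add_child(stage, tag)
      for (s in ss)
        xml2::xml_add_child(parent, "sample", id = s$id, type = s$sample_type,
                            label = s$label)
    }
    add_samples("inputs", st$inputs)
    add_samples("outputs", st$outputs)
  }
  wf <- xml2::xml_add_child(doc, "workflow", format = "dot")
  xml2::xml_set_text(wf, report$dot)
  as.character(doc)
}

#' Track cohorts of samples through staged experiments
#'
#' Cell (i, j) is TRUE iff founder i has a descendant sample produced by an
#' experiment whose protocol matches stage j. A stage selector matches a
#' protocol's group label (protocol_type) or, failing that, its exact name —
#' so stages can be as coarse as "Processing DNA" or as fine as "PCR".
#' Adding experiments can only turn cells TRUE, never FALSE.
#'
#' @inheritParams lims_get
#' @param founder_ids character vector of founder sample ids.
#' @param stage_types ordered character vector of stage selectors; may be
#'   empty (0-column matrix).
#' @param user username whose visibility applies; NULL for unrestricted.
#' @return logical matrix, founders x stages.
#' @export
lims_cohort_report <- function(store, founder_ids, stage_types, user = NULL) {
  for (f in founder_ids) {
    s <- lims_get(store, f)
    if (s$kind != "sample") abort_validation(sprintf("%s is not a sample", f))
    if (!is.null(user) && !lims_can_read(store, user, f))
      abort_permission(sprintf("user '%s' may not read %s", user, f))
  }
  m <- matrix(FALSE, nrow = length(founder_ids), ncol = length(stage_types),
              dimnames = list(founder_ids, stage_types))
  if (!length(stage_types) || !length(founder_ids)) return(m)
  adj <- provenance_adjacency(store)
  for (i in seq_along(founder_ids)) {
    # forward reachability over the feed graph
    seen <- character()
    frontier <- founder_ids[[i]]
    types_hit <- character()
    while (length(frontier)) {
      nxt <- character()
      for (node in frontier) {
        if (node %in% seen) next
        seen <- c(seen, node)
        rec <- store$objects[[node]]
        if (rec$kind == "experiment" &&
            (is.null(user) || lims_can_read(store, user, node))) {
          if (length(unlist(rec$output_sample_ids))) {
            prot <- store$objects[[rec$protocol_id]]
            types_hit <- c(types_hit, prot$protocol_type, prot$name)
          }
        }
        nxt <- c(nxt, adj[[node]] %||% character())
      }
      frontier <- setdiff(unique(nxt), seen)
    }
    key <- norm_type(types_hit)
    m[i, ] <- vapply(stage_types, function(st) norm_type(st) %in% key, logical(1))
  }
  m
}
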