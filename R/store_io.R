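# Persistence and exchange. The store lives in memory; a single JSON file
# (the bulk-export document plus store metadata) is its on-disk form. Bulk
# export/import moves data between installations as XML with a JSON mirror;
# element order is deterministic (by kind, then id) so exports are diffable
# and two exports of an unchanged store are byte-identical.

REF_SCALAR_FIELDS <- c("notebook_id", "produced_by", "construct_id",
                       "protocol_id", "copied_from", "access_override")
REF_LIST_FIELDS <- c("output_sample_ids", "target_ids", "component_target_ids")

serialize_record <- function(rec) {
  rec <- unclass(rec)
  if (!is.null(rec$attachments) && length(rec$attachments))
    rec$attachments <- lapply(rec$attachments, function(a) {
      a$payload <- jsonlite::base64_enc(a$payload)
      a
    })
  rec[order(names(rec))]
}

deserialize_record <- function(e) {
  if (is.null(e$kind) || is.null(e$id) || !e$kind %in% KNOWN_KINDS)
    abort_format("entity lacks a valid kind/id")
  chr1 <- function(x) if (is.null(x)) NULL else as.character(x)[1]
  for (f in REF_SCALAR_FIELDS) if (!is.null(e[[f]])) e[[f]] <- chr1(e[[f]])
  for (f in REF_LIST_FIELDS) if (!is.null(e[[f]]))
    e[[f]] <- as.list(as.character(unlist(e[[f]])))
  if (!is.null(e$output_sample_ids))
    e$output_sample_ids <- as.character(unlist(e$output_sample_ids))
  if (!is.null(e$input_bindings))
    e$input_bindings <- lapply(e$input_bindings, function(v) as.character(unlist(v)))
  if (!is.null(e$members)) e$members <- as.character(unlist(e$members))
  for (f in c("rows", "cols", "start_aa", "stop_aa"))
    if (!is.null(e[[f]])) e[[f]] <- as.integer(e[[f]])
  for (f in c("add_n_met", "add_stop", "cleavable"))
    if (!is.null(e[[f]])) e[[f]] <- as.logical(e[[f]])
  fix_slots <- function(slots) lapply(slots, function(s) {
    s$multiplicity <- as.integer(s$multiplicity); s
  })
  if (!is.null(e$input_slots)) e$input_slots <- fix_slots(e$input_slots)
  if (!is.null(e$output_slots)) e$output_slots <- fix_slots(e$output_slots)
  if (!is.null(e$attachments))
    e$attachments <- lapply(e$attachments, function(a) {
      a$payload <- jsonlite::base64_dec(a$payload)
      a
    })
  if (!is.null(e$wells)) e$wells <- lapply(e$wells, function(w) as.character(w)[1])
  for (f in c("notes", "external_refs", "setup_values", "result_values",
              "parameters", "tags"))
    if (!is.null(e[[f]]) && !is.list(e[[f]])) e[[f]] <- as.list(e[[f]])
  class(e) <- c(paste0("lims_", e$kind), "lims_record")
  e
}

export_entity_ids <- function(store, scope) {
  ids <- lims_ids(store)
  if (identical(scope, "all")) {
    ord <- order(vapply(ids, function(i) store$objects[[i]]$kind, character(1)), ids)
    return(ids[ord])
  }
  check_notebook(store, scope)
  in_scope <- Filter(function(i) {
    rec <- store$objects[[i]]
    identical(rec$notebook_id, scope) || identical(i, scope)
  }, ids)
  # pull in referenced protocols and targets (and constructs behind samples),
  # wherever they live — typically the PUBLIC library
  closure <- character()
  for (i in in_scope) {
    rec <- store$objects[[i]]
    closure <- c(closure,
                 rec$protocol_id %||% character(),
                 rec$construct_id %||% character(),
                 unlist(rec$target_ids) %||% character(),
                 unlist(rec$component_target_ids) %||% character())
  }
  for (cid in unique(closure)) {
    rec <- store$objects[[cid]]
    if (!is.null(rec) && rec$kind == "construct")
      closure <- c(closure, unlist(rec$target_ids))
  }
  extra <- setdiff(unique(closure), in_scope)
  extra <- Filter(function(i) store_has(store, i), extra)
  # sample-type registry and notebooks backing the extras travel along
  types <- lims_ls(store, "sample_type")
  nbs <- unique(vapply(extra, function(i) store$objects[[i]]$notebook_id %||% NA_character_,
                       character(1)))
  nbs <- nbs[!is.na(nbs)]
  out <- unique(c(in_scope, unlist(extra), types, nbs))
  ord <- order(vapply(out, function(i) store$objects[[i]]$kind, character(1)), out)
  out[ord]
}

export_document <- function(store, scope = "all") {
  ids <- export_entity_ids(store, scope)
  keep <- as.character(ids)
  ents <- lapply(keep, function(i) {
    rec <- store$objects[[i]]
    # references leaving the scope are dropped to keep the document closed
    if (!identical(scope, "all")) {
      if (!is.null(rec$produced_by) && !rec$produced_by %in% keep)
        rec$produced_by <- NULL
    }
    serialize_record(rec)
  })
  perms <- store$permissions
  if (!identical(scope, "all"))
    perms <- Filter(function(p) p$notebook_id %in% keep, perms)
  perms <- perms[order(vapply(perms, function(p) paste(p$group_id, p$notebook_id),
                              character(1)))]
  perms <- Filter(function(p) p$group_id %in% keep || identical(scope, "all"), perms)
  list(format = "lims-bulk", schema_version = store$schema_version,
       scope = if (identical(scope, "all")) "all" else scope,
       entities = ents, permissions = perms)
}

#' Bulk export of a store
#'
#' Produces a self-contained document holding every entity in scope plus the
#' protocols, targets and sample types they reference; the permission table
#' travels along for full exports. Entities are ordered by kind then id, so
#' an unchanged store always exports byte-identically.
#'
#' @inheritParams lims_get
#' @param scope "all" or a notebook id (that notebook's records plus
#'   referenced PUBLIC protocols and targets).
#' @param format "xml" (default) or "json".
#' @return the document as a single string.
#' @export
lims_export_bulk <- function(store, scope = "all", format = c("xml", "json")) {
  format <- match.arg(format)
  doc <- export_document(store, scope)
  if (format == "json")
    return(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null",
                                         digits = NA)))
  bulk_xml(doc)
}

# Generic value <-> XML encoding. Every element carries a type attribute so
# the decoder restores scalars, vectors and (named) lists faithfully.
xml_encode_value <- function(parent, tag, value, name_attr = NULL) {
  node <- xml2::xml_add_child(parent, tag)
  if (!is.null(name_attr)) xml2::xml_set_attr(node, "name", name_attr)
  if (is.null(value)) {
    xml2::xml_set_attr(node, "type", "null")
  } else if (is.list(value) || length(value) > 1L) {
    xml2::xml_set_attr(node, "type", "list")
    nms <- names(value)
    for (i in seq_along(value))
      xml_encode_value(node, "item", value[[i]],
                       name_attr = if (!is.null(nms) && nzchar(nms[i])) nms[i])
  } else if (is.logical(value)) {
    xml2::xml_set_attr(node, "type", "boolean")
    xml2::xml_set_text(node, if (value) "true" else "false")
  } else if (is.numeric(value)) {
    xml2::xml_set_attr(node, "type", "number")
    xml2::xml_set_text(node, format(value, digits = 17, scientific = FALSE))
  } else {
    xml2::xml_set_attr(node, "type", "string")
    xml2::xml_set_text(node, as.character(value))
  }
  node
}

xml_decode_value <- function(node) {
  type <- xml2::xml_attr(node, "type")
  if (is.na(type)) abort_format("bulk XML element lacks a type attribute")
  switch(type,
    null = NULL,
    string = xml2::xml_text(node),
    number = as.numeric(xml2::xml_text(node)),
    boolean = identical(xml2::xml_text(node), "true"),
    list = {
      kids <- xml2::xml_children(node)
      vals <- lapply(kids, xml_decode_value)
      nms <- xml2::xml_attr(kids, "name")
      if (length(nms) && any(!is.na(nms)))
        names(vals) <- ifelse(is.na(nms), "", nms)
      vals
    },
    abort_format(sprintf("unknown bulk XML type '%s'", type)))
}

bulk_xml <- function(doc) {
  root <- xml2::xml_new_root("lims-export")
  xml2::xml_set_attr(root, "format", doc$format)
  xml2::xml_set_attr(root, "schema-version", as.character(doc$schema_version))
  xml2::xml_set_attr(root, "scope", doc$scope)
  ents <- xml2::xml_add_child(root, "entities")
  for (e in doc$entities) {
    node <- xml2::xml_add_child(ents, "entity", kind = e$kind, id = e$id)
    for (f in setdiff(names(e), c("kind", "id")))
      xml_encode_value(node, "field", e[[f]], name_attr = f)
  }
  perms <- xml2::xml_add_child(root, "permissions")
  for (p in doc$permissions)
    xml2::xml_add_child(perms, "permission", group = p$group_id,
                        notebook = p$notebook_id, level = p$level)
  as.character(root)
}

parse_bulk_document <- function(text) {
  text <- paste(text, collapse = "\n")
  if (grepl("^\\s*\\{", text)) {
    doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                    error = function(e) abort_format("bulk document is not valid JSON"))
    if (!identical(doc$format, "lims-bulk"))
      abort_format("not a lims-bulk document")
    return(doc)
  }
  root <- tryCatch(xml2::read_xml(text),
                   error = function(e) abort_format("bulk document is not valid XML"))
  if (xml2::xml_name(root) != "lims-export")
    abort_format("not a lims-bulk document")
  ents <- lapply(xml2::xml_find_all(root, "./entities/entity"), function(node) {
    e <- list(kind = xml2::xml_attr(node, "kind"), id = xml2::xml_attr(node, "id"))
    for (f in xml2::xml_children(node))
      e[[xml2::xml_attr(f, "name")]] <- xml_decode_value(f)
    e
  })
  perms <- lapply(xml2::xml_find_all(root, "./permissions/permission"), function(node)
    list(group_id = xml2::xml_attr(node, "group"),
         notebook_id = xml2::xml_attr(node, "notebook"),
         level = xml2::xml_attr(node, "level")))
  list(format = "lims-bulk",
       schema_version = as.integer(xml2::xml_attr(root, "schema-version")),
       scope = xml2::xml_attr(root, "scope"),
       entities = ents, permissions = perms)
}

clone_store <- function(store) {
  copy <- new.env(parent = emptyenv())
  copy$objects <- new.env(parent = emptyenv())
  copy$type_cache <- new.env(parent = emptyenv())  # lazily rebuilt on lookup
  for (id in ls(store$objects)) copy$objects[[id]] <- store$objects[[id]]
  for (f in c("permissions", "access_log", "counter", "clock", "id_mode",
              "schema_version", "seeded", "location", "public_notebook_id"))
    copy[[f]] <- store[[f]]
  class(copy) <- "lims_store"
  copy
}

commit_store <- function(store, staged) {
  store$objects <- staged$objects
  store$permissions <- staged$permissions
  store$counter <- staged$counter
  store$clock <- staged$clock
  store$seeded <- staged$seeded
  invisible(store)
}

#' Bulk import into a store
#'
#' Creates the document's entities, remapping ids on collision and skipping
#' entities whose id is already present (so importing the same document
#' twice creates nothing the second time). An imported notebook named
#' PUBLIC merges into the store's own PUBLIC notebook. The import is atomic:
#' on any format or integrity violation the store is unchanged.
#'
#' @inheritParams lims_get
#' @param document a bulk XML or JSON document (string), or a file path.
#' @return a list: \code{created} and \code{skipped} counts plus the
#'   \code{id_map} applied.
#' @export
lims_import_bulk <- function(store, document) {
  if (length(document) == 1L && !grepl("[<{\n]", document) && file.exists(document))
    document <- paste(readLines(document, warn = FALSE), collapse = "\n")
  doc <- parse_bulk_document(document)
  if (!identical(as.integer(doc$schema_version), store$schema_version))
    abort_version(sprintf("document schema version %s does not match store version %s",
                          doc$schema_version, store$schema_version))
  staged <- clone_store(store)
  ents <- lapply(doc$entities, deserialize_record)
  id_map <- list()
  created <- 0L; skipped <- 0L
  for (e in ents) {
    existing <- staged$objects[[e$id]]
    if (e$kind == "notebook" && identical(e$name, "PUBLIC")) {
      id_map[[e$id]] <- staged$public_notebook_id
      skipped <- skipped + 1L
    } else if (!is.null(existing)) {
      if (identical(existing$kind, e$kind)) {
        id_map[[e$id]] <- e$id
        skipped <- skipped + 1L
      } else {
        id_map[[e$id]] <- new_id(staged, e$kind)
      }
    } else {
      id_map[[e$id]] <- e$id
    }
  }
  remap <- function(id) {
    if (is.null(id)) return(NULL)
    id_map[[id]] %||% id
  }
  for (e in ents) {
    new_e_id <- remap(e$id)
    if (!is.null(staged$objects[[new_e_id]])) next  # skipped duplicate
    e$id <- new_e_id
    for (f in REF_SCALAR_FIELDS)
      if (!is.null(e[[f]])) e[[f]] <- remap(e[[f]])
    for (f in REF_LIST_FIELDS)
      if (!is.null(e[[f]])) e[[f]] <- lapply(unlist(e[[f]]), remap)
    if (!is.null(e$output_sample_ids))
      e$output_sample_ids <- vapply(e$output_sample_ids, function(i) remap(i), character(1))
    if (!is.null(e$input_bindings))
      e$input_bindings <- lapply(e$input_bindings, function(v)
        vapply(v, function(i) remap(i), character(1)))
    if (!is.null(e$wells)) e$wells <- lapply(e$wells, remap)
    staged$objects[[e$id]] <- e
    created <- created + 1L
    suffix <- suppressWarnings(as.integer(sub("^.*-(\\d+)$", "\\1", e$id)))
    if (!is.na(suffix)) staged$counter <- max(staged$counter, suffix)
    if (e$kind == "protocol" && identical(e$name, "PCR")) staged$seeded <- TRUE
  }
  for (p in doc$permissions) {
    p <- list(group_id = remap(p$group_id), notebook_id = remap(p$notebook_id),
              level = p$level)
    dup <- any(vapply(staged$permissions, function(q)
      identical(q[c("group_id", "notebook_id", "level")],
                p[c("group_id", "notebook_id", "level")]), logical(1)))
    if (!dup && store_has(staged, p$group_id) && store_has(staged, p$notebook_id))
      staged$permissions <- c(staged$permissions, list(p))
  }
  problems <- lims_audit(staged)
  if (length(problems))
    abort_integrity(paste("import would corrupt the store:",
                          paste(utils::head(problems, 5L), collapse = "; ")))
  commit_store(store, staged)
  list(created = created, skipped = skipped, id_map = id_map)
}

#' Initialise, open and save a single-file store
#'
#' The on-disk form is the bulk JSON document plus store metadata (id mode,
#' counters, seeded flag, access log). [lims_init_store()] refuses to
#' overwrite an existing file; [lims_open_store()] checks the schema version.
#'
#' @param location file path for the store.
#' @param id_mode see [lims_store()].
#' @return a [lims_store()].
#' @export
lims_init_store <- function(location, id_mode = c("sequential", "uuid")) {
  if (file.exists(location))
    lims_abort("lims_already_exists_error",
               sprintf("a store already exists at %s", location))
  store <- lims_store(id_mode = match.arg(id_mode), location = location)
  lims_save_store(store)
  store
}

#' @rdname lims_init_store
#' @export
lims_open_store <- function(location) {
  if (!file.exists(location))
    abort_not_found(sprintf("no store at %s", location))
  text <- paste(readLines(location, warn = FALSE), collapse = "\n")
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e) abort_format("store file is not valid JSON"))
  if (!identical(doc$format, "lims-store"))
    abort_format("not a lims store file")
  meta <- doc$meta
  if (!identical(as.integer(doc$schema_version), 1L))
    abort_version(sprintf("store schema version %s needs migration", doc$schema_version))
  store <- lims_store(id_mode = meta$id_mode %||% "sequential", location = location)
  doc$format <- "lims-bulk"
  lims_import_bulk(store, as.character(jsonlite::toJSON(doc, auto_unbox = TRUE,
                                                        null = "null", digits = NA)))
  store$seeded <- isTRUE(meta$seeded)
  store$counter <- max(store$counter, as.integer(meta$counter %||% 0L))
  store$clock <- max(store$clock, as.integer(meta$clock %||% 0L))
  store$access_log <- lapply(doc$access_log %||% list(), function(e)
    list(user = e$user, entity_id = e$entity_id, kind = e$kind, time = e$time))
  store
}

#' @rdname lims_init_store
#' @param store a [lims_store()] with a location.
#' @export
lims_save_store <- function(store, location = NULL) {
  location <- location %||% store$location
  if (is.null(location)) abort_validation("store has no file location")
  doc <- export_document(store, "all")
  doc$format <- "lims-store"
  doc$meta <- list(id_mode = store$id_mode, seeded = store$seeded,
                   counter = store$counter, clock = store$clock)
  doc$access_log <- store$access_log
  writeLines(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null",
                                           digits = NA)), location)
  store$location <- location
  invisible(store)
}

#' Text search over one entity kind
#'
#' Case-insensitive substring match over name, label, description and note
#' text, filtered by what the user may read.
#'
#' @inheritParams lims_get
#' @param kind entity kind to search.
#' @param text non-empty query string.
#' @param user username whose visibility applies; NULL for unrestricted.
#' @return list of matching records.
#' @export
lims_search <- function(store, kind, text, user = NULL) {
  if (!is.character(kind) || length(kind) != 1L || !kind %in% KNOWN_KINDS)
    abort_validation(sprintf("unknown entity kind '%s'", paste(kind, collapse = ",")))
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    abort_validation("search text must be non-empty")
  needle <- tolower(text)
  ids <- lims_filter_visible(store, user, lims_ls(store, kind))
  hits <- Filter(function(i) {
    rec <- store$objects[[i]]
    hay <- c(rec$name %||% "", rec$label %||% "", rec$description %||% "",
             vapply(rec$notes %||% list(), function(n) n$text %||% "", character(1)))
    any(grepl(needle, tolower(hay), fixed = TRUE))
  }, ids)
  lapply(hits, function(i) store$objects[[i]])
}

#' Record and recall entity access
#'
#' [lims_record_access()] appends to the store's access log;
#' [lims_recent()] returns the user's most recently used entities (newest
#' first, deduplicated, readable only) — the data behind "recently used"
#' drop-down ordering.
#'
#' @inheritParams lims_get
#' @param user username.
#' @param id entity id that was viewed.
#' @return [lims_recent()]: list of records, length <= n.
#' @export
lims_record_access <- function(store, user, id) {
  rec <- lims_get(store, id)
  store$access_log[[length(store$access_log) + 1L]] <-
    list(user = user, entity_id = id, kind = rec$kind, time = lims_now(store))
  invisible(NULL)
}

#' @rdname lims_record_access
#' @param kind optional kind filter.
#' @param n maximum number of entities.
#' @export
lims_recent <- function(store, user, kind = NULL, n = 10L) {
  seen <- character()
  out <- list()
  for (e in rev(store$access_log)) {
    if (!identical(e$user, user)) next
    if (!is.null(kind) && !identical(e$kind, kind)) next
    if (e$entity_id %in% seen) next
    seen <- c(seen, e$entity_id)
    if (!store_has(store, e$entity_id)) next
    if (!lims_can_read(store, user, e$entity_id)) next
    out[[length(out) + 1L]] <- store$objects[[e$entity_id]]
    if (length(out) >= n) break
  }
  out
}
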