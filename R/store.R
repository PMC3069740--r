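#' Create an in-memory LIMS store
#'
#' The store is the unit of persistence: an entity registry keyed by id,
#' holding every notebook, user, group, sample type, target, construct,
#' protocol, experiment, sample, complex and plate, plus group permissions
#' and the access log used for recently-used lists. It has reference
#' semantics (an environment), so API functions mutate it in place.
#'
#' Two id modes exist. \code{"sequential"} (the default) issues deterministic
#' ids (\code{"sample-0001"} etc.) and timestamps from a logical clock, so a
#' given sequence of API calls always produces a byte-identical bulk export;
#' this is what reproducible fixtures and diffable exports rely on.
#' \code{"uuid"} issues random 128-bit hex ids and wall-clock timestamps for
#' multi-session use.
#'
#' Every new store contains one distinguished PUBLIC notebook. Records filed
#' there (the default protocol library, the construct-design protocol) are
#' readable by all users.
#'
#' @param id_mode "sequential" for deterministic ids and timestamps, "uuid"
#'   for random ids and wall-clock time.
#' @param location optional file path used by [lims_save_store()].
#' @return an object of class \code{lims_store}.
#' @export
lims_store <- function(id_mode = c("sequential", "uuid"), location = NULL) {
  id_mode <- match.arg(id_mode)
  store <- new.env(parent = emptyenv())
  store$objects <- new.env(parent = emptyenv())
  store$type_cache <- new.env(parent = emptyenv())  # norm name -> type id
  store$permissions <- list()
  store$access_log <- list()
  store$counter <- 0L
  store$clock <- 0L
  store$id_mode <- id_mode
  store$schema_version <- 1L
  store$seeded <- FALSE
  store$location <- location
  class(store) <- "lims_store"
  pub <- new_record(store, "notebook",
                    name = "PUBLIC",
                    description = "Globally readable notebook holding the default protocol library")
  store$public_notebook_id <- pub$id
  store
}

#' @export
print.lims_store <- function(x, ...) {
  kinds <- vapply(lims_ids(x), function(id) x$objects[[id]]$kind, character(1))
  cat("<lims_store> schema", x$schema_version,
      "|", length(kinds), "records\n")
  if (length(kinds)) print(table(kinds))
  invisible(x)
}

new_id <- function(store, kind) {
  store$counter <- store$counter + 1L
  if (store$id_mode == "sequential") {
    sprintf("%s-%04d", kind, store$counter)
  } else {
    paste0(kind, "-", paste(sprintf("%02x", sample.int(256L, 16L, replace = TRUE) - 1L),
                            collapse = ""))
  }
}

lims_now <- function(store) {
  store$clock <- store$clock + 1L
  if (store$id_mode == "sequential") {
    format(as.POSIXct("2024-01-01 00:00:00", tz = "UTC") + store$clock,
           "%Y-%m-%dT%H:%M:%SZ")
  } else {
    format(as.POSIXct(Sys.time(), tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ")
  }
}

# Kinds whose records carry notebook-page properties (notes, attachments,
# external refs, access override). Notebooks, users, groups and sample types
# are infrastructure and do not.
PAGE_KINDS <- c("target", "construct", "sample", "experiment", "protocol",
                "complex", "plate")

KNOWN_KINDS <- c("notebook", "user", "group", "sample_type", PAGE_KINDS)

new_record <- function(store, kind, ..., notebook_id = NULL, created_by = NULL) {
  stopifnot(kind %in% KNOWN_KINDS)
  rec <- list(id = new_id(store, kind), kind = kind,
              created_at = lims_now(store), created_by = created_by,
              notebook_id = notebook_id, ...)
  if (kind %in% PAGE_KINDS) {
    rec$notes <- list()
    rec$attachments <- list()
    rec$external_refs <- list()
    rec$access_override <- NULL
  }
  class(rec) <- c(paste0("lims_", kind), "lims_record")
  store$objects[[rec$id]] <- rec
  rec
}

store_put <- function(store, rec) {
  store$objects[[rec$id]] <- rec
  rec
}

#' Fetch a record by id
#'
#' @param store a [lims_store()].
#' @param id entity id.
#' @return the record (a named list with class \code{lims_record}).
#' @export
lims_get <- function(store, id) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    abort_validation("entity id must be a single non-empty string")
  rec <- store$objects[[id]]
  if (is.null(rec)) abort_not_found(sprintf("no such entity: %s", id))
  rec
}

store_has <- function(store, id) !is.null(store$objects[[id]])

lims_ids <- function(store) sort(ls(store$objects))

#' List record ids of one kind
#'
#' @inheritParams lims_get
#' @param kind entity kind, e.g. "sample" or "protocol".
#' @return sorted character vector of ids.
#' @export
lims_ls <- function(store, kind = NULL) {
  ids <- lims_ids(store)
  if (is.null(kind)) return(ids)
  if (!kind %in% KNOWN_KINDS)
    abort_validation(sprintf("unknown entity kind '%s'", kind))
  ids[vapply(ids, function(i) store$objects[[i]]$kind == kind, logical(1))]
}

# Case-insensitive, whitespace-normalized comparison key for sample-type
# names ("Template" and "template" are the same type).
norm_type <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Store-wide integrity audit
#'
#' Checks referential integrity (every reference resolves), the
#' single-producer rule (a sample's \code{produced_by} is mutually consistent
#' with that experiment's output list), type-chain soundness (every bound
#' input sample's type equals its slot's type, at the slot's multiplicity),
#' notebook membership of all page records, and acyclicity of the provenance
#' graph. A healthy store — including any store built purely through the API
#' — returns an empty character vector.
#'
#' @inheritParams lims_get
#' @return character vector of violation messages; \code{character(0)} if the
#'   store is sound.
#' @export
lims_audit <- function(store) {
  bad <- character()
  ids <- lims_ids(store)
  say <- function(fmt, ...) bad[[length(bad) + 1L]] <<- sprintf(fmt, ...)
  for (id in ids) {
    rec <- store$objects[[id]]
    if (rec$kind %in% PAGE_KINDS) {
      if (is.null(rec$notebook_id) || !store_has(store, rec$notebook_id) ||
          store$objects[[rec$notebook_id]]$kind != "notebook")
        say("%s: missing or dangling notebook", id)
    }
    if (rec$kind == "sample") {
      if (!is.null(rec$produced_by)) {
        if (!store_has(store, rec$produced_by)) {
          say("%s: produced_by dangles (%s)", id, rec$produced_by)
        } else {
          exp <- store$objects[[rec$produced_by]]
          if (!(id %in% unlist(exp$output_sample_ids)))
            say("%s: produced_by %s does not list it as output", id, exp$id)
        }
      }
      if (!is.null(rec$construct_id) && !store_has(store, rec$construct_id))
        say("%s: construct_id dangles", id)
    }
    if (rec$kind == "experiment") {
      if (!store_has(store, rec$protocol_id)) {
        say("%s: protocol dangles", id)
        next
      }
      prot <- store$objects[[rec$protocol_id]]
      for (slot in prot$input_slots) {
        bound <- rec$input_bindings[[slot$role]] %||% character()
        if (length(bound) != slot$multiplicity)
          say("%s: slot '%s' bound %d of %d", id, slot$role,
              length(bound), slot$multiplicity)
        for (sid in bound) {
          if (!store_has(store, sid)) { say("%s: input %s dangles", id, sid); next }
          s <- store$objects[[sid]]
          if (norm_type(s$sample_type) != norm_type(slot$sample_type))
            say("%s: slot '%s' expects %s, got %s", id, slot$role,
                slot$sample_type, s$sample_type)
        }
      }
      for (sid in rec$output_sample_ids) {
        if (!store_has(store, sid)) { say("%s: output %s dangles", id, sid); next }
        if (!identical(store$objects[[sid]]$produced_by, id))
          say("%s: output %s does not point back", id, sid)
      }
    }
    if (rec$kind == "construct") {
      for (tid in rec$target_ids)
        if (!store_has(store, tid)) say("%s: target %s dangles", id, tid)
    }
    if (rec$kind == "complex") {
      if (length(rec$component_target_ids) < 2L)
        say("%s: complex has < 2 components", id)
      for (tid in rec$component_target_ids)
        if (!store_has(store, tid)) say("%s: component %s dangles", id, tid)
    }
  }
  for (p in store$permissions) {
    if (!store_has(store, p$group_id)) say("permission: group %s dangles", p$group_id)
    if (!store_has(store, p$notebook_id)) say("permission: notebook %s dangles", p$notebook_id)
  }
  if (has_provenance_cycle(store)) say("provenance graph contains a cycle")
  bad
}

# Cycle detection over the sample/experiment feed graph (DFS, iterative).
has_provenance_cycle <- function(store) {
  adj <- provenance_adjacency(store)
  colour <- new.env(parent = emptyenv())
  for (start in names(adj)) {
    if (!is.null(colour[[start]])) next
    stack <- list(list(node = start, i = 0L))
    colour[[start]] <- "grey"
    while (length(stack)) {
      top <- stack[[length(stack)]]
      nbrs <- adj[[top$node]] %||% character()
      if (top$i < length(nbrs)) {
        stack[[length(stack)]]$i <- top$i + 1L
        nxt <- nbrs[[top$i + 1L]]
        cl <- colour[[nxt]]
        if (is.null(cl)) {
          colour[[nxt]] <- "grey"
          stack[[length(stack) + 1L]] <- list(node = nxt, i = 0L)
        } else if (cl == "grey") {
          return(TRUE)
        }
      } else {
        colour[[top$node]] <- "black"
        stack[[length(stack)]] <- NULL
      }
    }
  }
  FALSE
}

# Directed adjacency of the feed graph: sample -> consuming experiment,
# experiment -> output sample.
provenance_adjacency <- function(store) {
  adj <- list()
  for (id in lims_ls(store, "experiment")) {
    exp <- store$objects[[id]]
    for (sid in unlist(exp$input_bindings))
      adj[[sid]] <- c(adj[[sid]], id)
    adj[[id]] <- c(adj[[id]] %||% character(), unlist(exp$output_sample_ids))
  }
  adj
}
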