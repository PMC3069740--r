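# Authorization (not authentication): the caller asserts a username; this
# module decides what that user may see or change. Rights are granted per
# notebook to user groups; an entity's governing notebook defaults to the
# notebook of the nearest target in its provenance, so filing a target in a
# notebook controls access to all downstream work on it.

#' Create a user
#'
#' @inheritParams lims_get
#' @param username unique login name.
#' @param display_name human-readable name.
#' @return the user record.
#' @export
lims_create_user <- function(store, username, display_name = username) {
  check_nonempty(username, "username")
  for (id in lims_ls(store, "user"))
    if (identical(store$objects[[id]]$username, username))
      abort_duplicate(sprintf("username '%s' already exists", username))
  new_record(store, "user", name = display_name,
             username = username, display_name = display_name)
}

#' Create a user group
#'
#' @inheritParams lims_get
#' @param name group name.
#' @param members character vector of usernames.
#' @return the group record.
#' @export
lims_create_group <- function(store, name, members = character()) {
  check_nonempty(name, "group name")
  new_record(store, "group", name = name, members = unique(as.character(members)))
}

#' Add a user to a group
#'
#' @inheritParams lims_get
#' @param group_id group record id.
#' @param username username to add (membership is a set).
#' @return the updated group record, invisibly.
#' @export
lims_add_member <- function(store, group_id, username) {
  rec <- lims_get(store, group_id)
  if (rec$kind != "group") abort_validation(sprintf("%s is not a group", group_id))
  rec$members <- unique(c(rec$members, username))
  invisible(store_put(store, rec))
}

#' Grant or revoke notebook access for a group
#'
#' Levels are "read" and "write"; write implies read. Granting replaces any
#' previous grant for the same (group, notebook) pair; both operations are
#' idempotent.
#'
#' @inheritParams lims_add_member
#' @param notebook_id notebook record id.
#' @param level "read" or "write".
#' @return the permission record (a list), invisibly.
#' @export
lims_grant <- function(store, group_id, notebook_id, level = c("read", "write")) {
  level <- match.arg(level)
  grp <- lims_get(store, group_id)
  if (grp$kind != "group") abort_not_found(sprintf("%s is not a group", group_id))
  check_notebook(store, notebook_id)
  keep <- Filter(function(p) !(p$group_id == group_id && p$notebook_id == notebook_id),
                 store$permissions)
  perm <- list(group_id = group_id, notebook_id = notebook_id, level = level)
  store$permissions <- c(keep, list(perm))
  invisible(perm)
}

#' @rdname lims_grant
#' @export
lims_revoke <- function(store, group_id, notebook_id) {
  lims_get(store, group_id)
  lims_get(store, notebook_id)
  store$permissions <-
    Filter(function(p) !(p$group_id == group_id && p$notebook_id == notebook_id),
           store$permissions)
  invisible(NULL)
}

user_group_ids <- function(store, user) {
  ids <- lims_ls(store, "group")
  ids[vapply(ids, function(g) user %in% store$objects[[g]]$members, logical(1))]
}

#' Governing notebook of an entity
#'
#' Resolution order: the entity's own \code{access_override} notebook if set;
#' otherwise the notebook of the nearest target reachable over
#' construct/ancestry links (breadth-first; ties broken by the oldest
#' target); otherwise the entity's own notebook.
#'
#' @inheritParams lims_get
#' @param id entity id.
#' @return a notebook id.
#' @export
lims_effective_notebook <- function(store, id) {
  rec <- lims_get(store, id)
  if (!is.null(rec$access_override)) return(rec$access_override)
  if (rec$kind != "target") {
    tid <- nearest_target(store, rec)
    if (!is.null(tid)) {
      tgt <- store$objects[[tid]]
      return(tgt$access_override %||% tgt$notebook_id)
    }
  }
  rec$notebook_id
}

# BFS from an entity over links that relate it to a target: sample ->
# {construct, producing experiment}; experiment -> {bound inputs, outputs};
# construct -> targets; complex -> component targets; plate -> well entities.
nearest_target <- function(store, rec) {
  frontier <- rec$id
  seen <- character()
  while (length(frontier)) {
    found <- character()
    nxt <- character()
    for (id in frontier) {
      if (id %in% seen || !store_has(store, id)) next
      seen <- c(seen, id)
      r <- store$objects[[id]]
      nbr <- switch(r$kind,
        target = { found <- c(found, id); character() },
        sample = c(r$construct_id, r$produced_by),
        experiment = c(unlist(r$input_bindings), unlist(r$output_sample_ids)),
        construct = unlist(r$target_ids),
        complex = unlist(r$component_target_ids),
        plate = unlist(r$wells),
        character())
      nxt <- c(nxt, unlist(nbr))
    }
    if (length(found)) {
      # oldest target wins the tie at this radius
      created <- vapply(found, function(t) store$objects[[t]]$created_at, character(1))
      return(found[order(created, found)][1L])
    }
    frontier <- setdiff(unique(nxt), seen)
  }
  NULL
}

#' Can a user read / write an entity?
#'
#' Readable iff the entity's governing notebook (see
#' [lims_effective_notebook()]) is the PUBLIC notebook, or some group
#' containing the user holds at least the required level on it. A
#' \code{NULL} user means an unrestricted (administrative) context.
#'
#' @inheritParams lims_get
#' @param user username, or NULL for unrestricted access.
#' @param id entity id.
#' @return logical scalar.
#' @export
lims_can_read <- function(store, user, id) access_level(store, user, id) >= 1L

#' @rdname lims_can_read
#' @export
lims_can_write <- function(store, user, id) access_level(store, user, id) >= 2L

access_level <- function(store, user, id) {
  if (is.null(user)) return(2L)
  nb <- lims_effective_notebook(store, id)
  if (identical(nb, store$public_notebook_id)) return(1L)
  best <- 0L
  groups <- user_group_ids(store, user)
  for (p in store$permissions) {
    if (p$notebook_id == nb && p$group_id %in% groups)
      best <- max(best, if (p$level == "write") 2L else 1L)
  }
  best
}

#' Filter entity ids down to those a user may read
#'
#' Order-preserving; the single choke point every query operation (search,
#' suggestions, graphs, histories, recents) routes through.
#'
#' @inheritParams lims_can_read
#' @param ids character vector of entity ids.
#' @return the readable subset of \code{ids}, in input order.
#' @export
lims_filter_visible <- function(store, user, ids) {
  if (is.null(user)) return(ids)
  ids[vapply(ids, function(i) lims_can_read(store, user, i), logical(1))]
}
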