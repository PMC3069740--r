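#' Define a sample slot for a protocol
#'
#' A slot declares that experiments based on the protocol consume
#' (\code{direction = "input"}) or produce (\code{direction = "output"})
#' \code{multiplicity} samples of one type under a role name. Multiplicity 2
#' models slots like "2x PCR product"; bound samples must then be distinct.
#'
#' @param role role name, unique within a protocol.
#' @param direction "input" or "output".
#' @param sample_type sample-type name.
#' @param multiplicity positive integer.
#' @return a slot definition (list).
#' @export
lims_slot <- function(role, direction = c("input", "output"), sample_type,
                      multiplicity = 1L) {
  direction <- match.arg(direction)
  check_nonempty(role, "slot role")
  check_nonempty(sample_type, "slot sample type")
  multiplicity <- as.integer(multiplicity)
  if (is.na(multiplicity) || multiplicity < 1L)
    abort_validation("slot multiplicity must be a positive integer")
  list(role = role, direction = direction,
       sample_type = trimws(sample_type), multiplicity = multiplicity)
}

#' Define a setup or result parameter for a protocol
#'
#' @param name parameter name.
#' @param phase "setup" (recorded when the experiment is planned) or
#'   "result" (recorded as it progresses).
#' @param value_kind "text", "number", "boolean" or "date".
#' @param required must a value be resolvable (explicitly or via default) at
#'   instantiation time? Only meaningful for setup parameters.
#' @param default optional default value matching \code{value_kind}.
#' @param units free-text units for numeric parameters, e.g. "C" or "mL".
#' @return a parameter definition (list).
#' @export
lims_parameter <- function(name, phase = c("setup", "result"),
                           value_kind = c("text", "number", "boolean", "date"),
                           required = FALSE, default = NULL, units = NULL) {
  phase <- match.arg(phase)
  value_kind <- match.arg(value_kind)
  check_nonempty(name, "parameter name")
  if (!is.null(default) && !value_matches_kind(default, value_kind))
    abort_validation(sprintf("default for '%s' does not match kind %s", name, value_kind))
  list(name = name, phase = phase, value_kind = value_kind,
       required = isTRUE(required), default = default, units = units)
}

value_matches_kind <- function(value, kind) {
  switch(kind,
         text = is.character(value) && length(value) == 1L,
         number = is.numeric(value) && length(value) == 1L && !is.na(value),
         boolean = is.logical(value) && length(value) == 1L && !is.na(value),
         date = is.character(value) && length(value) == 1L &&
           grepl("^\\d{4}-\\d{2}-\\d{2}", value),
         FALSE)
}

#' Create a protocol
#'
#' Protocols are reusable experiment templates: typed input/output sample
#' slots plus setup/result parameter definitions. Once an experiment has been
#' based on a protocol it becomes immutable and undeletable; edit a copy
#' instead ([lims_copy_protocol()]).
#'
#' @inheritParams lims_get
#' @param name protocol name, unique among stored protocols.
#' @param protocol_type group label, e.g. "Processing DNA".
#' @param input_slots,output_slots lists of [lims_slot()] definitions.
#'   Measurement-only protocols have no output slots.
#' @param parameters list of [lims_parameter()] definitions.
#' @param methods methods description text.
#' @param notebook_id owning notebook; defaults to the PUBLIC notebook.
#' @param copied_from internal; id of the protocol this was copied from.
#' @return the protocol record.
#' @export
lims_create_protocol <- function(store, name, protocol_type = "General",
                                 input_slots = list(), output_slots = list(),
                                 parameters = list(), methods = "",
                                 notebook_id = NULL, copied_from = NULL) {
  check_nonempty(name, "protocol name")
  for (id in lims_ls(store, "protocol"))
    if (identical(store$objects[[id]]$name, name))
      abort_validation(sprintf("a protocol named '%s' already exists", name))
  slots <- c(lapply(input_slots, mark_dir, "input"),
             lapply(output_slots, mark_dir, "output"))
  roles <- vapply(slots, `[[`, character(1), "role")
  if (anyDuplicated(roles))
    abort_validation("slot roles must be unique within a protocol")
  for (s in slots) canonical_type(store, s$sample_type)
  params <- lapply(parameters, function(p) {
    if (is.null(p$name)) abort_validation("malformed parameter definition")
    p
  })
  pnames <- vapply(params, `[[`, character(1), "name")
  if (anyDuplicated(pnames))
    abort_validation("parameter names must be unique within a protocol")
  new_record(store, "protocol",
             name = name, notebook_id = notebook_id %||% store$public_notebook_id,
             protocol_type = protocol_type, methods_description = methods,
             input_slots = Filter(function(s) s$direction == "input", slots),
             output_slots = Filter(function(s) s$direction == "output", slots),
             parameters = params, copied_from = copied_from)
}

mark_dir <- function(slot, dir) {
  if (!identical(slot$direction, dir))
    abort_validation(sprintf("slot '%s' declared %s but passed as %s",
                             slot$role, slot$direction, dir))
  slot
}

#' Has a protocol been used by any experiment?
#'
#' Derived, never stored: true iff at least one experiment references it.
#'
#' @inheritParams lims_get
#' @param protocol_id protocol record id.
#' @return logical scalar.
#' @export
lims_protocol_used <- function(store, protocol_id) {
  length(experiments_of_protocol(store, protocol_id)) > 0L
}

experiments_of_protocol <- function(store, protocol_id) {
  ids <- lims_ls(store, "experiment")
  ids[vapply(ids, function(i) identical(store$objects[[i]]$protocol_id, protocol_id),
             logical(1))]
}

#' Copy a protocol under a new name
#'
#' The copy is a deep copy with \code{copied_from} set and is freely editable
#' regardless of whether the source has been used.
#'
#' @inheritParams lims_protocol_used
#' @param new_name name for the copy; must differ from the source name and be
#'   unique.
#' @param notebook_id notebook for the copy; defaults to the source's.
#' @return the new protocol record.
#' @export
lims_copy_protocol <- function(store, protocol_id, new_name, notebook_id = NULL) {
  src <- lims_get(store, protocol_id)
  if (src$kind != "protocol") abort_not_found(sprintf("%s is not a protocol", protocol_id))
  if (identical(new_name, src$name))
    abort_validation("the copy needs a different name")
  lims_create_protocol(store, new_name,
                       protocol_type = src$protocol_type,
                       input_slots = src$input_slots,
                       output_slots = src$output_slots,
                       parameters = src$parameters,
                       methods = src$methods_description,
                       notebook_id = notebook_id %||% src$notebook_id,
                       copied_from = src$id)
}

#' Modify or delete an unused protocol
#'
#' Both refuse if any experiment references the protocol, naming how many
#' block the change; edit a copy instead.
#'
#' @inheritParams lims_protocol_used
#' @param changes named list of replacement fields among \code{name},
#'   \code{protocol_type}, \code{methods_description}, \code{input_slots},
#'   \code{output_slots}, \code{parameters}.
#' @return the updated record ([lims_modify_protocol()]) or NULL
#'   ([lims_delete_protocol()]), invisibly.
#' @export
lims_modify_protocol <- function(store, protocol_id, changes) {
  rec <- lims_get(store, protocol_id)
  if (rec$kind != "protocol") abort_not_found(sprintf("%s is not a protocol", protocol_id))
  n_used <- length(experiments_of_protocol(store, protocol_id))
  if (n_used > 0L)
    abort_immutable(sprintf(
      "protocol '%s' has been used by %d experiment(s) and cannot be modified",
      rec$name, n_used))
  allowed <- c("name", "protocol_type", "methods_description",
               "input_slots", "output_slots", "parameters")
  bad <- setdiff(names(changes), allowed)
  if (length(bad))
    abort_validation(sprintf("cannot change field(s): %s", paste(bad, collapse = ", ")))
  rec[names(changes)] <- changes
  roles <- vapply(c(rec$input_slots, rec$output_slots), `[[`, character(1), "role")
  if (anyDuplicated(roles)) abort_validation("slot roles must be unique within a protocol")
  invisible(store_put(store, rec))
}

#' @rdname lims_modify_protocol
#' @export
lims_delete_protocol <- function(store, protocol_id) {
  rec <- lims_get(store, protocol_id)
  if (rec$kind != "protocol") abort_not_found(sprintf("%s is not a protocol", protocol_id))
  n_used <- length(experiments_of_protocol(store, protocol_id))
  if (n_used > 0L)
    abort_immutable(sprintf(
      "protocol '%s' has been used by %d experiment(s) and cannot be deleted",
      rec$name, n_used))
  rm(list = protocol_id, envir = store$objects)
  invisible(NULL)
}

#' Suggest protocols applicable to a sample
#'
#' Returns exactly those visible protocols with at least one input slot whose
#' sample type equals the sample's type, ordered most-recently-used first
#' (from the caller's access history), then alphabetically by name. This is
#' the type filter that keeps a soluble-protein sample from being offered a
#' PCR experiment.
#'
#' @inheritParams lims_get
#' @param sample_id sample record id.
#' @param user username whose visibility and usage history apply; NULL for
#'   unrestricted.
#' @return list of protocol records.
#' @export
lims_suggest_protocols <- function(store, sample_id, user = NULL) {
  smp <- lims_get(store, sample_id)
  if (smp$kind != "sample") abort_validation(sprintf("%s is not a sample", sample_id))
  if (!is.null(user) && !lims_can_read(store, user, sample_id))
    abort_permission(sprintf("user '%s' may not read %s", user, sample_id))
  key <- norm_type(smp$sample_type)
  ids <- lims_filter_visible(store, user, lims_ls(store, "protocol"))
  hit <- Filter(function(id) {
    p <- store$objects[[id]]
    any(vapply(p$input_slots, function(s) norm_type(s$sample_type) == key, logical(1)))
  }, ids)
  order_mru_alpha(store, user, hit)
}

order_mru_alpha <- function(store, user, ids) {
  if (!length(ids)) return(list())
  names_ <- vapply(ids, function(i) store$objects[[i]]$name, character(1))
  last_use <- rep(-Inf, length(ids))
  if (!is.null(user) && length(store$access_log)) {
    for (k in seq_along(store$access_log)) {
      e <- store$access_log[[k]]
      if (identical(e$user, user)) {
        j <- match(e$entity_id, ids)
        if (!is.na(j)) last_use[j] <- k
      }
    }
  }
  ids <- ids[order(-last_use, names_)]
  lapply(ids, function(i) store$objects[[i]])
}

#' Samples compatible with a protocol slot
#'
#' Exactly the readable samples whose type equals the slot's type — the
#' shortlist offered when binding an experiment input.
#'
#' @inheritParams lims_protocol_used
#' @param slot_role role name of a slot on the protocol.
#' @param user username whose visibility applies; NULL for unrestricted.
#' @return list of sample records.
#' @export
lims_compatible_samples <- function(store, protocol_id, slot_role, user = NULL) {
  prot <- lims_get(store, protocol_id)
  if (prot$kind != "protocol") abort_not_found(sprintf("%s is not a protocol", protocol_id))
  slot <- find_slot(prot, slot_role)
  key <- norm_type(slot$sample_type)
  ids <- lims_filter_visible(store, user, lims_ls(store, "sample"))
  ids <- Filter(function(i) norm_type(store$objects[[i]]$sample_type) == key, ids)
  lapply(ids, function(i) store$objects[[i]])
}

find_slot <- function(protocol, role) {
  for (s in c(protocol$input_slots, protocol$output_slots))
    if (identical(s$role, role)) return(s)
  abort_not_found(sprintf("protocol '%s' has no slot '%s'", protocol$name, role))
}

#' Instantiate an experiment from a protocol
#'
#' Validates every input binding (slot exists, sample readable, type equal,
#' multiplicity met with distinct samples) and that all required setup
#' parameters are resolvable (explicitly or via their default); then, and
#' only then, persists the experiment and creates one fresh output sample per
#' output slot per multiplicity, typed per the slot, with \code{produced_by}
#' pointing back. On any validation error nothing is persisted.
#'
#' @inheritParams lims_protocol_used
#' @param input_bindings named list: slot role -> character vector of sample
#'   ids.
#' @param setup_values named list of setup parameter values.
#' @param user acting username (NULL for unrestricted).
#' @param notebook_id notebook for the experiment and its outputs; defaults
#'   to the notebook of the first bound sample, or the protocol's.
#' @param name optional experiment name; defaults to the protocol name.
#' @return the experiment record; its \code{output_sample_ids} identify the
#'   new samples.
#' @export
lims_instantiate_experiment <- function(store, protocol_id, input_bindings = list(),
                                        setup_values = list(), user = NULL,
                                        notebook_id = NULL, name = NULL) {
  prot <- lims_get(store, protocol_id)
  if (prot$kind != "protocol") abort_not_found(sprintf("%s is not a protocol", protocol_id))
  roles <- vapply(prot$input_slots, `[[`, character(1), "role")
  extra <- setdiff(names(input_bindings), roles)
  if (length(extra))
    abort_validation(sprintf("no such input slot(s): %s", paste(extra, collapse = ", ")))
  # validate bindings
  for (slot in prot$input_slots) {
    bound <- as.character(input_bindings[[slot$role]] %||% character())
    if (length(bound) != slot$multiplicity)
      abort_validation(sprintf(
        "slot '%s' needs %d sample(s), got %d", slot$role, slot$multiplicity, length(bound)))
    if (slot$multiplicity > 1L && anyDuplicated(bound))
      abort_validation(sprintf("slot '%s' requires distinct samples", slot$role))
    for (sid in bound) {
      smp <- lims_get(store, sid)
      if (smp$kind != "sample")
        abort_validation(sprintf("%s is not a sample", sid))
      if (!is.null(user) && !lims_can_read(store, user, sid))
        abort_permission(sprintf("user '%s' may not read sample %s", user, sid))
      if (norm_type(smp$sample_type) != norm_type(slot$sample_type))
        abort_type(sprintf("slot '%s' expects type '%s' but sample %s has type '%s'",
                           slot$role, slot$sample_type, sid, smp$sample_type))
    }
  }
  # resolve setup parameters
  setup <- list()
  defs <- prot$parameters
  def_names <- vapply(defs, `[[`, character(1), "name")
  unknown <- setdiff(names(setup_values), def_names[vapply(defs, function(d) d$phase == "setup", logical(1))])
  if (length(unknown))
    abort_validation(sprintf("unknown setup parameter(s): %s", paste(unknown, collapse = ", ")))
  for (d in defs) {
    if (d$phase != "setup") next
    val <- setup_values[[d$name]] %||% d$default
    if (is.null(val)) {
      if (d$required)
        abort_validation(sprintf("required setup parameter '%s' missing and has no default", d$name))
      next
    }
    if (!value_matches_kind(val, d$value_kind))
      abort_validation(sprintf("setup parameter '%s' does not match kind %s", d$name, d$value_kind))
    setup[[d$name]] <- val
  }
  nb <- notebook_id
  if (is.null(nb)) {
    first <- unlist(input_bindings)[1]
    nb <- if (!is.null(first) && !is.na(first)) store$objects[[first]]$notebook_id
          else prot$notebook_id
  }
  check_notebook(store, nb)
  # commit: experiment, then output samples
  exp <- new_record(store, "experiment",
                    name = name %||% prot$name, notebook_id = nb, created_by = user,
                    protocol_id = prot$id,
                    input_bindings = lapply(input_bindings, as.character),
                    setup_values = setup, result_values = list(),
                    output_sample_ids = character(),
                    performed_at = lims_now(store))
  out_ids <- character()
  for (slot in prot$output_slots) {
    for (k in seq_len(slot$multiplicity)) {
      smp <- lims_create_sample(store, slot$sample_type, nb,
                                label = sprintf("%s %s%s", exp$name, slot$role,
                                                if (slot$multiplicity > 1L) paste0(" #", k) else ""),
                                owner = user)
      smp$produced_by <- exp$id
      store_put(store, smp)
      out_ids <- c(out_ids, smp$id)
    }
  }
  exp$output_sample_ids <- out_ids
  store_put(store, exp)
}

#' Record result-phase parameter values on an experiment
#'
#' Values merge into the experiment's results; re-recording a parameter
#' overwrites the value and appends an audit note to the experiment page.
#'
#' @inheritParams lims_get
#' @param experiment_id experiment record id.
#' @param result_values named list of result parameter values.
#' @param user acting username, recorded on audit notes.
#' @return the updated experiment record, invisibly.
#' @export
lims_record_results <- function(store, experiment_id, result_values, user = NULL) {
  exp <- lims_get(store, experiment_id)
  if (exp$kind != "experiment")
    abort_validation(sprintf("%s is not an experiment", experiment_id))
  prot <- lims_get(store, exp$protocol_id)
  defs <- prot$parameters
  for (nm in names(result_values)) {
    d <- NULL
    for (cand in defs) if (identical(cand$name, nm)) d <- cand
    if (is.null(d))
      abort_validation(sprintf("protocol '%s' has no parameter '%s'", prot$name, nm))
    if (d$phase != "result")
      abort_validation(sprintf("'%s' is a setup parameter; record it at instantiation", nm))
    if (!value_matches_kind(result_values[[nm]], d$value_kind))
      abort_validation(sprintf("result '%s' does not match kind %s", nm, d$value_kind))
  }
  audit_notes <- character()
  for (nm in names(result_values)) {
    if (!is.null(exp$result_values[[nm]]))
      audit_notes <- c(audit_notes,
                       sprintf("result '%s' overwritten (was %s)", nm,
                               format(exp$result_values[[nm]])))
    exp$result_values[[nm]] <- result_values[[nm]]
  }
  store_put(store, exp)
  for (msg in audit_notes) lims_annotate(store, exp$id, msg, user = user)
  invisible(lims_get(store, exp$id))
}

#' Find protocols by group label
#'
#' @inheritParams lims_get
#' @param protocol_type group label, matched case-insensitively.
#' @param user username whose visibility applies; NULL for unrestricted.
#' @return list of protocol records, alphabetical by name.
#' @export
lims_search_protocols_by_type <- function(store, protocol_type, user = NULL) {
  ids <- lims_filter_visible(store, user, lims_ls(store, "protocol"))
  ids <- Filter(function(i)
    norm_type(store$objects[[i]]$protocol_type) == norm_type(protocol_type), ids)
  nm <- vapply(ids, function(i) store$objects[[i]]$name, character(1))
  lapply(ids[order(nm)], function(i) store$objects[[i]])
}
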