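# Biological complexes are declared over two or more targets; detection then
# flags any sample whose provenance links it to all of a complex's targets
# (typically the output of a complexation or co-expression experiment), so
# that work on the sample counts as work toward the complex.

#' Declare a biological complex
#'
#' A complex represents a real biological assembly built from two or more
#' targets. Duplicated target ids record homo-oligomer stoichiometry (a
#' homodimer is \code{c(A, A)}).
#'
#' @inheritParams lims_get
#' @param target_ids character vector (length >= 2; duplicates allowed) of
#'   target ids.
#' @param name complex name.
#' @param notebook_id owning notebook.
#' @param user acting username; all component targets must be readable.
#' @return the complex record.
#' @export
lims_declare_complex <- function(store, target_ids, name, notebook_id, user = NULL) {
  if (length(target_ids) < 2L)
    abort_validation("a complex needs two or more component targets")
  check_nonempty(name, "complex name")
  check_notebook(store, notebook_id)
  for (tid in target_ids) {
    rec <- lims_get(store, tid)
    if (rec$kind != "target") abort_validation(sprintf("%s is not a target", tid))
    if (!is.null(user) && !lims_can_read(store, user, tid))
      abort_permission(sprintf("user '%s' may not read target %s", user, tid))
  }
  new_record(store, "complex", name = name, notebook_id = notebook_id,
             created_by = user,
             component_target_ids = as.list(as.character(target_ids)))
}

#' Targets linked to a sample
#'
#' The union of target ids reachable through the sample's own construct link
#' and through the construct links of all its ancestor samples — the output
#' of a complexation experiment over proteins of targets A and B is linked
#' to both.
#'
#' @inheritParams lims_get
#' @param sample_id sample record id.
#' @return character vector of target ids (possibly empty).
#' @export
lims_targets_of_sample <- function(store, sample_id) {
  smp <- lims_get(store, sample_id)
  if (smp$kind != "sample") abort_validation(sprintf("%s is not a sample", sample_id))
  samples <- sample_id
  for (e in ancestor_experiments(store, sample_id))
    samples <- c(samples, unlist(store$objects[[e]]$input_bindings),
                 unlist(store$objects[[e]]$output_sample_ids))
  targets <- character()
  for (sid in unique(samples)) {
    cid <- store$objects[[sid]]$construct_id
    if (!is.null(cid) && store_has(store, cid))
      targets <- c(targets, unlist(store$objects[[cid]]$target_ids))
  }
  sort(unique(targets))
}

#' Detect declared complexes a sample may realize
#'
#' Returns every visible declared complex whose component target set is a
#' subset of [lims_targets_of_sample()]. Matching uses target \emph{sets}
#' (stoichiometry is ignored), and a sample must be linked to at least two
#' distinct targets — except that homo-oligomer complexes (one distinct
#' component) match samples produced by a Complexation-protocol experiment
#' over their single target (controlled by \code{match_homo_oligomers}).
#'
#' @inheritParams lims_targets_of_sample
#' @param user username whose visibility applies; NULL for unrestricted.
#' @param match_homo_oligomers enable the homo-oligomer rule above.
#' @return list of complex records.
#' @export
lims_detect_complex_candidates <- function(store, sample_id, user = NULL,
                                           match_homo_oligomers = TRUE) {
  linked <- lims_targets_of_sample(store, sample_id)
  smp <- lims_get(store, sample_id)
  from_complexation <- FALSE
  if (!is.null(smp$produced_by) && store_has(store, smp$produced_by)) {
    prot <- store$objects[[store$objects[[smp$produced_by]]$protocol_id]]
    from_complexation <- !is.null(prot) && norm_type(prot$name) == "complexation"
  }
  ids <- lims_filter_visible(store, user, lims_ls(store, "complex"))
  hits <- Filter(function(id) {
    comp <- unique(unlist(store$objects[[id]]$component_target_ids))
    if (length(comp) >= 2L)
      length(linked) >= 2L && all(comp %in% linked)
    else
      isTRUE(match_homo_oligomers) && from_complexation && all(comp %in% linked)
  }, ids)
  lapply(hits, function(id) store$objects[[id]])
}
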