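#' Create a lab notebook
#'
#' Notebooks are the grouping and access-control unit: every page record
#' (target, construct, sample, experiment, protocol, complex, plate) belongs
#' to exactly one notebook, and read/write rights are granted per notebook to
#' user groups (see [lims_grant()]).
#'
#' @inheritParams lims_get
#' @param name non-empty notebook name.
#' @param description free text.
#' @return the notebook record.
#' @export
lims_create_notebook <- function(store, name, description = "") {
  check_nonempty(name, "notebook name")
  new_record(store, "notebook", name = name, description = description)
}

#' Register a sample type
#'
#' Sample types ("PCR product", "Soluble protein", ...) constrain which
#' samples can feed which experiments. Names compare case-insensitively
#' after whitespace normalization; re-registering an existing name returns
#' the existing record.
#'
#' @inheritParams lims_get
#' @param name type name.
#' @param description free text.
#' @return the sample-type record.
#' @export
lims_sample_type <- function(store, name, description = "") {
  check_nonempty(name, "sample type name")
  key <- norm_type(name)
  cached <- store$type_cache[[key]]
  if (!is.null(cached) && store_has(store, cached))
    return(store$objects[[cached]])
  for (id in lims_ls(store, "sample_type")) {
    rec <- store$objects[[id]]
    if (norm_type(rec$name) == key) {
      store$type_cache[[key]] <- id
      return(rec)
    }
  }
  rec <- new_record(store, "sample_type", name = trimws(name),
                    description = description)
  store$type_cache[[key]] <- rec$id
  rec
}

# Canonical (first-registered) spelling of a type name; registers on demand.
canonical_type <- function(store, name) lims_sample_type(store, name)$name

#' Create a sample
#'
#' @inheritParams lims_get
#' @param sample_type type name (registered on first use).
#' @param notebook_id owning notebook.
#' @param label short human label.
#' @param location free text, or a well reference like "plate-0001:A1".
#' @param owner username.
#' @param description free text.
#' @param creation_date ISO date string; defaults to the store clock.
#' @return the sample record.
#' @export
lims_create_sample <- function(store, sample_type, notebook_id,
                               label = "", location = "", owner = NULL,
                               description = "", creation_date = NULL) {
  check_notebook(store, notebook_id)
  stype <- canonical_type(store, sample_type)
  new_record(store, "sample",
             name = if (nzchar(label)) label else stype,
             notebook_id = notebook_id, created_by = owner,
             sample_type = stype,
             creation_date = creation_date %||% lims_now(store),
             label = label, location = location, owner = owner,
             description = description,
             produced_by = NULL, construct_id = NULL)
}

#' Create a protein target
#'
#' A target describes a full-length protein (the translation of a complete
#' open reading frame) and/or its DNA sequence, and anchors external
#' references and default access control for all work derived from it.
#' Construct design requires the DNA sequence.
#'
#' @inheritParams lims_get
#' @param name target name.
#' @param notebook_id owning notebook.
#' @param protein_sequence optional amino-acid string (IUPAC one-letter).
#' @param dna_sequence optional nucleotide string (IUPAC).
#' @param source_accession optional \code{list(database=, accession=)}.
#' @param description free text.
#' @return the target record.
#' @export
lims_create_target <- function(store, name, notebook_id,
                               protein_sequence = NULL, dna_sequence = NULL,
                               source_accession = NULL, description = "") {
  check_nonempty(name, "target name")
  check_notebook(store, notebook_id)
  if (is.null(protein_sequence) && is.null(dna_sequence))
    abort_validation("a target needs a protein and/or a DNA sequence")
  if (!is.null(protein_sequence)) protein_sequence <- check_aa(protein_sequence)
  if (!is.null(dna_sequence)) dna_sequence <- check_dna(dna_sequence)
  rec <- new_record(store, "target",
                    name = name, notebook_id = notebook_id,
                    protein_sequence = protein_sequence,
                    dna_sequence = dna_sequence,
                    source_accession = source_accession,
                    description = description)
  if (!is.null(source_accession))
    rec <- lims_add_external_ref(store, rec$id,
                                 source_accession$database,
                                 source_accession$accession)
  rec
}

#' Append a free-text note to a page record
#'
#' @inheritParams lims_get
#' @param id id of any page-carrying record.
#' @param note non-empty text.
#' @param user optional username recorded with the note.
#' @return the updated record, invisibly.
#' @export
lims_annotate <- function(store, id, note, user = NULL) {
  check_nonempty(note, "note")
  rec <- lims_get(store, id)
  check_page(rec)
  rec$notes[[length(rec$notes) + 1L]] <-
    list(time = lims_now(store), user = user, text = note)
  invisible(store_put(store, rec))
}

#' Attach a file to a page record
#'
#' The payload is stored verbatim and retrievable byte-identical via
#' [lims_get_attachment()]. Two attachments may share a filename; they are
#' distinguished by attachment id.
#'
#' @inheritParams lims_annotate
#' @param filename original file name.
#' @param media_type MIME type, e.g. "image/png".
#' @param payload raw vector (non-empty).
#' @return the updated record, invisibly; the new attachment id is in
#'   \code{attr(, "attachment_id")}.
#' @export
lims_attach_file <- function(store, id, filename, media_type, payload) {
  if (!is.raw(payload) || length(payload) == 0L)
    abort_validation("attachment payload must be a non-empty raw vector")
  check_nonempty(filename, "filename")
  rec <- lims_get(store, id)
  check_page(rec)
  att_id <- sprintf("%s/att-%d", rec$id, length(rec$attachments) + 1L)
  rec$attachments[[length(rec$attachments) + 1L]] <-
    list(attachment_id = att_id, filename = filename,
         media_type = media_type, payload = payload)
  rec <- store_put(store, rec)
  structure(invisible(rec), attachment_id = att_id)
}

#' Retrieve an attachment payload
#'
#' @inheritParams lims_get
#' @param attachment_id id returned by [lims_attach_file()].
#' @return a list with filename, media_type and the raw payload.
#' @export
lims_get_attachment <- function(store, attachment_id) {
  page_id <- sub("/att-\\d+$", "", attachment_id)
  rec <- lims_get(store, page_id)
  for (a in rec$attachments)
    if (identical(a$attachment_id, attachment_id)) return(a)
  abort_not_found(sprintf("no such attachment: %s", attachment_id))
}

#' Add an external database reference to a page record
#'
#' @inheritParams lims_annotate
#' @param database database name, e.g. "UniProt".
#' @param accession accession string.
#' @return the updated record, invisibly.
#' @export
lims_add_external_ref <- function(store, id, database, accession) {
  check_nonempty(database, "database")
  check_nonempty(accession, "accession")
  rec <- lims_get(store, id)
  check_page(rec)
  for (r in rec$external_refs)
    if (identical(r$database, database) && identical(r$accession, accession))
      abort_duplicate(sprintf("reference %s:%s already present", database, accession))
  rec$external_refs[[length(rec$external_refs) + 1L]] <-
    list(database = database, accession = accession)
  invisible(store_put(store, rec))
}

check_nonempty <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || !nzchar(trimws(x)))
    abort_validation(sprintf("%s must be a non-empty string", what))
  invisible(x)
}

check_notebook <- function(store, notebook_id) {
  rec <- lims_get(store, notebook_id)
  if (rec$kind != "notebook")
    abort_validation(sprintf("%s is not a notebook", notebook_id))
  invisible(rec)
}

check_page <- function(rec) {
  if (!rec$kind %in% PAGE_KINDS)
    abort_validation(sprintf("%s records carry no notebook-page properties", rec$kind))
  invisible(rec)
}
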