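# Target registration from local sequence flat files. FASTA is read with
# Biostrings; GenBank and EMBL records are read by a minimal flat-file
# scanner (LOCUS/ID header, ACCESSION/AC, DEFINITION/DE, the first CDS
# feature's /translation, ORIGIN/SQ sequence block). Network accession fetch
# is deliberately out of scope: records are imported from files only.

#' Import a target from a FASTA, GenBank or EMBL file
#'
#' Creates a [lims_create_target()] record with sequences, accession and
#' description parsed from the file, and an external reference to the source
#' database. For a GenBank/EMBL record the protein sequence is taken from the
#' first CDS \code{/translation} qualifier when present, otherwise the full
#' sequence's frame-0 translation. For FASTA the alphabet decides whether the
#' record is DNA or protein.
#'
#' @inheritParams lims_get
#' @param path path to the flat file.
#' @param notebook_id notebook to file the target in.
#' @param format "auto" (default; sniffs the first non-blank line),
#'   "fasta", "genbank" or "embl".
#' @return the new target record.
#' @export
lims_import_target <- function(store, path, notebook_id,
                               format = c("auto", "fasta", "genbank", "embl")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_not_found(sprintf("no such file: %s", path))
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) abort_format("file is not readable text"))
  first <- lines[nzchar(trimws(lines))][1]
  if (is.na(first)) abort_format("file is empty")
  if (format == "auto") {
    format <- if (startsWith(first, ">")) "fasta"
      else if (grepl("^LOCUS", first)) "genbank"
      else if (grepl("^ID\\s", first)) "embl"
      else abort_format("unrecognized sequence file format")
  }
  rec <- switch(format,
                fasta = parse_fasta_record(path),
                genbank = parse_flatfile(lines, "genbank"),
                embl = parse_flatfile(lines, "embl"))
  if (is.null(rec$dna) && is.null(rec$protein))
    abort_validation("record contains no sequence")
  lims_create_target(store, rec$name, notebook_id,
                     protein_sequence = rec$protein,
                     dna_sequence = rec$dna,
                     source_accession = rec$accession,
                     description = rec$description %||% "")
}

parse_fasta_record <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort_format("not a parseable FASTA file"))
  if (length(set) == 0L) abort_format("FASTA file holds no records")
  header <- names(set)[1]
  seq <- toupper(as.character(set[[1]]))
  if (!nzchar(seq)) abort_validation("FASTA record has an empty sequence")
  name <- sub("\\s.*$", "", header)
  desc <- trimws(sub("^\\S+\\s*", "", header))
  is_dna <- !grepl("[^ACGTUNRYSWKMBDHV]", seq)
  if (is_dna) {
    list(name = name, description = desc, dna = gsub("U", "T", seq),
         protein = NULL, accession = NULL)
  } else {
    list(name = name, description = desc, dna = NULL,
         protein = seq, accession = NULL)
  }
}

parse_flatfile <- function(lines, dialect) {
  db <- if (dialect == "genbank") "GenBank" else "EMBL"
  acc_tag <- if (dialect == "genbank") "^ACCESSION\\s+(\\S+)" else "^AC\\s+(\\S+?);?\\s*$"
  def_tag <- if (dialect == "genbank") "^DEFINITION\\s+(.*)$" else "^DE\\s+(.*)$"
  seq_start <- if (dialect == "genbank") "^ORIGIN" else "^SQ\\s"
  name <- accession <- NULL
  desc <- character()
  if (dialect == "genbank") {
    m <- regmatches(lines[1], regexec("^LOCUS\\s+(\\S+)", lines[1]))[[1]]
    if (length(m) == 2L) name <- m[2]
  } else {
    m <- regmatches(lines[1], regexec("^ID\\s+([^;\\s]+)", lines[1]))[[1]]
    if (length(m) == 2L) name <- m[2]
  }
  if (is.null(name)) abort_format(sprintf("malformed %s header line", db))
  in_seq <- FALSE
  seq_chunks <- character()
  translation <- NULL
  in_translation <- FALSE
  for (ln in lines[-1]) {
    if (grepl(seq_start, ln)) { in_seq <- TRUE; next }
    if (in_seq) {
      if (grepl("^//", ln)) break
      seq_chunks <- c(seq_chunks, gsub("[^A-Za-z]", "", ln))
      next
    }
    m <- regmatches(ln, regexec(acc_tag, ln))[[1]]
    if (length(m) == 2L && is.null(accession)) accession <- m[2]
    m <- regmatches(ln, regexec(def_tag, ln))[[1]]
    if (length(m) == 2L) desc <- c(desc, m[2])
    if (in_translation) {
      frag <- trimws(ln)
      frag <- sub("^/?", "", frag)
      end <- grepl("\"", frag)
      translation <- paste0(translation, gsub("[^A-Za-z]", "", frag))
      if (end) in_translation <- FALSE
      next
    }
    tm <- regmatches(ln, regexec("/translation=\"([A-Za-z]*)(\"?)", ln))[[1]]
    if (length(tm) >= 2L && is.null(translation)) {
      translation <- tm[2]
      in_translation <- !identical(tm[3], "\"")
    }
  }
  dna <- toupper(paste(seq_chunks, collapse = ""))
  if (!nzchar(dna)) dna <- NULL
  protein <- if (!is.null(translation) && nzchar(translation)) toupper(translation)
             else if (!is.null(dna) && nchar(dna) >= 3L) translate_dna(dna)
  if (!is.null(protein) && !nzchar(protein)) protein <- NULL
  list(name = name,
       description = paste(desc, collapse = " "),
       dna = dna, protein = protein,
       accession = if (!is.null(accession)) list(database = db, accession = accession))
}
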