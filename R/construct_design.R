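# Construct design: a windowed region of a target protein, optional
# N-terminal Met and affinity tags, Tm-driven PCR primer suggestion, and the
# no-input hybrid experiment that yields the template and primer samples
# needed to start a PCR. Residue indices are 1-based inclusive (the
# biologist's convention); DNA is handled internally as 0-based half-open
# offsets, converted in codon_window().

#' Define an affinity/solubility tag
#'
#' @param name tag name, e.g. "His6".
#' @param aa_sequence tag amino-acid sequence.
#' @param terminus "N" or "C".
#' @param cleavable can the tag be removed after purification? Cleavable
#'   tags appear in the expressed protein but not the final protein.
#' @return a tag definition (list).
#' @export
lims_tag <- function(name, aa_sequence, terminus = c("N", "C"), cleavable = FALSE) {
  terminus <- match.arg(terminus)
  check_nonempty(name, "tag name")
  aa_sequence <- check_aa(aa_sequence, "tag sequence")
  list(name = name, aa_sequence = aa_sequence, terminus = terminus,
       cleavable = isTRUE(cleavable))
}

#' Common tags
#'
#' Ready-made [lims_tag()] definitions: a hexahistidine tag for either
#' terminus.
#'
#' @param terminus "N" or "C".
#' @param cleavable see [lims_tag()].
#' @return a tag definition.
#' @export
tag_his6 <- function(terminus = "N", cleavable = TRUE)
  lims_tag("His6", "HHHHHH", terminus, cleavable)

# One codon per amino acid for back-translating tag/Met add-ons
# (high-usage E. coli codons; fixed so primer add-ons are deterministic).
BACKTRANSLATION_CODONS <- c(
  A = "GCG", R = "CGT", N = "AAC", D = "GAT", C = "TGC", Q = "CAG",
  E = "GAA", G = "GGC", H = "CAT", I = "ATT", L = "CTG", K = "AAA",
  M = "ATG", F = "TTT", P = "CCG", S = "AGC", T = "ACC", W = "TGG",
  Y = "TAT", V = "GTG", `*` = "TAA")

backtranslate <- function(aa) {
  if (!nzchar(aa)) return("")
  letters_ <- strsplit(aa, "")[[1]]
  bad <- setdiff(letters_, names(BACKTRANSLATION_CODONS))
  if (length(bad))
    abort_alphabet(sprintf("cannot back-translate residue(s): %s",
                           paste(unique(bad), collapse = ", ")))
  paste(BACKTRANSLATION_CODONS[letters_], collapse = "")
}

# 0-based offset of the first coding base in the target DNA. When the target
# carries a protein sequence, the frame whose translation contains it wins;
# otherwise frame 0 from base 1 is assumed.
locate_cds <- function(target) {
  if (is.null(target$dna_sequence))
    abort_missing_seq(sprintf("target '%s' has no DNA sequence", target$name))
  if (is.null(target$protein_sequence)) return(0L)
  for (frame in 0:2) {
    if (nchar(target$dna_sequence) - frame < 3L) next
    aa <- translate_dna(target$dna_sequence, frame, to_stop = FALSE)
    pos <- regexpr(target$protein_sequence, aa, fixed = TRUE)
    if (pos > 0L) return(frame + 3L * (as.integer(pos) - 1L))
  }
  abort_validation(sprintf(
    "target '%s': protein sequence not found in any reading frame of its DNA",
    target$name))
}

# DNA substring covering residues start_aa..stop_aa (1-based inclusive).
codon_window <- function(dna, cds_offset, start_aa, stop_aa) {
  from <- cds_offset + 3L * (start_aa - 1L)      # 0-based start
  to <- cds_offset + 3L * stop_aa                # 0-based past-the-end
  if (to > nchar(dna))
    abort_range("requested residue window runs past the end of the target DNA")
  substr(dna, from + 1L, to)
}

target_protein <- function(target) {
  if (!is.null(target$protein_sequence)) return(target$protein_sequence)
  translate_dna(target$dna_sequence, 0L, to_stop = TRUE)
}

#' Design a PCR primer pair for a construct region
#'
#' The forward annealing region is a prefix of the coding region starting at
#' the first codon of \code{start_aa}; the reverse annealing region is the
#' reverse complement of a suffix ending at the last codon of
#' \code{stop_aa}. Each starts at 18 nt and is extended 3'-wards in 1 nt
#' steps until its melting temperature reaches \code{target_tm} or 35 nt is
#' hit (then flagged \code{tm_reached = FALSE}). 5' add-ons — the Met codon,
#' back-translated tag codons and (for the reverse primer, when no C-tag is
#' present and \code{add_stop} is TRUE) a TAA stop codon — sit outside the
#' annealing region and are excluded from the Tm.
#'
#' @inheritParams lims_get
#' @param construct_id construct record id; primers are stored back on the
#'   construct.
#' @param target_tm target melting temperature in degrees C (default 60).
#' @param method Tm estimator, see [melting_temperature()].
#' @return list with elements \code{forward} and \code{reverse}, each a
#'   primer record (sequence 5'->3', orientation, anneal_len, tm_c, method,
#'   tm_reached).
#' @export
lims_design_primers <- function(store, construct_id, target_tm = 60,
                                method = c("nearest_neighbor", "wallace")) {
  method <- match.arg(method)
  con <- lims_get(store, construct_id)
  if (con$kind != "construct")
    abort_validation(sprintf("%s is not a construct", construct_id))
  tgt <- lims_get(store, con$target_ids[[1]])
  pair <- primer_pair(tgt, con$start_aa, con$stop_aa, con$add_n_met, con$tags,
                      target_tm, method, add_stop = con$add_stop %||% TRUE)
  con$forward_primer <- pair$forward
  con$reverse_primer <- pair$reverse
  store_put(store, con)
  pair
}

primer_pair <- function(target, start_aa, stop_aa, add_n_met, tags,
                        target_tm, method, add_stop = TRUE) {
  cds <- locate_cds(target)
  region <- codon_window(target$dna_sequence, cds, start_aa, stop_aa)
  if (nchar(region) < 18L)
    abort_validation("coding region shorter than the 18 nt minimum primer length")
  region_aa_first <- translate_dna(substr(region, 1L, 3L), to_stop = FALSE)
  ntag_aa <- paste(vapply(Filter(function(t) t$terminus == "N", tags),
                          `[[`, character(1), "aa_sequence"), collapse = "")
  ctag_aa <- paste(vapply(Filter(function(t) t$terminus == "C", tags),
                          `[[`, character(1), "aa_sequence"), collapse = "")
  fwd_addon <- paste0(
    if (isTRUE(add_n_met) && region_aa_first != "M") "ATG" else "",
    backtranslate(ntag_aa))
  rev_tail_sense <- paste0(backtranslate(ctag_aa),
                           if (isTRUE(add_stop) && !nzchar(ctag_aa)) "TAA" else "")
  fwd <- grow_primer(region, target_tm, method)
  rev <- grow_primer(reverse_complement(region), target_tm, method)
  list(
    forward = list(
      sequence = paste0(fwd_addon, fwd$anneal), orientation = "forward",
      anneal_len = fwd$len, tm_c = fwd$tm, method = method,
      target_tm = target_tm, tm_reached = fwd$reached),
    reverse = list(
      sequence = paste0(if (nzchar(rev_tail_sense)) reverse_complement(rev_tail_sense) else "",
                        rev$anneal),
      orientation = "reverse",
      anneal_len = rev$len, tm_c = rev$tm, method = method,
      target_tm = target_tm, tm_reached = rev$reached))
}

# Extend a prefix of `template` from 18 nt until Tm >= target or 35 nt /
# template end; first length meeting the target wins.
grow_primer <- function(template, target_tm, method) {
  max_len <- min(35L, nchar(template))
  len <- min(18L, max_len)
  repeat {
    anneal <- substr(template, 1L, len)
    tm <- melting_temperature(anneal, method)
    if (tm >= target_tm || len >= max_len) break
    len <- len + 1L
  }
  list(anneal = anneal, len = len, tm = tm, reached = tm >= target_tm)
}

#' Design a construct and its hybrid no-input experiment
#'
#' Stores a construct (window \code{start_aa..stop_aa} of the target,
#' optional N-terminal Met, tags, computed expressed and final protein
#' sequences, suggested primers) and records the design as a special hybrid
#' experiment with no input samples and three outputs: one Template sample
#' and two Primers samples (forward and reverse), all carrying the construct
#' id — everything needed to move straight on to a PCR experiment.
#'
#' The expressed protein is \code{[Met] + N-tags + region + C-tags} (the Met
#' only when requested and the region does not already start with one); the
#' final protein is the expressed protein with cleavable tags removed.
#'
#' @inheritParams lims_get
#' @param target_id target record id; the target must have a DNA sequence.
#' @param start_aa,stop_aa 1-based inclusive residue window into the
#'   target protein.
#' @param add_n_met prepend an N-terminal methionine if the region lacks one?
#' @param tags list of [lims_tag()] definitions.
#' @param target_tm,method see [lims_design_primers()].
#' @param notebook_id notebook for the construct and samples; defaults to
#'   the target's notebook.
#' @param user acting username.
#' @param name construct name; defaults to "<target> (start-stop)".
#' @param add_stop append a TAA stop codon via the reverse primer when the
#'   construct has no C-terminal tag?
#' @return list with elements \code{construct}, \code{experiment} and
#'   \code{samples} (template, forward primer, reverse primer records).
#' @export
lims_design_construct <- function(store, target_id, start_aa, stop_aa,
                                  add_n_met = FALSE, tags = list(),
                                  target_tm = 60,
                                  method = c("nearest_neighbor", "wallace"),
                                  notebook_id = NULL, user = NULL, name = NULL,
                                  add_stop = TRUE) {
  method <- match.arg(method)
  tgt <- lims_get(store, target_id)
  if (tgt$kind != "target") abort_validation(sprintf("%s is not a target", target_id))
  if (!is.null(user) && !lims_can_read(store, user, target_id))
    abort_permission(sprintf("user '%s' may not read target %s", user, target_id))
  prot <- target_protein(tgt)
  start_aa <- as.integer(start_aa); stop_aa <- as.integer(stop_aa)
  if (is.na(start_aa) || is.na(stop_aa) || start_aa < 1L || start_aa > stop_aa)
    abort_range("need 1 <= start_aa <= stop_aa")
  if (stop_aa > nchar(prot))
    abort_range(sprintf("stop_aa %d exceeds target protein length %d",
                        stop_aa, nchar(prot)))
  region <- substr(prot, start_aa, stop_aa)
  ntag_aa <- paste(vapply(Filter(function(t) t$terminus == "N", tags),
                          `[[`, character(1), "aa_sequence"), collapse = "")
  ctag_aa <- paste(vapply(Filter(function(t) t$terminus == "C", tags),
                          `[[`, character(1), "aa_sequence"), collapse = "")
  keep <- function(term) paste(vapply(
    Filter(function(t) t$terminus == term && !t$cleavable, tags),
    `[[`, character(1), "aa_sequence"), collapse = "")
  met <- if (isTRUE(add_n_met) && substr(region, 1L, 1L) != "M") "M" else ""
  expressed <- paste0(met, ntag_aa, region, ctag_aa)
  final <- paste0(met, keep("N"), region, keep("C"))
  nb <- notebook_id %||% tgt$notebook_id
  check_notebook(store, nb)
  con <- new_record(store, "construct",
                    name = name %||% sprintf("%s (%d-%d)", tgt$name, start_aa, stop_aa),
                    notebook_id = nb, created_by = user,
                    target_ids = list(target_id),
                    start_aa = start_aa, stop_aa = stop_aa,
                    add_n_met = isTRUE(add_n_met), tags = tags,
                    add_stop = isTRUE(add_stop),
                    expressed_protein = expressed, final_protein = final,
                    forward_primer = NULL, reverse_primer = NULL)
  pair <- lims_design_primers(store, con$id, target_tm, method)
  prot_id <- construct_design_protocol(store)$id
  exp <- lims_instantiate_experiment(store, prot_id, input_bindings = list(),
                                     user = user, notebook_id = nb,
                                     name = sprintf("Construct design: %s", con$name))
  samples <- lapply(exp$output_sample_ids, function(sid) {
    s <- lims_get(store, sid)
    s$construct_id <- con$id
    store_put(store, s)
  })
  # outputs arrive template-first, then the two primer samples
  samples[[1]]$label <- sprintf("%s template", con$name)
  samples[[2]]$label <- sprintf("%s forward primer", con$name)
  samples[[2]]$description <- pair$forward$sequence
  samples[[3]]$label <- sprintf("%s reverse primer", con$name)
  samples[[3]]$description <- pair$reverse$sequence
  for (s in samples) store_put(store, s)
  list(construct = lims_get(store, con$id), experiment = lims_get(store, exp$id),
       samples = lapply(samples, function(s) lims_get(store, s$id)))
}

# The special hybrid protocol behind construct design: no inputs, outputs a
# Template and two Primers samples. Created lazily in the PUBLIC notebook.
construct_design_protocol <- function(store) {
  for (id in lims_ls(store, "protocol")) {
    p <- store$objects[[id]]
    if (identical(p$name, "Construct design")) return(p)
  }
  lims_create_protocol(store, "Construct design",
                       protocol_type = "Construct design",
                       input_slots = list(),
                       output_slots = list(
                         lims_slot("template", "output", "Template"),
                         lims_slot("primers", "output", "Primers", 2L)),
                       methods = "Virtual experiment: construct definition and primer design.",
                       notebook_id = store$public_notebook_id)
}

well_labels <- function(rows, cols) {
  if (rows > 26L) abort_validation("plates with more than 26 rows are not supported")
  as.vector(t(outer(LETTERS[seq_len(rows)], seq_len(cols), paste0)))
}

#' Lay out constructs on a plate
#'
#' Fills wells row-major (A1, A2, ... A12, B1, ...) on an 8x12 plate by
#' default.
#'
#' @inheritParams lims_get
#' @param construct_ids character vector of construct ids,
#'   length <= rows*cols.
#' @param rows,cols plate dimensions.
#' @param notebook_id notebook for the plate record; defaults to the first
#'   construct's notebook.
#' @param name plate name.
#' @return the plate record; \code{$wells} maps well label to construct id.
#' @export
lims_layout_constructs <- function(store, construct_ids, rows = 8L, cols = 12L,
                                   notebook_id = NULL, name = "Construct plate") {
  if (length(construct_ids) == 0L) abort_validation("no constructs to lay out")
  if (length(construct_ids) > rows * cols)
    abort_capacity(sprintf("%d constructs exceed plate capacity %d",
                           length(construct_ids), rows * cols))
  for (cid in construct_ids) {
    rec <- lims_get(store, cid)
    if (rec$kind != "construct") abort_validation(sprintf("%s is not a construct", cid))
  }
  wells <- stats::setNames(as.list(construct_ids),
                           well_labels(rows, cols)[seq_along(construct_ids)])
  nb <- notebook_id %||% lims_get(store, construct_ids[[1]])$notebook_id
  new_record(store, "plate", name = name, notebook_id = nb,
             rows = as.integer(rows), cols = as.integer(cols),
             wells = wells, plate_kind = "construct")
}

#' Derive template and primer plates from a construct plate
#'
#' For every construct on the plate, places its template sample and its
#' forward/reverse primer samples in the \emph{same well label} on three new
#' plates, so ordered primers stay matched to their templates. Requires each
#' construct's design experiment to have been run
#' ([lims_design_construct()]).
#'
#' @inheritParams lims_get
#' @param plate_id a construct plate from [lims_layout_constructs()].
#' @return list of plate records: \code{template}, \code{forward_primers},
#'   \code{reverse_primers}.
#' @export
lims_derive_plates <- function(store, plate_id) {
  plate <- lims_get(store, plate_id)
  if (plate$kind != "plate" || !identical(plate$plate_kind, "construct"))
    abort_validation(sprintf("%s is not a construct plate", plate_id))
  tpl <- fwd <- rev_ <- list()
  for (well in names(plate$wells)) {
    cid <- plate$wells[[well]]
    trio <- construct_output_samples(store, cid)
    tpl[[well]] <- trio$template
    fwd[[well]] <- trio$forward
    rev_[[well]] <- trio$reverse
  }
  mk <- function(wells, kind, label) {
    new_record(store, "plate", name = paste(plate$name, "-", label),
               notebook_id = plate$notebook_id,
               rows = plate$rows, cols = plate$cols,
               wells = wells, plate_kind = kind)
  }
  list(template = mk(tpl, "template", "templates"),
       forward_primers = mk(fwd, "primer_forward", "forward primers"),
       reverse_primers = mk(rev_, "primer_reverse", "reverse primers"))
}

construct_output_samples <- function(store, construct_id) {
  tpl <- fwd <- rev_ <- NULL
  for (sid in lims_ls(store, "sample")) {
    s <- store$objects[[sid]]
    if (!identical(s$construct_id, construct_id)) next
    if (norm_type(s$sample_type) == "template" && is.null(tpl)) tpl <- sid
    if (norm_type(s$sample_type) == "primers") {
      if (grepl("forward", s$label)) fwd <- sid else if (grepl("reverse", s$label)) rev_ <- sid
    }
  }
  if (is.null(tpl) || is.null(fwd) || is.null(rev_))
    abort_validation(sprintf(
      "construct %s has no template/primer samples; run its design experiment first",
      construct_id))
  list(template = tpl, forward = fwd, reverse = rev_)
}

#' Primer order sheet for a construct plate
#'
#' @inheritParams lims_derive_plates
#' @return a data.frame with columns well, construct, primer
#'   (forward/reverse), sequence (5'->3') and tm_c — ready for
#'   \code{write.csv()}.
#' @export
lims_primer_orders <- function(store, plate_id) {
  plate <- lims_get(store, plate_id)
  if (plate$kind != "plate" || !identical(plate$plate_kind, "construct"))
    abort_validation(sprintf("%s is not a construct plate", plate_id))
  rows <- list()
  for (well in names(plate$wells)) {
    con <- lims_get(store, plate$wells[[well]])
    for (ori in c("forward", "reverse")) {
      p <- con[[paste0(ori, "_primer")]]
      if (is.null(p))
        abort_validation(sprintf("construct %s has no designed primers", con$id))
      rows[[length(rows) + 1L]] <- data.frame(
        well = well, construct = con$name, primer = ori,
        sequence = p$sequence, tm_c = p$tm_c, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
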