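# Sequence primitives shared by target import, construct design and the
# fixture generator. Alphabet checks and translation delegate to Biostrings;
# melting temperatures are computed here (Wallace rule and a unified
# nearest-neighbor model).

check_dna <- function(x, what = "DNA sequence") {
  if (!is.character(x) || length(x) != 1L || !nzchar(x))
    abort_validation(sprintf("%s must be a non-empty string", what))
  x <- toupper(gsub("\\s", "", x))
  ok <- tryCatch({ Biostrings::DNAString(x); TRUE },
                 error = function(e) FALSE)
  if (!ok) abort_alphabet(sprintf("%s contains non-IUPAC characters", what))
  x
}

check_aa <- function(x, what = "protein sequence") {
  if (!is.character(x) || length(x) != 1L || !nzchar(x))
    abort_validation(sprintf("%s must be a non-empty string", what))
  x <- toupper(gsub("\\s", "", x))
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYXBZJUO*]", x))
    abort_alphabet(sprintf("%s contains non-IUPAC characters", what))
  x
}

#' Translate a DNA sequence
#'
#' Standard-genetic-code translation of the given reading frame. Any
#' incomplete trailing codon is dropped.
#'
#' @param dna nucleotide string (IUPAC; unambiguous bases are translated,
#'   ambiguous codons become "X").
#' @param frame reading-frame offset: 0, 1 or 2 skipped leading bases.
#' @param to_stop if TRUE (default), translation stops before the first stop
#'   codon; if FALSE, stops are reported as "*".
#' @return amino-acid string.
#' @export
translate_dna <- function(dna, frame = 0L, to_stop = TRUE) {
  dna <- check_dna(dna)
  if (!frame %in% 0:2) abort_validation("frame must be 0, 1 or 2")
  body <- substr(dna, frame + 1L, nchar(dna))
  n <- nchar(body) %/% 3L * 3L
  if (n < 3L) abort_validation("fewer than one complete codon in this frame")
  body <- substr(body, 1L, n)
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(body), if.fuzzy.codon = "solve",
                          no.init.codon = TRUE)))
  if (to_stop) sub("\\*.*$", "", aa) else aa
}

#' Reverse complement of a DNA sequence
#'
#' @param dna nucleotide string (IUPAC).
#' @return the reverse complement, 5'\eqn{\to}3'.
#' @export
reverse_complement <- function(dna) {
  dna <- check_dna(dna)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

# Unified nearest-neighbor parameters (10 Watson-Crick stacks), ΔH in
# kcal/mol and ΔS in cal/(mol·K), plus terminal initiation terms. Default
# conditions: 50 mM monovalent salt, 500 nM total oligo, salt correction
# 0.368·(N−1)·ln[Na+] applied to ΔS.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
NN_INIT_DH <- c(GC = 0.1, AT = 2.3)
NN_INIT_DS <- c(GC = -2.8, AT = 4.1)

#' Oligonucleotide melting temperature
#'
#' Two estimators are available. The Wallace rule,
#' \eqn{2(A+T) + 4(G+C)} degrees C, is the quick formula for short oligos.
#' The nearest-neighbor model sums duplex stacking enthalpies and entropies
#' over the unified parameter set with terminal initiation terms, applies a
#' salt correction of \eqn{0.368 (N-1) \ln[Na^+]} to the entropy, and
#' evaluates \eqn{T_m = \Delta H / (\Delta S + R \ln(C_T/4)) - 273.15} at
#' 50 mM monovalent salt and 500 nM total oligo.
#'
#' Both estimators are strand-symmetric: \code{melting_temperature(x)} equals
#' \code{melting_temperature(reverse_complement(x))}.
#'
#' @param seq nucleotide string, unambiguous bases only, length >= 4.
#' @param method "nearest_neighbor" (default) or "wallace".
#' @param na_mM monovalent cation concentration in mM (nearest neighbor only).
#' @param oligo_nM total oligonucleotide concentration in nM (nearest
#'   neighbor only).
#' @return melting temperature in degrees Celsius.
#' @export
melting_temperature <- function(seq, method = c("nearest_neighbor", "wallace"),
                                na_mM = 50, oligo_nM = 500) {
  method <- match.arg(method)
  seq <- check_dna(seq)
  if (grepl("[^ACGT]", seq))
    abort_alphabet("melting temperature needs unambiguous A/C/G/T bases")
  n <- nchar(seq)
  if (n < 4L) abort_validation("sequence too short for a melting temperature (need >= 4 nt)")
  base <- strsplit(seq, "")[[1]]
  if (method == "wallace") {
    at <- sum(base %in% c("A", "T"))
    return(2 * at + 4 * (n - at))
  }
  stacks <- paste0(base[-n], base[-1L])
  dH <- sum(NN_DH[stacks])
  dS <- sum(NN_DS[stacks])
  for (term in c(base[1L], base[n])) {
    cls <- if (term %in% c("G", "C")) "GC" else "AT"
    dH <- dH + NN_INIT_DH[[cls]]
    dS <- dS + NN_INIT_DS[[cls]]
  }
  dS <- dS + 0.368 * (n - 1L) * log(na_mM / 1000)
  ct <- oligo_nM * 1e-9
  dH * 1000 / (dS + 1.987 * log(ct / 4)) - 273.15
}
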