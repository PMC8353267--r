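#' Assay-design configuration
#'
#' Bundles the panel-design rules: which precursor and fragment charge
#' states are enumerated, how many top-ranked fragments are kept during
#' assay development, the panel bounds (peptides per protein, transitions
#' per peptide), candidate peptide length limits, the in-silico digestion
#' settings and the heavy-label shifts.
#'
#' Defaults reflect common practice for a validated multiplexed SRM panel:
#' doubly/triply charged precursors, singly/doubly charged b/y fragments,
#' the 20 most probable fragments screened per precursor, final panels
#' with 2-8 proteotypic peptides per protein carrying their 4-10 best
#' transitions each.
#'
#' @param precursor_charges Integer vector of precursor charges.
#' @param fragment_charges Integer vector of fragment charges.
#' @param top_n_fragments Fragments kept per precursor charge during
#'   enumeration.
#' @param min_peptides,max_peptides Bounds on peptides per protein.
#' @param min_transitions,max_transitions Bounds on transitions per peptide.
#' @param min_peptide_length,max_peptide_length Candidate peptide length
#'   window (residues) for panel building.
#' @param heavy_shifts Named vector of C-terminal label shifts in Da.
#' @param missed_cleavages Missed cleavages allowed by the digest.
#' @param proline_rule Suppress cleavage before proline?
#' @return A `design_config` list.
#' @export
design_config <- function(precursor_charges = c(2L, 3L),
                          fragment_charges = c(1L, 2L),
                          top_n_fragments = 20L,
                          min_peptides = 2L, max_peptides = 8L,
                          min_transitions = 4L, max_transitions = 10L,
                          min_peptide_length = 7L, max_peptide_length = 25L,
                          heavy_shifts = c(K = 8.014199, R = 10.008269),
                          missed_cleavages = 0L,
                          proline_rule = TRUE) {
  stopifnot(min_peptides <= max_peptides,
            min_transitions <= max_transitions,
            top_n_fragments >= max_transitions,
            min_peptide_length <= max_peptide_length,
            missed_cleavages >= 0)
  structure(
    list(precursor_charges = as.integer(precursor_charges),
         fragment_charges = as.integer(fragment_charges),
         top_n_fragments = as.integer(top_n_fragments),
         min_peptides = as.integer(min_peptides),
         max_peptides = as.integer(max_peptides),
         min_transitions = as.integer(min_transitions),
         max_transitions = as.integer(max_transitions),
         min_peptide_length = as.integer(min_peptide_length),
         max_peptide_length = as.integer(max_peptide_length),
         heavy_shifts = heavy_shifts,
         missed_cleavages = as.integer(missed_cleavages),
         proline_rule = isTRUE(proline_rule)),
    class = "design_config"
  )
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R, optionally suppressing cleavage when the next
#' residue is proline. Dual LysC+trypsin digestion converges to fully
#' tryptic peptides, so a single K/R rule covers both proteases. Peptides
#' with up to `config$missed_cleavages` missed cleavage sites are appended
#' after the fully cleaved set.
#'
#' @param sequence Protein sequence (canonical residues only).
#' @param config A [design_config()].
#' @return Character vector of peptides; the fully cleaved peptides come
#'   first and concatenate, in order, to the input sequence.
#' @examples
#' digest_protein("AKCRGPK")  # "AK" "CR" "GPK"
#' @export
digest_protein <- function(sequence, config = design_config()) {
  residues <- .check_sequence(sequence)
  n <- length(residues)
  # cleavage after position i: residue K/R, not followed by P (proline rule)
  cut_after <- which(residues %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n]
  if (config$proline_rule) {
    cut_after <- cut_after[residues[cut_after + 1L] != "P"]
  }
  bounds <- c(0L, cut_after, n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  base <- vapply(seq_along(starts), function(i) {
    paste(residues[starts[i]:ends[i]], collapse = "")
  }, character(1))
  peptides <- base
  if (config$missed_cleavages > 0 && length(base) > 1) {
    for (k in seq_len(config$missed_cleavages)) {
      if (k >= length(base)) break
      joined <- vapply(seq_len(length(base) - k), function(i) {
        paste(base[i:(i + k)], collapse = "")
      }, character(1))
      peptides <- c(peptides, joined)
    }
  }
  peptides
}

#' Read a reference proteome from FASTA
#'
#' The first whitespace-delimited token of each description line is taken
#' as the protein identifier.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return Named character vector `protein_id -> sequence`.
#' @export
read_proteome_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  out <- as.character(seqs)
  names(out) <- ids
  out
}

#' Is a peptide proteotypic within a reference proteome?
#'
#' A peptide is proteotypic when it occurs as a substring of exactly one
#' proteome entry. A peptide absent from every entry is not proteotypic:
#' specificity is defined with respect to the reference proteome, so a
#' target must exist there.
#'
#' @param peptide Peptide sequence.
#' @param proteome Named character vector `protein_id -> sequence`.
#' @return `TRUE` iff the peptide maps to exactly one proteome entry.
#' @export
check_proteotypic <- function(peptide, proteome) {
  if (!is.character(peptide) || length(peptide) != 1L || !nzchar(peptide)) {
    stop("peptide must be a single non-empty string", call. = FALSE)
  }
  if (!length(proteome)) stop("proteome must be non-empty", call. = FALSE)
  hits <- sum(vapply(proteome, function(s) grepl(peptide, s, fixed = TRUE),
                     logical(1)))
  hits == 1L
}
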