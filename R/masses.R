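#' Monoisotopic residue masses and mass constants
#'
#' Internal tables used by all m/z arithmetic. Residue masses are
#' monoisotopic (Da); the instrument in this workflow operates at unit
#' resolution on monoisotopic targets, so average masses are never used.
#'
#' @name mass-constants
#' @keywords internal
NULL

# monoisotopic residue masses, 20 canonical amino acids
.AA_MONO <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009184, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

.PROTON <- 1.007276
.WATER  <- 18.010565

# fixed modification: carbamidomethylation of cysteine (iodoacetamide)
.CARBAMIDOMETHYL <- 57.021464

# stable-isotope label shifts for C-terminal K/R of tryptic reference peptides
.HEAVY_SHIFTS <- c(K = 8.014199, R = 10.008269)

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      !nzchar(sequence)) {
    stop("peptide/protein sequence must be a single non-empty string",
         call. = FALSE)
  }
  residues <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!(residues %in% names(.AA_MONO)))
  if (length(bad)) {
    stop(sprintf("non-canonical residue '%s' at position %d in '%s'",
                 residues[bad[1]], bad[1], sequence), call. = FALSE)
  }
  residues
}

#' Create a peptide specification
#'
#' A `peptide_spec` carries the sequence together with the fixed-modification
#' set, the label state and the heavy-label mass shift, and optionally an
#' indexed retention time (iRT) score. Heavy peptides model spiked-in
#' stable-isotope-labelled synthetic references: the label sits on the
#' C-terminal K or R, so it shifts the precursor and all y ions but no b ion.
#'
#' @param sequence Uppercase amino-acid string (20 canonical residues).
#' @param protein_id Identifier of the parent protein.
#' @param label `"light"` or `"heavy"`.
#' @param heavy_shift Mass shift in Da for the heavy label. Defaults to the
#'   standard SIL shifts (+8.014199 for K, +10.008269 for R) looked up from
#'   the C-terminal residue when `label = "heavy"`, 0 when light.
#' @param irt Optional dimensionless iRT score.
#' @param fixed_mods Named numeric vector of per-residue mass shifts (Da);
#'   default carbamidomethyl on C.
#' @return An object of class `peptide_spec`.
#' @examples
#' peptide_spec("SAMPLEK", protein_id = "P1", label = "heavy")
#' @export
peptide_spec <- function(sequence, protein_id = NA_character_,
                         label = c("light", "heavy"), heavy_shift = NULL,
                         irt = NA_real_,
                         fixed_mods = c(C = .CARBAMIDOMETHYL)) {
  label <- match.arg(label)
  residues <- .check_sequence(sequence)
  if (label == "heavy") {
    cterm <- residues[length(residues)]
    if (is.null(heavy_shift)) {
      if (!cterm %in% names(.HEAVY_SHIFTS)) {
        stop("heavy peptides must end in K or R (tryptic C-terminus)",
             call. = FALSE)
      }
      heavy_shift <- unname(.HEAVY_SHIFTS[cterm])
    }
    if (heavy_shift <= 0) stop("heavy_shift must be > 0 for heavy peptides",
                               call. = FALSE)
  } else {
    heavy_shift <- 0
  }
  structure(
    list(sequence = sequence, protein_id = protein_id, label = label,
         heavy_shift = heavy_shift, irt = irt, fixed_mods = fixed_mods),
    class = "peptide_spec"
  )
}

.as_peptide_spec <- function(x, ...) {
  if (inherits(x, "peptide_spec")) x else peptide_spec(x, ...)
}

# per-residue masses including fixed modifications, no water
.residue_masses <- function(peptide) {
  residues <- .check_sequence(peptide$sequence)
  m <- unname(.AA_MONO[residues])
  if (length(peptide$fixed_mods)) {
    for (res in names(peptide$fixed_mods)) {
      m[residues == res] <- m[residues == res] + peptide$fixed_mods[[res]]
    }
  }
  m
}

#' Neutral monoisotopic mass of a peptide
#'
#' Sum of residue masses plus fixed-modification shifts, the heavy-label
#' shift (if any) and one water.
#'
#' @param peptide A `peptide_spec` or a plain sequence string (treated as
#'   light with default fixed modifications).
#' @return Neutral mass in Da.
#' @export
peptide_neutral_mass <- function(peptide) {
  peptide <- .as_peptide_spec(peptide)
  sum(.residue_masses(peptide)) + peptide$heavy_shift + .WATER
}

#' Precursor m/z of a peptide
#'
#' @inheritParams peptide_neutral_mass
#' @param charge Positive integer charge state.
#' @return m/z in Thomson.
#' @examples
#' peptide_mz("R", 1)  # 175.1190, the y1/arginine reference value
#' @export
peptide_mz <- function(peptide, charge) {
  if (!is.numeric(charge) || length(charge) != 1L || is.na(charge) ||
      charge < 1 || charge != round(charge)) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  (peptide_neutral_mass(peptide) + charge * .PROTON) / charge
}

#' Fragment-ion m/z for the b and y series
#'
#' b ions contain residues `1..index`; y ions contain residues
#' `index+1..n` plus water. The heavy label is C-terminal, so it shifts all
#' y ions (and the precursor) but never a b ion.
#'
#' @inheritParams peptide_mz
#' @param series `"b"` or `"y"`.
#' @param index Fragment index, `1 <= index <= nchar(sequence) - 1`. For a
#'   y ion the index is the number of C-terminal residues retained.
#' @return m/z in Thomson.
#' @examples
#' fragment_mz("AGR", "y", 1, 1)  # y1 of an R-terminated peptide: 175.1190
#' @export
fragment_mz <- function(peptide, series = c("b", "y"), index, charge) {
  series <- match.arg(series)
  peptide <- .as_peptide_spec(peptide)
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != round(charge)) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  n <- nchar(peptide$sequence)
  if (!is.numeric(index) || length(index) != 1L || index != round(index) ||
      index < 1 || index > n - 1) {
    stop(sprintf("fragment index must be in 1..%d (sequence '%s')",
                 n - 1, peptide$sequence), call. = FALSE)
  }
  m <- .residue_masses(peptide)
  neutral <- if (series == "b") {
    sum(m[seq_len(index)])
  } else {
    sum(m[seq.int(n - index + 1, n)]) + .WATER + peptide$heavy_shift
  }
  (neutral + charge * .PROTON) / charge
}
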