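#' Enumerate ranked transitions for one peptide
#'
#' Candidate transitions are all b/y fragments (index `1..n-1`) at the
#' configured fragment charges, for each configured precursor charge. For
#' every precursor charge at most `config$top_n_fragments` transitions are
#' kept, ordered by library intensity rank (1 = most intense). Ties are
#' broken deterministically: y before b, lower fragment index first, lower
#' fragment charge first. Light and heavy twins are emitted as matched
#' pairs with identical fragment coordinates; the heavy C-terminal label
#' shifts the precursor and y-ion m/z but not b ions.
#'
#' @param peptide A [peptide_spec()] (light) or sequence string.
#' @param fragment_ranks Data frame with columns `fragment` (e.g. `"y7"`),
#'   `fragment_charge`, `rank`. Fragments missing from the table are not
#'   rankable and are dropped.
#' @param config A [design_config()].
#' @return Data frame of transitions with columns `protein`,
#'   `peptide_sequence`, `label`, `precursor_mz`, `precursor_charge`,
#'   `fragment`, `fragment_charge`, `product_mz`, `irt`, `rank`.
#' @export
enumerate_transitions <- function(peptide, fragment_ranks,
                                  config = design_config()) {
  light <- .as_peptide_spec(peptide)
  n <- nchar(light$sequence)
  cterm <- substr(light$sequence, n, n)
  heavy <- if (cterm %in% names(config$heavy_shifts)) {
    peptide_spec(light$sequence, protein_id = light$protein_id,
                 label = "heavy",
                 heavy_shift = unname(config$heavy_shifts[cterm]),
                 irt = light$irt, fixed_mods = light$fixed_mods)
  } else {
    NULL
  }

  cand <- expand.grid(series = c("y", "b"),
                      index = seq_len(n - 1L),
                      fragment_charge = config$fragment_charges,
                      stringsAsFactors = FALSE)
  cand$fragment <- paste0(cand$series, cand$index)
  key <- function(f, z) paste(f, z, sep = "/")
  ranks <- stats::setNames(fragment_ranks$rank,
                           key(fragment_ranks$fragment,
                               fragment_ranks$fragment_charge))
  cand$rank <- unname(ranks[key(cand$fragment, cand$fragment_charge)])
  cand <- cand[!is.na(cand$rank), , drop = FALSE]
  if (!nrow(cand)) {
    stop(sprintf("no rankable fragments for peptide '%s'", light$sequence),
         call. = FALSE)
  }
  # rank, then y-before-b, lower index, lower fragment charge
  cand <- cand[order(cand$rank, match(cand$series, c("y", "b")),
                     cand$index, cand$fragment_charge), , drop = FALSE]
  keep <- utils::head(cand, config$top_n_fragments)

  one_label <- function(pep, z) {
    data.frame(
      protein = pep$protein_id,
      peptide_sequence = pep$sequence,
      label = pep$label,
      precursor_mz = peptide_mz(pep, z),
      precursor_charge = z,
      fragment = keep$fragment,
      fragment_charge = keep$fragment_charge,
      product_mz = vapply(seq_len(nrow(keep)), function(i) {
        fragment_mz(pep, keep$series[i], keep$index[i],
                    keep$fragment_charge[i])
      }, numeric(1)),
      irt = pep$irt,
      rank = keep$rank,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(config$precursor_charges, function(z) {
    rows <- one_label(light, z)
    if (!is.null(heavy)) rows <- rbind(rows, one_label(heavy, z))
    rows
  }))
  rownames(out) <- NULL
  out
}

#' Assemble a validated multiplexed SRM panel
#'
#' Per target protein: in-silico digest, keep candidate peptides within the
#' configured length window, keep only proteotypic peptides when a
#' reference proteome is supplied, score peptides by their library fragment
#' evidence, and attach each selected peptide's best transitions (one
#' precursor charge per peptide, up to `max_transitions`, requiring at
#' least `min_transitions`). Proteins that end up with fewer than
#' `min_peptides` usable peptides are excluded with a reason — the fate of
#' markers whose tryptic peptides are all shared with other proteome
#' entries.
#'
#' @param targets Data frame with columns `protein_id`, `sequence`, or a
#'   named character vector of sequences.
#' @param proteome Optional named character vector `protein_id -> sequence`
#'   used for proteotypicity checks.
#' @param library_ranks Data frame with columns `peptide_sequence`,
#'   `fragment`, `fragment_charge`, `rank` (spectral-library intensity
#'   ranks per peptide).
#' @param irts Optional named numeric vector `peptide_sequence -> iRT`.
#' @param config A [design_config()].
#' @return A `protein_panel`: list with `proteins` (validated ids),
#'   `peptides`, `transitions`, `excluded` data frames and the `config`.
#' @export
build_panel <- function(targets, proteome = NULL, library_ranks = NULL,
                        irts = NULL, config = design_config()) {
  if (is.character(targets)) {
    targets <- data.frame(protein_id = names(targets), sequence = unname(targets),
                          stringsAsFactors = FALSE)
  }
  if (!nrow(targets)) stop("target list is empty", call. = FALSE)

  peptide_rows <- list(); transition_rows <- list(); excluded <- list()

  for (i in seq_len(nrow(targets))) {
    pid <- targets$protein_id[i]
    peps <- digest_protein(targets$sequence[i], config)
    peps <- unique(peps)
    len <- nchar(peps)
    peps <- peps[len >= config$min_peptide_length &
                   len <= config$max_peptide_length]
    if (!length(peps)) {
      excluded[[pid]] <- "no candidate peptides in length window"
      next
    }
    proteotypic_checked <- !is.null(proteome)
    if (proteotypic_checked) {
      keep <- vapply(peps, check_proteotypic, logical(1), proteome = proteome)
      if (!any(keep)) {
        excluded[[pid]] <- "no proteotypic peptides"
        next
      }
      peps <- peps[keep]
    }
    # score peptides by library evidence: sum of 1/rank over ranked fragments
    score <- vapply(peps, function(p) {
      if (is.null(library_ranks)) return(0)
      r <- library_ranks$rank[library_ranks$peptide_sequence == p]
      if (!length(r)) return(-Inf)
      sum(1 / r)
    }, numeric(1))
    ord <- order(-score, peps)
    peps <- peps[ord]; score <- score[ord]

    accepted_pep <- list(); accepted_trans <- list()
    for (j in seq_along(peps)) {
      if (length(accepted_pep) >= config$max_peptides) break
      p <- peps[j]
      ranks_p <- if (is.null(library_ranks)) NULL else
        library_ranks[library_ranks$peptide_sequence == p,
                      c("fragment", "fragment_charge", "rank"), drop = FALSE]
      if (is.null(ranks_p) || !nrow(ranks_p)) next
      irt_p <- if (!is.null(irts) && p %in% names(irts)) unname(irts[[p]])
               else NA_real_
      spec <- peptide_spec(p, protein_id = pid, irt = irt_p)
      tr <- tryCatch(enumerate_transitions(spec, ranks_p, config),
                     error = function(e) NULL)
      if (is.null(tr)) next
      # pick the precursor charge with the best (lowest) summed rank over
      # its top transitions, then trim to the per-peptide bounds
      by_z <- split(tr, tr$precursor_charge)
      best <- names(by_z)[which.min(vapply(by_z, function(d) {
        lt <- d[d$label == "light", ]
        sum(utils::head(sort(lt$rank), config$max_transitions))
      }, numeric(1)))]
      tr <- by_z[[best]]
      frag_keys <- unique(paste(tr$fragment, tr$fragment_charge, sep = "/"))
      keep_keys <- utils::head(frag_keys, config$max_transitions)
      tr <- tr[paste(tr$fragment, tr$fragment_charge, sep = "/") %in%
                 keep_keys, ]
      n_tr <- sum(tr$label == "light")
      if (n_tr < config$min_transitions) next
      accepted_pep[[p]] <- data.frame(
        protein = pid, peptide_sequence = p, irt = irt_p,
        peptide_score = score[j],
        precursor_charge = as.integer(best),
        n_transitions = n_tr,
        proteotypic = proteotypic_checked,
        stringsAsFactors = FALSE)
      accepted_trans[[p]] <- tr
    }
    if (length(accepted_pep) < config$min_peptides) {
      excluded[[pid]] <- sprintf(
        "insufficient usable peptides (%d < %d)",
        length(accepted_pep), config$min_peptides)
      next
    }
    peptide_rows[[pid]] <- do.call(rbind, accepted_pep)
    transition_rows[[pid]] <- do.call(rbind, accepted_trans)
  }

  if (!length(peptide_rows)) {
    reasons <- paste(sprintf("%s: %s", names(excluded), unlist(excluded)),
                     collapse = "; ")
    stop("all targets excluded — ", reasons, call. = FALSE)
  }
  panel <- structure(
    list(proteins = names(peptide_rows),
         peptides = {
           d <- do.call(rbind, peptide_rows); rownames(d) <- NULL; d
         },
         transitions = {
           d <- do.call(rbind, transition_rows); rownames(d) <- NULL; d
         },
         excluded = if (length(excluded)) {
           data.frame(protein = names(excluded), reason = unlist(excluded),
                      row.names = NULL, stringsAsFactors = FALSE)
         } else {
           data.frame(protein = character(), reason = character())
         },
         config = config),
    class = "protein_panel")
  panel
}

#' @export
print.protein_panel <- function(x, ...) {
  cat(sprintf("protein_panel: %d proteins, %d peptides, %d transitions (light)\n",
              length(x$proteins), nrow(x$peptides),
              sum(x$transitions$label == "light")))
  if (nrow(x$excluded)) {
    cat("excluded:\n")
    for (i in seq_len(nrow(x$excluded)))
      cat(sprintf("  %s: %s\n", x$excluded$protein[i], x$excluded$reason[i]))
  }
  invisible(x)
}

#' Validate a panel against its design rules
#'
#' Checks, per protein, the peptide count against the min/max peptide
#' bounds and, per peptide, the (light) transition count against the
#' min/max transition bounds. The panel is valid iff every check passes.
#'
#' @param panel A `protein_panel`.
#' @return A `panel_validation` list: `protein_summary`, `peptide_summary`
#'   data frames and a logical `valid`.
#' @export
validate_panel <- function(panel) {
  cfg <- panel$config
  lt <- panel$transitions[panel$transitions$label == "light", ]
  pep_counts <- table(panel$peptides$protein)
  tr_counts <- stats::aggregate(
    fragment ~ protein + peptide_sequence, data = lt, FUN = length)
  names(tr_counts)[3] <- "n_transitions"
  tr_counts$transitions_ok <- tr_counts$n_transitions >= cfg$min_transitions &
    tr_counts$n_transitions <= cfg$max_transitions
  protein_summary <- data.frame(
    protein = names(pep_counts),
    n_peptides = as.integer(pep_counts),
    stringsAsFactors = FALSE)
  protein_summary$peptides_ok <-
    protein_summary$n_peptides >= cfg$min_peptides &
    protein_summary$n_peptides <= cfg$max_peptides
  protein_summary$transitions_ok <- vapply(protein_summary$protein,
    function(p) all(tr_counts$transitions_ok[tr_counts$protein == p]),
    logical(1))
  protein_summary$pass <- protein_summary$peptides_ok &
    protein_summary$transitions_ok
  structure(list(protein_summary = protein_summary,
                 peptide_summary = tr_counts,
                 valid = all(protein_summary$pass)),
            class = "panel_validation")
}

#' @export
print.panel_validation <- function(x, ...) {
  cat(sprintf("panel validation: %s\n", if (x$valid) "VALID" else "INVALID"))
  print(x$protein_summary, row.names = FALSE)
  invisible(x)
}

.TRANSITION_LIST_COLS <- c("protein", "peptide_sequence", "label",
                           "precursor_mz", "precursor_charge", "fragment",
                           "fragment_charge", "product_mz", "irt", "rank")

#' Write / read a transition-list CSV
#'
#' Columns (exactly): protein, peptide_sequence, label, precursor_mz,
#' precursor_charge, fragment, fragment_charge, product_mz, irt, rank.
#' m/z and iRT values are written with 4 decimals.
#'
#' @param x A `protein_panel` or a transition data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transition_list <- function(x, path) {
  d <- if (inherits(x, "protein_panel")) x$transitions else x
  d <- d[, .TRANSITION_LIST_COLS]
  for (col in c("precursor_mz", "product_mz", "irt")) {
    d[[col]] <- sprintf("%.4f", d[[col]])
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transition_list
#' @export
read_transition_list <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.TRANSITION_LIST_COLS, names(d))
  if (length(missing)) {
    stop("transition list missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  d
}

#' Count transitions by label state
#'
#' @param x Transition data frame (or `protein_panel`).
#' @return Named integer vector with `light`, `heavy` and `total` counts.
#' @export
transition_counts <- function(x) {
  d <- if (inherits(x, "protein_panel")) x$transitions else x
  light <- sum(d$label == "light")
  heavy <- sum(d$label == "heavy")
  c(light = light, heavy = heavy, total = light + heavy)
}
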