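#' Run the full quantification pipeline on a transition report
#'
#' Applies, in order: the top-transition S/N peak-group filter,
#' below-background imputation, log2 transformation, median-of-transition
#' peptide abundances, per-condition detection calls, mixed-effects
#' condition-versus-control comparisons for every protein quantifiable on
#' either side of a comparison, and Benjamini-Hochberg adjustment across
#' proteins within each comparison.
#'
#' Quantification uses light-label areas; heavy spiked-in references serve
#' co-elution verification (see [verify_coelution()]) unless
#' `config$ratio_to_heavy` is set, in which case log2(light/heavy) ratios
#' are modelled instead.
#'
#' @param report Transition-report data frame (see
#'   [read_transition_report()]).
#' @param config A [quant_config()].
#' @return An `srm_quant_result` list: `comparisons` (per protein and
#'   condition: log2fc, se, t_value, df, p_value, adj_p_value,
#'   significant), `detection` (per protein and condition: status and
#'   peptide counts), `peptide_abundance`, `protein_abundance` (median of
#'   peptide abundances per replicate), `condition_summary`, the rejection
#'   log and the config.
#' @export
quantify_experiment <- function(report, config = quant_config()) {
  retained <- filter_peak_groups(report, config)
  rejected <- attr(retained, "rejected")

  light <- retained[retained$label == "light", , drop = FALSE]
  if (!nrow(light)) stop("no peak groups survived filtering", call. = FALSE)
  area <- impute_below_background(light$peak_area, light$background,
                                  config$imputation_factor)
  light$log2_area <- log2(pmax(area, .Machine$double.eps))
  if (config$ratio_to_heavy) {
    heavy <- retained[retained$label == "heavy", , drop = FALSE]
    hkey <- paste(heavy$protein, heavy$peptide_sequence,
                  heavy$precursor_charge, heavy$fragment,
                  heavy$fragment_charge, heavy$run_id)
    lkey <- paste(light$protein, light$peptide_sequence,
                  light$precursor_charge, light$fragment,
                  light$fragment_charge, light$run_id)
    h_area <- heavy$peak_area[match(lkey, hkey)]
    light$log2_area <- light$log2_area -
      log2(pmax(h_area, .Machine$double.eps))
  }
  light$feature <- paste(light$peptide_sequence, light$precursor_charge,
                         light$fragment, light$fragment_charge, sep = "_")

  conditions <- unique(report$condition)
  proteins <- unique(report$protein)

  # detection calls: peptide detected in a replicate iff retained there
  detection <- do.call(rbind, lapply(proteins, function(pr) {
    do.call(rbind, lapply(conditions, function(cd) {
      sub <- light[light$protein == pr & light$condition == cd, ]
      reps <- sort(unique(report$replicate[report$condition == cd]))
      peps <- unique(report$peptide_sequence[report$protein == pr])
      mat <- matrix(FALSE, nrow = length(peps), ncol = length(reps),
                    dimnames = list(peps, reps))
      if (nrow(sub)) {
        hit <- unique(sub[, c("peptide_sequence", "replicate")])
        mat[cbind(match(hit$peptide_sequence, peps),
                  match(hit$replicate, reps))] <- TRUE
      }
      call <- call_detection(mat, config)
      data.frame(protein = pr, condition = cd, status = call$status,
                 n_peptides_detected = call$n_peptides_detected,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(detection) <- NULL

  # peptide abundances: median of transition log2 areas per run
  pep_ab <- stats::aggregate(
    log2_area ~ protein + peptide_sequence + condition + replicate + run_id,
    data = light, FUN = peptide_abundance)
  names(pep_ab)[names(pep_ab) == "log2_area"] <- "abundance"
  # protein abundance per replicate: median of its peptide abundances
  prot_ab <- stats::aggregate(
    abundance ~ protein + condition + replicate + run_id,
    data = pep_ab, FUN = stats::median)

  condition_summary <- do.call(rbind, lapply(
    split(prot_ab, list(prot_ab$protein, prot_ab$condition), drop = TRUE),
    function(d) {
      cbind(data.frame(protein = d$protein[1], condition = d$condition[1],
                       stringsAsFactors = FALSE),
            summarize_condition(d$abundance, config$ci_level))
    }))
  rownames(condition_summary) <- NULL

  status_of <- function(pr, cd) {
    s <- detection$status[detection$protein == pr &
                            detection$condition == cd]
    if (length(s)) s[1] else "not_detected"
  }

  control <- config$control_condition
  test_conditions <- setdiff(conditions, control)
  comparisons <- do.call(rbind, lapply(test_conditions, function(cd) {
    rows <- do.call(rbind, lapply(proteins, function(pr) {
      # a comparison is quantifiable if either side is
      if (status_of(pr, cd) != "quantifiable" &&
          status_of(pr, control) != "quantifiable") return(NULL)
      d <- light[light$protein == pr, c("condition", "run_id", "feature",
                                        "log2_area")]
      fit <- tryCatch(fit_group_comparison(d, cd, control, config),
                      error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      cbind(data.frame(protein = pr, condition = cd, control = control,
                       stringsAsFactors = FALSE), fit)
    }))
    if (is.null(rows)) return(NULL)
    # BH across proteins within one condition-vs-control comparison
    rows$adj_p_value <- adjust_bh(rows$p_value)
    rows$significant <- rows$adj_p_value <= config$fdr_alpha
    rows
  }))
  if (!is.null(comparisons)) rownames(comparisons) <- NULL

  structure(list(comparisons = comparisons, detection = detection,
                 peptide_abundance = pep_ab, protein_abundance = prot_ab,
                 condition_summary = condition_summary,
                 rejected = rejected, config = config),
            class = "srm_quant_result")
}

#' @export
print.srm_quant_result <- function(x, ...) {
  n_sig <- if (is.null(x$comparisons)) 0L else sum(x$comparisons$significant)
  cat(sprintf(paste0("srm_quant_result: %d proteins, %d comparisons ",
                     "(%d significant at FDR %.2f)\n"),
              length(unique(x$detection$protein)),
              if (is.null(x$comparisons)) 0L else nrow(x$comparisons),
              n_sig, x$config$fdr_alpha))
  tab <- table(x$detection$status)
  cat("detection calls: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Write quantification results to CSV files
#'
#' Writes `results.csv` (protein, condition, control, status, log2fc, se,
#' t_value, df, p_value, adj_p_value, significant), `detection.csv`
#' (protein, condition, status, n_peptides_detected) and
#' `abundances.csv` (protein-level abundances per replicate).
#'
#' @param result An `srm_quant_result`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_quant_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if (!is.null(result$comparisons)) {
    res <- result$comparisons
    res$status <- mapply(function(pr, cd) {
      s <- result$detection$status[result$detection$protein == pr &
                                     result$detection$condition == cd]
      if (length(s)) s[1] else NA_character_
    }, res$protein, res$condition)
    res <- res[, c("protein", "condition", "control", "status", "log2fc",
                   "se", "t_value", "df", "p_value", "adj_p_value",
                   "significant")]
    p <- file.path(dir, "results.csv")
    utils::write.csv(res, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "detection.csv")
  utils::write.csv(result$detection, p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "abundances.csv")
  utils::write.csv(result$protein_abundance, p, row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
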