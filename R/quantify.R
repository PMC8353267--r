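#' Quantification configuration
#'
#' Thresholds and options of the transition-level quantification pipeline:
#' the signal-to-noise rule (a peak group is kept when its top transition
#' has S/N strictly greater than `snr_threshold`), the below-background
#' imputation factor (peak areas below the transition-specific background
#' are assigned `imputation_factor` times the background), the
#' detectable/quantifiable calling rules, the FDR level for the adjusted
#' p-value cut-off, the confidence level of condition summaries, the
#' control condition, and the light/heavy co-elution acceptance rules.
#'
#' @param snr_threshold S/N threshold (strict `>`).
#' @param imputation_factor Fraction of background assigned to censored
#'   areas; default 1/3.
#' @param min_peptides_quantifiable Distinct peptides needed for a
#'   "quantifiable" call.
#' @param min_replicates_detected Replicates in which each such peptide
#'   must be detected.
#' @param fdr_alpha BH-adjusted p-value cut-off.
#' @param ci_level Confidence level for condition summaries.
#' @param control_condition Reference condition label.
#' @param coelution_dotp_min Minimum normalised dot product between light
#'   and heavy fragment-area vectors.
#' @param coelution_rt_tol Maximum |mean RT(light) - mean RT(heavy)|, min.
#' @param ratio_to_heavy Quantify light/heavy ratios instead of light
#'   areas. Off by default: heavy areas serve co-elution verification.
#' @return A `quant_config` list.
#' @export
quant_config <- function(snr_threshold = 3, imputation_factor = 1 / 3,
                         min_peptides_quantifiable = 2L,
                         min_replicates_detected = 3L,
                         fdr_alpha = 0.05, ci_level = 0.95,
                         control_condition = "NSC",
                         coelution_dotp_min = 0.9, coelution_rt_tol = 0.5,
                         ratio_to_heavy = FALSE) {
  stopifnot(snr_threshold >= 0, imputation_factor > 0, imputation_factor < 1,
            fdr_alpha > 0, fdr_alpha < 1, ci_level > 0, ci_level < 1)
  structure(list(snr_threshold = snr_threshold,
                 imputation_factor = imputation_factor,
                 min_peptides_quantifiable = as.integer(min_peptides_quantifiable),
                 min_replicates_detected = as.integer(min_replicates_detected),
                 fdr_alpha = fdr_alpha, ci_level = ci_level,
                 control_condition = control_condition,
                 coelution_dotp_min = coelution_dotp_min,
                 coelution_rt_tol = coelution_rt_tol,
                 ratio_to_heavy = isTRUE(ratio_to_heavy)),
            class = "quant_config")
}

.REPORT_COLS <- c("protein", "peptide_sequence", "precursor_charge",
                  "fragment", "fragment_charge", "label", "condition",
                  "replicate", "run_id", "rt_observed", "peak_area",
                  "background", "snr")

#' Read a transition-report CSV
#'
#' Vendor-neutral peak-area export: one row per transition per run.
#' Mandatory columns: protein, peptide_sequence, precursor_charge,
#' fragment, fragment_charge, label, condition, replicate, run_id,
#' rt_observed, peak_area, background, snr. Rows with non-finite or
#' negative peak_area/background/snr are rejected and logged (attribute
#' `"rejected"`, with line numbers); valid rows are returned unchanged.
#'
#' @param path CSV path.
#' @return Data frame of measurements; rejected rows in
#'   `attr(, "rejected")`.
#' @export
read_transition_report <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.REPORT_COLS, names(d))
  if (length(missing)) {
    stop("transition report missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num <- c("peak_area", "background", "snr")
  ok <- rep(TRUE, nrow(d))
  for (col in num) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    d[[col]] <- v
    ok <- ok & is.finite(v) & v >= 0
  }
  ok <- ok & d$label %in% c("light", "heavy")
  rejected <- d[!ok, , drop = FALSE]
  if (nrow(rejected)) rejected$line <- which(!ok) + 1L  # header is line 1
  out <- d[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Verify light/heavy co-elution and fragment-ratio match
#'
#' A heavy spiked-in reference must co-elute with its endogenous light
#' twin and show matching relative fragment intensities. The check passes
#' when the mean RT difference is within `coelution_rt_tol` and the
#' normalised dot product between the matched fragment-area vectors is at
#' least `coelution_dotp_min` (scale-invariant, so the 100-fold abundance
#' difference between endogenous and spiked peptide is irrelevant).
#'
#' @param light,heavy Data frames with columns `fragment`,
#'   `fragment_charge`, `peak_area` and `rt_observed` for one peptide in
#'   one run.
#' @param config A [quant_config()].
#' @return List with `pass`, `dotp`, `rt_delta`, `n_fragments`.
#' @export
verify_coelution <- function(light, heavy, config = quant_config()) {
  key <- function(d) paste(d$fragment, d$fragment_charge, sep = "/")
  shared <- intersect(key(light), key(heavy))
  if (!length(shared)) stop("no shared fragments between labels",
                            call. = FALSE)
  la <- light$peak_area[match(shared, key(light))]
  ha <- heavy$peak_area[match(shared, key(heavy))]
  nl <- sqrt(sum(la^2)); nh <- sqrt(sum(ha^2))
  dotp <- if (nl == 0 || nh == 0) 0 else sum(la * ha) / (nl * nh)
  rt_delta <- abs(mean(light$rt_observed) - mean(heavy$rt_observed))
  list(pass = dotp >= config$coelution_dotp_min &&
         rt_delta <= config$coelution_rt_tol,
       dotp = dotp, rt_delta = rt_delta, n_fragments = length(shared))
}

#' Filter peak groups by the top-transition S/N rule
#'
#' A peak group (all transitions of one peptide precursor in one run) is
#' retained iff its top transition — the one with the highest light peak
#' area in that run — has S/N strictly greater than the threshold.
#' Retention is decided per peak group, never per transition, and heavy
#' rows follow their group's fate. Every input row appears in exactly one
#' of the retained output or the rejection log.
#'
#' @param measurements Transition-report data frame.
#' @param config A [quant_config()].
#' @return Retained rows; rejected rows (with `reason`) in
#'   `attr(, "rejected")`.
#' @export
filter_peak_groups <- function(measurements, config = quant_config()) {
  if (!nrow(measurements)) {
    attr(measurements, "rejected") <- measurements
    return(measurements)
  }
  grp <- interaction(measurements$protein, measurements$peptide_sequence,
                     measurements$precursor_charge, measurements$condition,
                     measurements$replicate, measurements$run_id,
                     drop = TRUE)
  keep_grp <- vapply(split(seq_len(nrow(measurements)), grp), function(ix) {
    rows <- measurements[ix, ]
    light <- rows[rows$label == "light", ]
    if (!nrow(light)) return(FALSE)
    top <- which.max(light$peak_area)
    light$snr[top] > config$snr_threshold
  }, logical(1))
  keep <- keep_grp[as.character(grp)]
  retained <- measurements[keep, , drop = FALSE]
  rejected <- measurements[!keep, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- sprintf("top transition S/N <= %g",
                               config$snr_threshold)
  }
  rownames(retained) <- NULL
  attr(retained, "rejected") <- rejected
  retained
}

#' Impute peak areas below the transition-specific background
#'
#' Areas strictly below their background level are assigned
#' `factor * background` (default one-third of the background); areas at
#' or above background are unchanged. Idempotent: background/3 is itself
#' below background, but a second application recomputes the same value.
#'
#' @param peak_area,background Non-negative numeric vectors.
#' @param factor Imputation factor in (0, 1).
#' @return Adjusted peak areas.
#' @examples
#' impute_below_background(50, 300)   # 100
#' impute_below_background(400, 300)  # 400
#' @export
impute_below_background <- function(peak_area, background, factor = 1 / 3) {
  if (any(!is.finite(peak_area)) || any(!is.finite(background)) ||
      any(peak_area < 0) || any(background < 0)) {
    stop("peak_area and background must be finite and non-negative",
         call. = FALSE)
  }
  ifelse(peak_area < background, background * factor, peak_area)
}

#' Peptide abundance as the median of its transition log2 areas
#'
#' @param log2_areas Numeric vector of log2-transformed transition peak
#'   areas of one peptide in one run.
#' @return The median, or `NA` for empty input (no value is emitted for
#'   that run).
#' @export
peptide_abundance <- function(log2_areas) {
  log2_areas <- log2_areas[is.finite(log2_areas)]
  if (!length(log2_areas)) return(NA_real_)
  stats::median(log2_areas)
}

#' Detection call for one protein in one condition
#'
#' A peptide counts as detected in a replicate iff its peak group survived
#' the S/N filter there. The protein is `quantifiable` when at least
#' `min_peptides_quantifiable` distinct peptides are each detected in at
#' least `min_replicates_detected` replicates; `detectable` when at least
#' one peptide was detected anywhere but the quantifiable rule is unmet;
#' `not_detected` otherwise.
#'
#' @param detected Logical matrix or data frame, peptides x replicates:
#'   was the peptide's peak group retained in that replicate?
#' @param config A [quant_config()].
#' @return List with `status`, `n_peptides_detected` (peptides meeting the
#'   replicate rule) and `replicate_counts` per peptide.
#' @export
call_detection <- function(detected, config = quant_config()) {
  detected <- as.matrix(detected)
  if (!nrow(detected) || !any(detected)) {
    return(list(status = "not_detected", n_peptides_detected = 0L,
                replicate_counts = integer(0)))
  }
  counts <- rowSums(detected)
  n_ok <- sum(counts >= config$min_replicates_detected)
  status <- if (n_ok >= config$min_peptides_quantifiable) "quantifiable"
            else "detectable"
  list(status = status, n_peptides_detected = as.integer(n_ok),
       replicate_counts = counts)
}

#' Mixed-effects condition-versus-control comparison for one protein
#'
#' Fits `log2_area ~ condition + feature + (1 | run)` on the protein's
#' transition-level log2 abundances, where features are the
#' peptide/charge/transition combinations (fixed), the condition is fixed
#' and the run is random; the log2 fold-change is the condition contrast
#' against the control. Degrees of freedom use the Satterthwaite
#' approximation. When the run-variance estimate is zero (singular fit) or
#' there is only one feature, the model degrades gracefully to the
#' fixed-effects two-way fit with residual degrees of freedom. On balanced
#' complete data the estimate equals the difference of group means.
#'
#' @param data Data frame with columns `condition`, `run_id`, `feature`,
#'   `log2_area` for one protein, covering the condition and the control.
#' @param condition,control Condition labels to contrast.
#' @param config A [quant_config()].
#' @return One-row data frame: `log2fc`, `se`, `t_value`, `df`, `p_value`.
#' @export
fit_group_comparison <- function(data, condition, control,
                                 config = quant_config()) {
  d <- data[data$condition %in% c(condition, control), , drop = FALSE]
  d <- d[is.finite(d$log2_area), , drop = FALSE]
  if (!all(c(condition, control) %in% d$condition)) {
    stop("both the condition and the control must have data", call. = FALSE)
  }
  d$condition <- factor(d$condition, levels = c(control, condition))
  d$feature <- factor(d$feature)
  d$run_id <- factor(d$run_id)
  if (nlevels(d$run_id) < 2) {
    stop("singular design: only one run in total", call. = FALSE)
  }
  coef_name <- paste0("condition", condition)

  fit_fixed <- function() {
    fml <- if (nlevels(d$feature) > 1) log2_area ~ condition + feature
           else log2_area ~ condition
    fit <- stats::lm(fml, data = d)
    co <- summary(fit)$coefficients
    list(est = co[coef_name, 1], se = co[coef_name, 2],
         df = fit$df.residual)
  }

  res <- NULL
  if (nlevels(d$feature) > 1 &&
      nlevels(d$run_id) > nlevels(d$condition)) {
    mm <- tryCatch(suppressMessages(suppressWarnings(
      lmerTest::lmer(log2_area ~ condition + feature + (1 | run_id),
                     data = d))), error = function(e) NULL)
    if (!is.null(mm) && !lme4::isSingular(mm, tol = 1e-6)) {
      co <- stats::coef(summary(mm, ddf = "Satterthwaite"))
      res <- list(est = co[coef_name, "Estimate"],
                  se = co[coef_name, "Std. Error"],
                  df = co[coef_name, "df"])
    }
  }
  if (is.null(res)) res <- fit_fixed()

  est <- unname(res$est); se <- unname(res$se); df <- unname(res$df)
  if (!is.finite(se) || se < 1e-12) {
    # degenerate: no residual variation (e.g. condition copies the control)
    t_value <- if (abs(est) < 1e-12) 0 else sign(est) * Inf
    p <- if (abs(est) < 1e-12) 1 else 0
  } else {
    t_value <- est / se
    p <- 2 * stats::pt(-abs(t_value), df = df)
  }
  data.frame(log2fc = est, se = se, t_value = t_value, df = df,
             p_value = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, order-preserving with respect
#' to the input positions and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
adjust_bh <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be finite and in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Condition summary: median and confidence interval
#'
#' Summarises replicate-level protein abundances by their median; the
#' interval is the t-interval about the mean (displayed alongside the
#' median, as in condition plots). With a single replicate only the
#' median is defined.
#'
#' @param values Replicate-level abundances.
#' @param ci_level Confidence level.
#' @return One-row data frame: `median`, `ci_low`, `ci_high`, `n`.
#' @export
summarize_condition <- function(values, ci_level = 0.95) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (!n) return(data.frame(median = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, n = 0L))
  med <- stats::median(values)
  if (n < 2) {
    return(data.frame(median = med, ci_low = NA_real_, ci_high = NA_real_,
                      n = n))
  }
  se <- stats::sd(values) / sqrt(n)
  tq <- stats::qt(1 - (1 - ci_level) / 2, df = n - 1)
  m <- mean(values)
  data.frame(median = med, ci_low = m - tq * se, ci_high = m + tq * se,
             n = n)
}
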